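#' Pipeline run configuration
#'
#' Bundles every choice for a full turnover analysis: input tables, the
#' similarity index, PCA retention, the zonations to compare, the decay forms
#' and the permutation policy. Inputs may be given as file paths or as
#' already-constructed objects.
#'
#' @param occurrence path to an occurrence CSV, or an [occurrence_matrix()].
#' @param sites path to a site CSV, or a [site_table()].
#' @param index similarity index (`"jaccard"` or `"simpson"`).
#' @param variance_target,n_components PCA retention rule (see [env_pca()]).
#' @param zone_specs named list of [zone_spec()] objects (may be empty).
#' @param forms decay forms to fit.
#' @param n_perm permutation count (default 1000; reduce for quick runs).
#' @param seed integer seed; mandatory when `n_perm > 0`.
#' @param out_dir optional directory for CSV/JSON outputs; `NULL` keeps
#'   results in memory only.
#' @return a `run_config` list.
#' @export
run_config <- function(occurrence, sites, index = "jaccard",
                       variance_target = 0.95, n_components = NULL,
                       zone_specs = list(), forms = DECAY_FORMS,
                       n_perm = 1000, seed = NULL, out_dir = NULL) {
  if (n_perm > 0 && is.null(seed))
    stopf("a seed is mandatory when permutation tests are requested")
  for (p in list(occurrence, sites)) {
    if (is.character(p) && !file.exists(p)) stopf("input file not found: %s", p)
  }
  structure(list(occurrence = occurrence, sites = sites, index = index,
                 variance_target = variance_target, n_components = n_components,
                 zone_specs = zone_specs,
                 forms = match.arg(forms, DECAY_FORMS, several.ok = TRUE),
                 n_perm = n_perm, seed = seed, out_dir = out_dir),
            class = "run_config")
}

#' Run the full species-turnover pipeline
#'
#' Similarity matrix, the four explanatory distance matrices (geodesic,
#' environmental-PCA, mean-elevation difference, elevation-range difference)
#' plus area difference; whole-region decay fits with permutation
#' significance and halving distances; per-zone decay reports; simple and
#' partial Mantel tests of similarity against each explanatory matrix;
#' seven-fraction variation partitioning with incremental contributions of
#' elevation-range and area differences. Each stage error is re-thrown with
#' the stage name. With an output directory set, matrices are written as
#' CSV and results as JSON, along with a manifest (seed, config hash,
#' package version) sufficient to reproduce the run.
#'
#' @param cfg a [run_config()].
#' @return a `pipeline_result` list: `similarity`, `distances`, `pca`,
#'   `decay` (region-level fits), `zones` (per-spec report tables), `mantel`
#'   (simple and partial), `varpart`, `incremental`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  occ <- stage("read_occurrence", {
    if (is.character(cfg$occurrence)) read_occurrence(cfg$occurrence)
    else cfg$occurrence
  })
  sites <- stage("read_sites", {
    s <- if (is.character(cfg$sites)) read_sites(cfg$sites) else cfg$sites
    align_sites(s, occ)
  })
  sim <- stage("similarity", similarity_matrix(occ, index = cfg$index))
  pca <- stage("env_pca", env_pca(sites, variance_target = cfg$variance_target,
                                  n_components = cfg$n_components))
  dists <- stage("distances", list(
    geo = geo_distance_matrix(sites),
    env = env_distance_matrix(pca),
    elev = scalar_diff_matrix(sites, "mean_elev"),
    range = scalar_diff_matrix(sites, "elev_range"),
    area = scalar_diff_matrix(sites, "area")))
  decay_fits <- stage("decay", {
    fits <- lapply(cfg$forms, function(fm) {
      if (cfg$n_perm > 0)
        permutation_significance(sim, dists$geo, fm, n_perm = cfg$n_perm,
                                 seed = cfg$seed)
      else fit_decay(sim, dists$geo, fm)
    })
    names(fits) <- cfg$forms
    fits
  })
  zone_reports <- stage("zones", lapply(cfg$zone_specs, function(zs)
    zone_decay_report(occ, sites, zs, forms = cfg$forms, index = cfg$index,
                      n_perm = cfg$n_perm, seed = cfg$seed)))
  expl <- dists[c("geo", "env", "elev", "range")]
  mantel_res <- stage("mantel", {
    simple <- lapply(expl, function(m)
      mantel_simple(sim, m, n_perm = max(cfg$n_perm, 1), seed = cfg$seed))
    partial <- lapply(names(expl), function(nm)
      mantel_partial(sim, expl[[nm]], control = expl[names(expl) != nm],
                     n_perm = max(cfg$n_perm, 1), seed = cfg$seed))
    names(partial) <- names(expl)
    list(simple = simple, partial = partial)
  })
  vp <- stage("varpart", partition3(sim, g = dists$geo, e = dists$env,
                                    a = dists$elev))
  incr <- stage("incremental_r2", list(
    elev_range = incremental_r2(sim, list(G = dists$geo, E = dists$env,
                                          A = dists$elev), dists$range),
    area = incremental_r2(sim, list(G = dists$geo, E = dists$env,
                                    A = dists$elev), dists$area)))
  manifest <- list(
    package = "betadecay",
    version = as.character(utils::packageVersion("betadecay")),
    seed = cfg$seed, n_perm = cfg$n_perm, index = cfg$index,
    n_sites = nrow(occ), n_species = ncol(occ), n_pairs = n_pairs(occ),
    config_hash = config_hash(cfg))
  res <- structure(list(similarity = sim, distances = dists, pca = pca,
                        decay = decay_fits, zones = zone_reports,
                        mantel = mantel_res, varpart = vp, incremental = incr,
                        manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

# Stable hash of the configuration's serialised form (inputs by path or dims).
config_hash <- function(cfg) {
  key <- cfg
  if (!is.character(key$occurrence)) key$occurrence <- dim(key$occurrence)
  if (!is.character(key$sites)) key$sites <- dim(as.data.frame(key$sites))
  key$out_dir <- NULL
  bytes <- as.integer(serialize(key, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1e9
  sprintf("%09.0f", h)
}

# Write every stage's output as plain CSV / JSON plus the manifest.
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pairwise_csv(res$similarity, file.path(out_dir, "similarity.csv"))
  for (nm in names(res$distances))
    write_pairwise_csv(res$distances[[nm]],
                       file.path(out_dir, paste0("dist_", nm, ".csv")))
  decay_tab <- do.call(rbind, lapply(names(res$decay), function(fm) {
    f <- res$decay[[fm]]
    data.frame(form = fm, a = f$a, b = f$b, r2 = f$r2, p_perm = f$p_perm,
               s0 = f$s0, halving_distance = f$halving_distance,
               n_pairs = f$n_pairs, n_used = f$n_used)
  }))
  utils::write.csv(decay_tab, file.path(out_dir, "decay_fits.csv"),
                   row.names = FALSE)
  for (nm in names(res$zones))
    utils::write.csv(res$zones[[nm]],
                     file.path(out_dir, paste0("zones_", nm, ".csv")),
                     row.names = FALSE)
  mantel_tab <- do.call(rbind, lapply(c("simple", "partial"), function(kind)
    do.call(rbind, lapply(names(res$mantel[[kind]]), function(nm) {
      m <- res$mantel[[kind]][[nm]]
      data.frame(kind = kind, matrix = nm, r = m$r, p_perm = m$p_perm,
                 n_perm = m$n_perm,
                 controlled = paste(m$controlled, collapse = "+"))
    }))))
  utils::write.csv(mantel_tab, file.path(out_dir, "mantel.csv"),
                   row.names = FALSE)
  jsonlite::write_json(res$varpart[setdiff(names(res$varpart), "r2")],
                       file.path(out_dir, "varpart.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$incremental, file.path(out_dir, "incremental_r2.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("pipeline_result: %d sites, %d species, %d pairs (seed %s)\n",
              m$n_sites, m$n_species, m$n_pairs, m$seed))
  for (fm in names(x$decay)) print(x$decay[[fm]])
  print(x$varpart)
  invisible(x)
}
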