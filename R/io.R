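#' Construct a validated site-by-species occurrence matrix
#'
#' The core incidence container: a binary matrix with sites as rows and
#' species as columns. Every site must hold at least one species (an empty
#' assemblage makes pairwise similarity undefined); species recorded nowhere
#' are dropped with a warning, since subsetting sites into zones routinely
#' strands species.
#'
#' @param incidence numeric/integer matrix of 0/1 entries, sites x species.
#' @param site_ids,species_ids identifiers; default to dimnames.
#' @return an `occurrence_matrix`: the binary matrix with class attribute.
#' @export
occurrence_matrix <- function(incidence, site_ids = rownames(incidence),
                              species_ids = colnames(incidence)) {
  incidence <- as.matrix(incidence)
  if (is.null(site_ids)) site_ids <- paste0("site", seq_len(nrow(incidence)))
  if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(ncol(incidence)))
  site_ids <- as.character(site_ids)
  species_ids <- as.character(species_ids)
  if (anyDuplicated(site_ids))
    stopf("duplicate site ids: %s",
          paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  if (anyDuplicated(species_ids))
    stopf("duplicate species ids: %s",
          paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "))
  bad <- which(!(incidence %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(incidence))
    stopf("non-binary cell at site '%s', species '%s' (value %s)",
          site_ids[rc[1L]], species_ids[rc[2L]], incidence[bad[1L]])
  }
  storage.mode(incidence) <- "integer"
  dimnames(incidence) <- list(site_ids, species_ids)
  empty_sites <- rowSums(incidence) == 0L
  if (any(empty_sites))
    stopf("site(s) with no recorded species: %s",
          paste(site_ids[empty_sites], collapse = ", "))
  absent <- colSums(incidence) == 0L
  if (any(absent)) {
    warnf("dropping %d species recorded at no site: %s",
          sum(absent), paste(species_ids[absent], collapse = ", "))
    incidence <- incidence[, !absent, drop = FALSE]
  }
  structure(incidence, class = c("occurrence_matrix", "matrix", "array"))
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf(
    "occurrence_matrix: %d sites x %d species (%d site pairs), richness %d-%d\n",
    n, ncol(x), (n * (n - 1L)) %/% 2L, min(rowSums(x)), max(rowSums(x))))
  invisible(x)
}

#' Number of unordered site pairs
#'
#' @param x an `occurrence_matrix`, `pairwise_matrix`, or a site count.
#' @return n(n-1)/2.
#' @export
n_pairs <- function(x) {
  n <- if (is.matrix(x)) nrow(x) else as.integer(x)
  (n * (n - 1L)) %/% 2L
}

#' Read an occurrence CSV
#'
#' Expects a header row of species ids and a first column of site ids
#' (`orientation = "sites_rows"`), or the transpose
#' (`orientation = "species_rows"`). Cells must be 0/1.
#'
#' @param path CSV file path.
#' @param orientation which dimension the file's rows represent.
#' @return an [occurrence_matrix()]; row/column order as in the file.
#' @export
read_occurrence <- function(path, orientation = c("sites_rows", "species_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stopf("occurrence file needs an id column plus data: %s", path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(num)) {
    rc <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("non-numeric cell at row '%s', column '%s'", ids[rc[1L]], colnames(m)[rc[2L]])
  }
  dimnames(num) <- list(ids, colnames(m))
  if (orientation == "species_rows") num <- t(num)
  occurrence_matrix(num)
}

#' Write an occurrence matrix as CSV (sites as rows)
#'
#' @param occ an [occurrence_matrix()].
#' @param path output path.
#' @export
write_occurrence <- function(occ, path) {
  df <- data.frame(site_id = rownames(occ), unclass(occ), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

SITE_REQUIRED_COLS <- c("site_id", "lon", "lat", "mean_elev", "elev_range", "area")

#' Construct / validate a site metadata table
#'
#' One row per site: id, centroid longitude/latitude (decimal degrees), mean
#' elevation (m), within-site elevation range (m), area (km2), plus any
#' number of additional numeric environmental columns (complete cases
#' required).
#'
#' @param df data.frame with at least the required columns
#'   (`site_id, lon, lat, mean_elev, elev_range, area`).
#' @return a validated `site_table` (data.frame subclass); environmental
#'   column names are recorded in the `env_vars` attribute.
#' @export
site_table <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(SITE_REQUIRED_COLS, names(df))
  if (length(missing_cols))
    stopf("site table missing column(s): %s", paste(missing_cols, collapse = ", "))
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) stopf("duplicate site ids in site table")
  env_vars <- setdiff(names(df), SITE_REQUIRED_COLS)
  num_cols <- c(setdiff(SITE_REQUIRED_COLS, "site_id"), env_vars)
  for (cl in num_cols) {
    df[[cl]] <- as.numeric(df[[cl]])
    if (anyNA(df[[cl]])) stopf("missing or non-numeric value in column '%s'", cl)
  }
  if (any(df$lon < -180 | df$lon > 180)) stopf("longitude out of [-180, 180]")
  if (any(df$lat < -90 | df$lat > 90)) stopf("latitude out of [-90, 90]")
  if (any(df$elev_range < 0)) stopf("elev_range must be >= 0")
  if (any(df$area <= 0)) stopf("area must be > 0")
  rownames(df) <- NULL
  structure(df, env_vars = env_vars, class = c("site_table", "data.frame"))
}

#' Read a site metadata CSV
#'
#' @param path CSV path with the columns described in [site_table()].
#' @return a validated `site_table`.
#' @export
read_sites <- function(path) {
  site_table(utils::read.csv(path, check.names = FALSE))
}

#' Align a site table to an occurrence matrix by site id
#'
#' Reorders the site table rows to match the occurrence matrix; errors if the
#' site sets differ.
#'
#' @param sites a [site_table()].
#' @param occ an [occurrence_matrix()].
#' @return the reordered `site_table`.
#' @export
align_sites <- function(sites, occ) {
  want <- rownames(occ)
  missing_sites <- setdiff(want, sites$site_id)
  if (length(missing_sites))
    stopf("site table lacks sites present in occurrence data: %s",
          paste(utils::head(missing_sites, 5L), collapse = ", "))
  extra <- setdiff(sites$site_id, want)
  if (length(extra))
    stopf("site table has sites absent from occurrence data: %s",
          paste(utils::head(extra, 5L), collapse = ", "))
  out <- sites[match(want, sites$site_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, env_vars = attr(sites, "env_vars"),
            class = c("site_table", "data.frame"))
}
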