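#' Geodesic distance matrix between site centroids (km, WGS84)
#'
#' Pairwise geodesic distances on the WGS84 ellipsoid (Karney's algorithm via
#' \pkg{geosphere}). Coincident centroids are legal (distance 0) but flagged,
#' because the logarithmic decay model cannot use zero distances.
#'
#' @param sites a [site_table()].
#' @param method `"geodesic"` (default, ellipsoidal) or `"haversine"`
#'   (spherical approximation; agrees with the geodesic to well under 1%).
#' @return a [pairwise_matrix()] of kind `"distance"`, in kilometres.
#' @export
geo_distance_matrix <- function(sites, method = c("geodesic", "haversine")) {
  method <- match.arg(method)
  p <- cbind(sites$lon, sites$lat)
  fun <- switch(method, geodesic = geosphere::distGeo,
                haversine = geosphere::distHaversine)
  m <- geosphere::distm(p, fun = fun) / 1000
  out <- pairwise_matrix(m, kind = "distance", site_ids = sites$site_id)
  zero_off <- sum(pair_vector(out) == 0)
  if (zero_off > 0)
    warnf("%d site pair(s) have coincident centroids (distance 0 km)", zero_off)
  out
}

#' PCA of the environmental variables (correlation matrix)
#'
#' Standardises each environmental variable to zero mean and unit variance
#' and runs a principal component analysis — i.e. PCA on the correlation
#' matrix, which removes the arbitrary units and collinearity of climate
#' variables. Components are retained up to a cumulative explained-variance
#' target, or a fixed count.
#'
#' @param sites a [site_table()] with >= 1 environmental column.
#' @param variance_target cumulative fraction of variance to retain
#'   (default 0.95); the smallest k reaching it is kept.
#' @param n_components optional fixed number of axes, overriding the target.
#' @return an `env_pca` list: `loadings`, `explained_fraction`, `n_retained`,
#'   `scores` (site x retained axes), `site_ids`.
#' @export
env_pca <- function(sites, variance_target = 0.95, n_components = NULL) {
  env_vars <- attr(sites, "env_vars")
  if (is.null(env_vars) || length(env_vars) == 0L)
    stopf("site table has no environmental columns")
  if (nrow(sites) < 2L) stopf("need at least 2 sites for PCA")
  x <- as.matrix(as.data.frame(sites)[, env_vars, drop = FALSE])
  const <- apply(x, 2L, stats::sd) == 0
  if (any(const)) {
    warnf("dropping constant environmental variable(s): %s",
          paste(env_vars[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    if (ncol(x) == 0L) stopf("all environmental variables are constant")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- if (!is.null(n_components)) {
    min(as.integer(n_components), length(expl))
  } else {
    which(cumsum(expl) >= variance_target - 1e-12)[1L]
  }
  structure(list(
    loadings = pc$rotation,
    explained_fraction = expl,
    n_retained = k,
    scores = pc$x[, seq_len(k), drop = FALSE],
    site_ids = sites$site_id
  ), class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("env_pca: %d axes retained, cumulative variance %.1f%%\n",
              x$n_retained, 100 * sum(x$explained_fraction[seq_len(x$n_retained)])))
  invisible(x)
}

#' Environmental distance matrix from retained PCA axes
#'
#' Unweighted Euclidean distance between sites in the space of the retained
#' principal-component scores, collapsing the environmental contrast between
#' two sites into a single variable.
#'
#' @param pca an [env_pca()] result.
#' @return a [pairwise_matrix()] of kind `"distance"`.
#' @export
env_distance_matrix <- function(pca) {
  if (!inherits(pca, "env_pca")) stopf("expected an env_pca object")
  m <- as.matrix(stats::dist(pca$scores, method = "euclidean"))
  pairwise_matrix(m, kind = "distance", site_ids = pca$site_ids)
}

#' Absolute-difference matrix of a per-site scalar
#'
#' |x_i - x_j| for a scalar site attribute. With `mean_elev` this is the
#' geographic-isolation proxy; with `elev_range` the environmental-
#' heterogeneity proxy; `area` quantifies county-size disparity.
#'
#' @param sites a [site_table()].
#' @param field one of `"mean_elev"`, `"elev_range"`, `"area"`, or any
#'   numeric column present in the table.
#' @return a [pairwise_matrix()] of kind `"distance"`.
#' @export
scalar_diff_matrix <- function(sites, field = c("mean_elev", "elev_range", "area")) {
  field <- if (length(field) > 1L) match.arg(field) else field
  if (!field %in% names(sites)) stopf("field '%s' not in site table", field)
  x <- as.numeric(sites[[field]])
  m <- abs(outer(x, x, "-"))
  pairwise_matrix(m, kind = "distance", site_ids = sites$site_id)
}
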