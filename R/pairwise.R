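#' Labelled symmetric pairwise matrix
#'
#' The common container for site-by-site similarity and distance matrices.
#' A `pairwise_matrix` is a base symmetric matrix with site ids as dimnames
#' and a `kind` attribute (`"similarity"` or `"distance"`). Similarities live
#' in \[0, 1\] with a unit diagonal; distances are non-negative with a zero
#' diagonal.
#'
#' @param values square numeric matrix, symmetric to within `tol`.
#' @param kind `"similarity"` or `"distance"`.
#' @param site_ids optional character vector of site identifiers; defaults to
#'   existing rownames, or `"s1"..."sn"`.
#' @param tol absolute tolerance for the symmetry check.
#' @return an object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, kind = c("similarity", "distance"),
                            site_ids = NULL, tol = 1e-8) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stopf("pairwise matrix must be square")
  if (any(!is.finite(values))) stopf("pairwise matrix contains non-finite values")
  if (max(abs(values - t(values))) > tol)
    stopf("matrix is asymmetric beyond tolerance %g", tol)
  if (is.null(site_ids)) site_ids <- rownames(values)
  if (is.null(site_ids)) site_ids <- paste0("s", seq_len(nrow(values)))
  site_ids <- as.character(site_ids)
  if (anyDuplicated(site_ids)) stopf("duplicate site ids in pairwise matrix")
  if (length(site_ids) != nrow(values)) stopf("site_ids length mismatch")
  if (kind == "similarity") {
    if (min(values) < -tol || max(values) > 1 + tol)
      stopf("similarity values must lie in [0, 1]")
    diag(values) <- 1
  } else {
    if (min(values) < -tol) stopf("distance values must be non-negative")
    diag(values) <- 0
  }
  values <- (values + t(values)) / 2
  dimnames(values) <- list(site_ids, site_ids)
  structure(values, kind = kind, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("pairwise_matrix (%s): %d sites, %d pairs\n",
              attr(x, "kind"), n, (n * (n - 1L)) %/% 2L))
  print(unclass(x)[seq_len(min(n, 6L)), seq_len(min(n, 6L)), drop = FALSE], ...)
  if (n > 6L) cat(sprintf("... (%d sites omitted)\n", n - 6L))
  invisible(x)
}

#' Unroll a pairwise matrix into the canonical pair vector
#'
#' Returns the n(n-1)/2 off-diagonal values in the fixed ordering used by
#' every regression and Mantel statistic in the package: pairs (i, j) with
#' i < j, enumerated row by row of the lower triangle — (1,2), (1,3), (2,3),
#' (1,4), ... Both ends of the pipeline must use this one ordering; mixing it
#' with, e.g., the [stats::dist()] ordering silently misaligns pairs.
#'
#' @param m a [pairwise_matrix()] (or plain symmetric matrix).
#' @param tol symmetry tolerance when `m` is a plain matrix.
#' @return numeric vector of length n(n-1)/2 with attributes `i` and `j`
#'   (integer site indices, i < j) and `site_ids`.
#' @export
pair_vector <- function(m, tol = 1e-8) {
  if (!inherits(m, "pairwise_matrix")) {
    m <- as.matrix(m)
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > tol)
      stopf("pair_vector needs a symmetric square matrix")
  }
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 sites for a pair vector")
  up <- upper.tri(m)
  v <- m[up]  # column-major upper triangle == row-major lower triangle, i < j
  idx <- which(up, arr.ind = TRUE)
  attr(v, "i") <- as.integer(idx[, 1L])
  attr(v, "j") <- as.integer(idx[, 2L])
  attr(v, "site_ids") <- rownames(m)
  v
}

# Rebuild a symmetric matrix from a canonical pair vector (zero/unit diagonal).
pair_unvector <- function(v, n, diag_value = 0) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

# Reindex the pair vector of m after a joint row/column permutation `perm`:
# value for pair (i, j) becomes m[perm[i], perm[j]]. Returns plain vector.
pair_vector_permuted <- function(m, perm) {
  pc <- pair_cache(nrow(m))
  m[cbind(perm[attr(pc, "i")], perm[attr(pc, "j")])]
}

# Cached (i, j) index pairs for a given n, since permutation loops reuse them.
pair_cache_env <- new.env(parent = emptyenv())
pair_cache <- function(n) {
  key <- as.character(n)
  got <- pair_cache_env[[key]]
  if (!is.null(got)) return(got)
  up <- upper.tri(matrix(0, n, n))
  idx <- which(up, arr.ind = TRUE)
  v <- structure(numeric(0), i = as.integer(idx[, 1L]), j = as.integer(idx[, 2L]))
  pair_cache_env[[key]] <- v
  v
}

#' Write / read a pairwise matrix as labelled CSV
#'
#' @param m a [pairwise_matrix()].
#' @param path file path.
#' @param kind kind to assign on read.
#' @return `read_pairwise_csv` returns a [pairwise_matrix()];
#'   `write_pairwise_csv` returns `path` invisibly.
#' @export
write_pairwise_csv <- function(m, path) {
  df <- data.frame(site_id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairwise_csv
#' @export
read_pairwise_csv <- function(path, kind = c("similarity", "distance")) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  pairwise_matrix(m, kind = match.arg(kind))
}
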