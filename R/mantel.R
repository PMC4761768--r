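#' Simple Mantel test
#'
#' Pearson correlation between the unrolled off-diagonal pair vectors of two
#' pairwise matrices, with significance from joint row/column permutation of
#' the second matrix' site labels (the only valid null for distance data,
#' since the n(n-1)/2 pairs are not independent observations). The
#' add-one-corrected p is two-sided by default; the paper-style alternative
#' tests can be requested one-sided.
#'
#' @param a,b [pairwise_matrix()] objects over the same sites, same order.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return a `mantel_result`: `r`, `p_perm`, `n_perm`, `kind = "simple"`,
#'   `alternative`, `controlled` (empty).
#' @export
mantel_simple <- function(a, b, n_perm = 1000, seed = NULL,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  check_same_sites(a, b)
  va <- as.numeric(pair_vector(a))
  vb <- as.numeric(pair_vector(b))
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stopf("constant pair vector: Mantel r undefined")
  r_obs <- stats::cor(va, vb)
  n <- nrow(a)
  bm <- unclass(b)
  perm_r <- function(perm) stats::cor(va, pair_vector_permuted(bm, perm))
  rs <- mantel_null_distribution(n, n_perm, seed, perm_r)
  structure(list(r = r_obs, p_perm = perm_pvalue(rs$values, r_obs, alternative,
                                                 exhaustive = rs$exhaustive),
                 n_perm = rs$n, kind = "simple", alternative = alternative,
                 controlled = character(0)),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation between matrices `a` and `b` after removing, by ordinary least
#' squares on the pair vectors, the linear effect of one or more conditioning
#' matrices. Significance follows the residual-permutation scheme of the
#' ecodist lineage: the residuals of `a` given the conditioning matrices are
#' folded back into a symmetric matrix and its site labels permuted, keeping
#' rows and columns coherent.
#'
#' @inheritParams mantel_simple
#' @param control a [pairwise_matrix()] or list of them to condition on.
#' @return a `mantel_result` with `kind = "partial"` and the conditioning
#'   matrix labels in `controlled`.
#' @export
mantel_partial <- function(a, b, control, n_perm = 1000, seed = NULL,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (inherits(control, "pairwise_matrix")) control <- list(control)
  check_same_sites(a, b)
  for (cm in control) check_same_sites(a, cm)
  va <- as.numeric(pair_vector(a))
  vb <- as.numeric(pair_vector(b))
  cc <- vapply(control, function(m) as.numeric(pair_vector(m)),
               numeric(length(va)))
  X <- cbind(1, cc)
  if (qr(X)$rank < ncol(X))
    stopf("conditioning matrices are collinear")
  if (qr(cbind(X, vb))$rank == qr(X)$rank)
    stopf("matrix b is perfectly explained by the conditioning matrices")
  if (qr(cbind(X, va))$rank == qr(X)$rank)
    stopf("matrix a is perfectly explained by the conditioning matrices")
  res_b <- stats::.lm.fit(X, vb)$residuals
  res_a <- stats::.lm.fit(X, va)$residuals
  r_obs <- stats::cor(res_a, res_b)
  n <- nrow(a)
  res_a_mat <- pair_unvector(res_a, n)  # residuals as a symmetric matrix
  perm_r <- function(perm) stats::cor(pair_vector_permuted(res_a_mat, perm), res_b)
  rs <- mantel_null_distribution(n, n_perm, seed, perm_r)
  labels <- names(control)
  if (is.null(labels)) labels <- paste0("C", seq_along(control))
  structure(list(r = r_obs, p_perm = perm_pvalue(rs$values, r_obs, alternative,
                                                 exhaustive = rs$exhaustive),
                 n_perm = rs$n, kind = "partial", alternative = alternative,
                 controlled = labels),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
              x$kind, x$r, x$p_perm, x$alternative, x$n_perm))
  if (length(x$controlled))
    cat("  controlling for:", paste(x$controlled, collapse = ", "), "\n")
  invisible(x)
}

# Null distribution of the permuted statistic; exhaustive for tiny n.
mantel_null_distribution <- function(n, n_perm, seed, perm_stat) {
  if (factorial(n) <= n_perm) {
    warnf("only %d distinct permutations for n = %d sites; enumerating exhaustively",
          factorial(n), n)
    perms <- all_permutations(n)
    list(values = apply(perms, 1L, perm_stat), n = nrow(perms), exhaustive = TRUE)
  } else {
    vals <- with_seed(seed, replicate(n_perm, perm_stat(sample.int(n))))
    list(values = vals, n = n_perm, exhaustive = FALSE)
  }
}

# Add-one permutation p-value (exact proportion when exhaustive).
perm_pvalue <- function(null_values, observed, alternative, exhaustive = FALSE) {
  eps <- 1e-12
  hits <- switch(alternative,
    two.sided = sum(abs(null_values) >= abs(observed) - eps),
    greater   = sum(null_values >= observed - eps),
    less      = sum(null_values <= observed + eps))
  if (exhaustive) hits / length(null_values)
  else (1 + hits) / (length(null_values) + 1)
}
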