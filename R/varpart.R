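#' Multiple regression on distance matrices (MRM)
#'
#' OLS of the response pair vector on one or more predictor pair vectors,
#' with significance from joint row/column permutation of the response
#' matrix, refitting the model each time (one-sided on R-squared). This is
#' the workhorse for variation partitioning.
#'
#' @param sim response [pairwise_matrix()] (typically a similarity matrix).
#' @param predictors a named list of predictor [pairwise_matrix()] objects.
#' @param n_perm number of permutations (0 skips the test).
#' @param seed integer seed.
#' @return an `mrm_fit`: `predictors` (labels), `coefficients` (intercept +
#'   slopes), `r2`, `p_perm`, `n_pairs`.
#' @export
mrm <- function(sim, predictors, n_perm = 1000, seed = NULL) {
  if (inherits(predictors, "pairwise_matrix")) predictors <- list(predictors)
  if (length(predictors) < 1L) stopf("need at least one predictor matrix")
  for (p in predictors) check_same_sites(sim, p)
  labels <- names(predictors)
  if (is.null(labels) || any(labels == ""))
    labels <- paste0("X", seq_along(predictors))
  y <- as.numeric(pair_vector(sim))
  X <- cbind(intercept = 1,
             vapply(predictors, function(m) as.numeric(pair_vector(m)),
                    numeric(length(y))))
  colnames(X) <- c("intercept", labels)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stopf("collinear predictor matrices (dependency involves: %s)",
          paste(qr_dependent_columns(X), collapse = ", "))
  fit <- stats::lm.fit(X, y)
  r2_obs <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  p_perm <- NA_real_
  if (n_perm > 0) {
    n <- nrow(sim)
    sm <- unclass(sim)
    Q <- qr.Q(qrX)
    perm_r2 <- function(perm) {
      yp <- pair_vector_permuted(sm, perm)
      ypc <- yp - mean(yp)
      fitted <- Q %*% crossprod(Q, yp)
      1 - sum((yp - fitted)^2) / sum(ypc^2)
    }
    if (factorial(n) <= n_perm) {
      warnf("only %d distinct permutations for n = %d sites; enumerating exhaustively",
            factorial(n), n)
      r2s <- apply(all_permutations(n), 1L, perm_r2)
      p_perm <- mean(r2s >= r2_obs - 1e-12)
    } else {
      r2s <- with_seed(seed, replicate(n_perm, perm_r2(sample.int(n))))
      p_perm <- (1 + sum(r2s >= r2_obs - 1e-12)) / (n_perm + 1)
    }
  }
  structure(list(predictors = labels, coefficients = fit$coefficients,
                 r2 = r2_obs, p_perm = p_perm, n_pairs = length(y)),
            class = "mrm_fit")
}

# Name the predictor columns involved in a rank deficiency.
qr_dependent_columns <- function(X) {
  q <- qr(X)
  colnames(X)[q$pivot[-seq_len(q$rank)]]
}

#' @export
print.mrm_fit <- function(x, ...) {
  cat(sprintf("MRM fit: R2 = %.4f over %d pairs", x$r2, x$n_pairs))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Seven-fraction variation partitioning over three distance matrices
#'
#' Partitions the R-squared of the full three-predictor MRM of the similarity
#' matrix on geographic distance (G), environmental distance (E) and
#' mean-elevation difference (A) into pure and joint Venn fractions by
#' inclusion-exclusion over the seven subset regressions. Joint fractions are
#' differences of R-squared values and can legitimately be negative (e.g.
#' under suppression); they are reported as computed, never clipped.
#'
#' @param sim response similarity [pairwise_matrix()].
#' @param g,e,a the three explanatory [pairwise_matrix()] objects.
#' @return a `varpart_result` with fractions `pure_G`, `pure_E`, `pure_A`,
#'   `joint_GE`, `joint_GA`, `joint_EA`, `joint_GEA`, plus `residual`,
#'   `total_explained` (= R2 of the full model) and the seven subset `r2`
#'   values.
#' @export
partition3 <- function(sim, g, e, a) {
  r2_of <- function(preds) mrm(sim, preds, n_perm = 0)$r2
  r2 <- c(G   = r2_of(list(G = g)),
          E   = r2_of(list(E = e)),
          A   = r2_of(list(A = a)),
          GE  = r2_of(list(G = g, E = e)),
          GA  = r2_of(list(G = g, A = a)),
          EA  = r2_of(list(E = e, A = a)),
          GEA = r2_of(list(G = g, E = e, A = a)))
  pure_G <- r2[["GEA"]] - r2[["EA"]]
  pure_E <- r2[["GEA"]] - r2[["GA"]]
  pure_A <- r2[["GEA"]] - r2[["GE"]]
  joint_GEA <- r2[["G"]] + r2[["E"]] + r2[["A"]] -
    r2[["GE"]] - r2[["GA"]] - r2[["EA"]] + r2[["GEA"]]
  joint_GE <- r2[["G"]] + r2[["E"]] - r2[["GE"]] - joint_GEA
  joint_GA <- r2[["G"]] + r2[["A"]] - r2[["GA"]] - joint_GEA
  joint_EA <- r2[["E"]] + r2[["A"]] - r2[["EA"]] - joint_GEA
  structure(list(pure_G = pure_G, pure_E = pure_E, pure_A = pure_A,
                 joint_GE = joint_GE, joint_GA = joint_GA, joint_EA = joint_EA,
                 joint_GEA = joint_GEA,
                 total_explained = r2[["GEA"]],
                 residual = 1 - r2[["GEA"]],
                 r2 = r2),
            class = "varpart_result")
}

#' @export
print.varpart_result <- function(x, ...) {
  fr <- unlist(x[c("pure_G", "pure_E", "pure_A", "joint_GE", "joint_GA",
                   "joint_EA", "joint_GEA")])
  cat("Variation partitioning (fractions of similarity variance):\n")
  for (nm in names(fr)) cat(sprintf("  %-9s %6.1f%%\n", nm, 100 * fr[[nm]]))
  cat(sprintf("  %-9s %6.1f%%\n", "residual", 100 * x$residual))
  cat(sprintf("  total explained: %.1f%%\n", 100 * x$total_explained))
  invisible(x)
}

#' Incremental R-squared of an extra distance matrix
#'
#' How much additional similarity variance an extra explanatory matrix
#' accounts for on top of a base set: `R2(base + extra) - R2(base)`.
#' Non-negative by nesting.
#'
#' @param sim response similarity [pairwise_matrix()].
#' @param base list of base predictor [pairwise_matrix()] objects.
#' @param extra the additional [pairwise_matrix()].
#' @return scalar increment in R-squared.
#' @export
incremental_r2 <- function(sim, base, extra) {
  if (inherits(base, "pairwise_matrix")) base <- list(base)
  for (m in c(base, list(extra))) check_same_sites(sim, m)
  y <- as.numeric(pair_vector(sim))
  Xb <- cbind(1, vapply(base, function(m) as.numeric(pair_vector(m)),
                        numeric(length(y))))
  Xf <- cbind(Xb, as.numeric(pair_vector(extra)))
  # lm.fit handles an extra matrix aliased with the base (Delta R2 = 0)
  r2_of <- function(X) {
    f <- stats::lm.fit(X, y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  max(r2_of(Xf) - r2_of(Xb), 0)  # clip the tiny negative round-off only
}
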