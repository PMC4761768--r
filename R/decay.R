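DECAY_FORMS <- c("linear", "logarithmic", "exponential")

#' Parametric distance-decay model
#'
#' The three classical forms for similarity y against geographic distance x
#' (km): linear `y = a x + b`, logarithmic `y = a ln(x) + b`, and exponential
#' `y = b exp(a x)`. A negative `a` means similarity decays with distance.
#' Construct directly (e.g. from published coefficients) or via
#' [fit_decay()].
#'
#' @param form one of `"linear"`, `"logarithmic"`, `"exponential"`.
#' @param a slope-like coefficient (per km; per ln km for the logarithmic
#'   form).
#' @param b intercept (similarity units), or the multiplier for the
#'   exponential form.
#' @param r2,n_pairs,n_used,s0,p_perm optional fit metadata.
#' @return a `decay_fit` object.
#' @export
decay_fit <- function(form, a, b, r2 = NA_real_, n_pairs = NA_integer_,
                      n_used = NA_integer_, s0 = NA_real_, p_perm = NA_real_) {
  form <- match.arg(form, DECAY_FORMS)
  structure(list(form = form, a = a, b = b, r2 = r2, n_pairs = n_pairs,
                 n_used = n_used, s0 = s0, p_perm = p_perm,
                 halving_distance = NA_real_),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("decay_fit [%s]: a = %.5g, b = %.4g", x$form, x$a, x$b))
  if (!is.na(x$r2)) cat(sprintf(", r2 = %.3f", x$r2))
  if (!is.na(x$n_pairs)) cat(sprintf(", n = %d", x$n_pairs))
  cat("\n")
  if (!is.na(x$s0)) cat(sprintf("  S0 = %.3g", x$s0))
  if (!is.na(x$halving_distance))
    cat(sprintf(", halving distance = %d km", round(x$halving_distance)))
  if (!is.na(x$p_perm)) cat(sprintf(", permutation p = %.4g", x$p_perm))
  cat("\n")
  invisible(x)
}

#' @export
predict.decay_fit <- function(object, x, ...) {
  switch(object$form,
    linear      = object$a * x + object$b,
    logarithmic = object$a * log(x) + object$b,
    exponential = object$b * exp(object$a * x))
}

# Transform (x, y) pairs to the scale on which each form is fit by OLS,
# dropping pairs the transform cannot use. Returns tx, ty, n_excluded.
decay_transform <- function(x, y, form) {
  keep <- switch(form,
    linear      = rep(TRUE, length(x)),
    logarithmic = x > 0,
    exponential = y > 0)
  list(tx = switch(form, logarithmic = log(x[keep]), x[keep]),
       ty = switch(form, exponential = log(y[keep]), y[keep]),
       n_excluded = sum(!keep))
}

#' Fit a distance-decay regression
#'
#' Ordinary least squares of similarity on distance on the transformed scale
#' of the chosen form: y on x (linear), y on ln x (logarithmic), ln y on x
#' (exponential, with `b` back-transformed from the intercept). R-squared is
#' reported on the transformed scale of the fit. Pairs a transform cannot use
#' (zero distances for the logarithmic form, zero similarities for the
#' exponential) are excluded and counted in `n_used` vs `n_pairs`, with a
#' message.
#'
#' @param sim similarity [pairwise_matrix()].
#' @param dist distance [pairwise_matrix()] over the same sites, same order.
#' @param form decay form, see [decay_fit()].
#' @param s0 `"max_observed"` (default: the largest off-diagonal similarity)
#'   or a fixed numeric in (0, 1]; stored on the fit and used for the halving
#'   distance.
#' @return a `decay_fit` with coefficients, `r2`, `s0` and (for decaying
#'   fits) `halving_distance`; `p_perm` is left `NA` — see
#'   [permutation_significance()].
#' @export
fit_decay <- function(sim, dist, form = c("linear", "logarithmic", "exponential"),
                      s0 = "max_observed") {
  form <- match.arg(form)
  check_same_sites(sim, dist)
  y <- as.numeric(pair_vector(sim))
  x <- as.numeric(pair_vector(dist))
  tr <- decay_transform(x, y, form)
  if (tr$n_excluded > 0)
    message(sprintf("fit_decay(%s): excluded %d unusable pair(s)",
                    form, tr$n_excluded))
  if (length(tr$tx) < 3L) stopf("fewer than 3 usable pairs for the %s fit", form)
  if (stats::sd(tr$tx) == 0) stopf("zero variance in distances; cannot fit decay")
  cf <- stats::.lm.fit(cbind(1, tr$tx), tr$ty)$coefficients
  a <- cf[2L]
  b <- if (form == "exponential") exp(cf[1L]) else cf[1L]
  fit <- decay_fit(form, a = a, b = b,
                   r2 = r_squared(tr$tx, tr$ty),
                   n_pairs = length(y), n_used = length(tr$tx),
                   s0 = initial_similarity(sim, if (is.numeric(s0)) "fixed" else s0,
                                           value = if (is.numeric(s0)) s0 else NULL))
  if (fit$a < 0)  # NA when the fitted curve never reaches S0/2
    fit$halving_distance <- tryCatch(halving_distance(fit),
                                     error = function(e) NA_real_)
  fit
}

#' Initial similarity for the halving-distance computation
#'
#' The similarity level from which the decay is halved. By default the
#' maximum observed pairwise similarity of the region (1 whenever the region
#' contains an identical pair of assemblages); alternatively a fixed value.
#'
#' @param sim similarity [pairwise_matrix()].
#' @param method `"max_observed"` or `"fixed"`.
#' @param value required when `method = "fixed"`; must lie in (0, 1].
#' @return scalar S0.
#' @export
initial_similarity <- function(sim, method = c("max_observed", "fixed"),
                               value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || value <= 0 || value > 1)
      stopf("fixed initial similarity must lie in (0, 1]")
    return(as.numeric(value))
  }
  max(pair_vector(sim))
}

#' Halving distance of a fitted decay model
#'
#' The geographic distance at which the model's predicted similarity falls to
#' half the initial similarity S0 — the package's headline turnover statistic
#' (smaller halving distance = faster turnover). Solved in closed form:
#' linear `(b - S0/2) / (-a)`; logarithmic `exp((S0/2 - b) / a)`; exponential
#' `ln(2 b / S0) / (-a)`. Full precision is returned; round for display.
#'
#' @param fit a [decay_fit()] with `a < 0`.
#' @param s0 initial similarity; defaults to the fit's stored `s0`.
#' @return halving distance in km.
#' @export
halving_distance <- function(fit, s0 = NULL) {
  if (!inherits(fit, "decay_fit")) stopf("expected a decay_fit")
  if (is.null(s0)) s0 <- fit$s0
  if (is.na(s0)) stopf("no initial similarity available; supply s0")
  if (s0 <= 0 || s0 > 1) stopf("initial similarity must lie in (0, 1]")
  if (fit$a >= 0) stopf("no decay: slope coefficient is non-negative")
  half <- s0 / 2
  hd <- switch(fit$form,
    linear      = (fit$b - half) / (-fit$a),
    logarithmic = exp((half - fit$b) / fit$a),
    exponential = log(2 * fit$b / s0) / (-fit$a))
  if (!is.finite(hd) || hd <= 0)
    stopf("half-similarity not reached at a positive distance")
  hd
}

#' Permutation significance of a distance-decay regression
#'
#' Tests whether the decay is stronger than expected when assemblages are
#' randomly reassigned to locations. Site labels of the similarity matrix are
#' permuted (rows and columns together, preserving symmetry), the regression
#' is refit each time, and the one-sided, add-one-corrected p-value is
#' `(1 + #\{r2_perm >= r2_obs\}) / (n_perm + 1)`. When fewer than `n_perm`
#' distinct permutations exist the test switches to exhaustive enumeration
#' over all n! arrangements (warning), giving an exact p.
#'
#' @inheritParams fit_decay
#' @param n_perm number of random permutations (default 1000).
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return the fitted `decay_fit` with `p_perm` filled in.
#' @export
permutation_significance <- function(sim, dist,
                                     form = c("linear", "logarithmic", "exponential"),
                                     n_perm = 1000, seed = NULL) {
  form <- match.arg(form)
  fit <- fit_decay(sim, dist, form)
  n <- nrow(sim)
  x <- as.numeric(pair_vector(dist))
  perm_r2 <- function(perm) {
    y <- pair_vector_permuted(unclass(sim), perm)
    tr <- decay_transform(x, y, form)
    if (length(tr$tx) < 3L || stats::sd(tr$tx) == 0) return(0)
    r_squared(tr$tx, tr$ty)
  }
  if (factorial(n) <= n_perm) {
    warnf("only %d distinct permutations for n = %d sites; enumerating exhaustively",
          factorial(n), n)
    perms <- all_permutations(n)
    r2s <- apply(perms, 1L, perm_r2)
    fit$p_perm <- mean(r2s >= fit$r2 - 1e-12)
  } else {
    r2s <- with_seed(seed, replicate(n_perm, perm_r2(sample.int(n))))
    fit$p_perm <- (1 + sum(r2s >= fit$r2 - 1e-12)) / (n_perm + 1)
  }
  fit
}

# Shared guard: two pairwise matrices must cover the same sites in the same order.
check_same_sites <- function(a, b) {
  if (nrow(a) != nrow(b) || !identical(rownames(a), rownames(b)))
    stopf("pairwise matrices cover different site sets or orderings")
  invisible(TRUE)
}
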