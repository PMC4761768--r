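# Internal helpers shared across modules.

#' Run code with a locally seeded RNG
#'
#' Evaluates `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so library calls never perturb user-level randomness.
#' A `NULL` seed evaluates `expr` under the current RNG state.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# All n! permutations of seq_len(n) as rows of a matrix (n small).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep.int(k, rows), matrix(setdiff(seq_len(n), k)[sub], rows))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# Squared Pearson correlation without the overhead of cor(); NA-free inputs.
r_squared <- function(x, y) {
  cx <- x - mean(x)
  cy <- y - mean(y)
  s <- sum(cx * cy)
  s * s / (sum(cx * cx) * sum(cy * cy))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
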