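# Independent oracles and fixture builders. Everything here is deliberately
# naive (set operations, normal equations, recursive enumeration) so it cannot
# share a bug with the package's vectorised implementations.

# All permutations of 1..n by recursive insertion (independent of the
# package's internal enumerator).
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  shorter <- perms_of(n - 1L)
  out <- list()
  for (p in shorter) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# Similarity by explicit set operations on species-name sets.
brute_similarity <- function(occ, index = "jaccard") {
  n <- nrow(occ)
  sp <- colnames(occ)
  sets <- lapply(seq_len(n), function(i) sp[occ[i, ] == 1])
  m <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- length(intersect(sets[[i]], sets[[j]]))
    b <- length(setdiff(sets[[i]], sets[[j]]))
    cc <- length(setdiff(sets[[j]], sets[[i]]))
    m[i, j] <- m[j, i] <- if (index == "jaccard") a / (a + b + cc)
                          else a / (a + min(b, cc))
  }
  dimnames(m) <- list(rownames(occ), rownames(occ))
  m
}

# OLS coefficients by explicit normal equations.
brute_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Unroll a symmetric matrix in the package's pair order (i < j, by j then i),
# written out longhand as a double loop.
brute_pair_vector <- function(m) {
  n <- nrow(m)
  v <- numeric(0)
  for (j in 2:n) for (i in 1:(j - 1)) v <- c(v, m[i, j])
  v
}

# Random binary occurrence matrix with non-empty sites and species.
random_occ <- function(n_sites, n_species, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_sites * n_species, 1, p), n_sites, n_species,
                dimnames = list(paste0("s", seq_len(n_sites)),
                                paste0("sp", seq_len(n_species))))
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(occurrence_matrix(m))
  }
}

# Random site table with environmental columns.
random_sites <- function(n, seed = 1, n_env = 4) {
  set.seed(seed)
  env <- matrix(rnorm(n * n_env), n, n_env,
                dimnames = list(NULL, paste0("env", seq_len(n_env))))
  site_table(data.frame(
    site_id = paste0("s", seq_len(n)),
    lon = runif(n, 95, 105), lat = runif(n, 22, 34),
    mean_elev = runif(n, 500, 4500), elev_range = runif(n, 100, 2500),
    area = runif(n, 500, 30000), env, check.names = FALSE))
}

# Random symmetric pairwise matrix.
random_pairmat <- function(n, kind = "distance", seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- if (kind == "similarity") runif(n_pairs(n)) else
    runif(n_pairs(n), 0.1, 100)
  m <- m + t(m)
  pairwise_matrix(m, kind = kind)
}

# Build a similarity pairwise matrix whose pair values follow a given decay
# curve of a distance matrix exactly.
sim_from_curve <- function(dist, fun) {
  v <- fun(pair_vector(dist))
  stopifnot(all(v >= 0 & v <= 1))
  pairwise_matrix(pair_unvector_local(v, nrow(dist), 1),
                  kind = "similarity", site_ids = rownames(dist))
}

pair_unvector_local <- function(v, n, diag_value = 0) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag_value
  m
}
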