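test_that("noiseless data on each model form is recovered exactly", {
  dist <- random_pairmat(12, "distance", seed = 1)

  sim <- sim_from_curve(dist, function(x) -0.0005 * x + 0.8)
  f <- fit_decay(sim, dist, "linear")
  expect_equal(f$a, -0.0005, tolerance = 1e-9)
  expect_equal(f$b, 0.8, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  sim <- sim_from_curve(dist, function(x) 0.9 * exp(-0.002 * x))
  f <- fit_decay(sim, dist, "exponential")
  expect_equal(f$a, -0.002, tolerance = 1e-9)
  expect_equal(f$b, 0.9, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)

  sim <- sim_from_curve(dist, function(x) -0.1 * log(x) + 0.7)
  f <- fit_decay(sim, dist, "logarithmic")
  expect_equal(f$a, -0.1, tolerance = 1e-9)
  expect_equal(f$b, 0.7, tolerance = 1e-9)
  expect_equal(f$r2, 1, tolerance = 1e-9)
})

test_that("noisy decay recovers generating coefficients within sampling error", {
  for (seed in 21:23) {
    set.seed(seed)
    n <- 33  # 528 pairs
    coords <- data.frame(site_id = paste0("s", 1:n),
                         lon = runif(n, 96, 104), lat = runif(n, 24, 32),
                         mean_elev = 1000, elev_range = 100, area = 10,
                         env1 = rnorm(n))
    dist <- suppressWarnings(geo_distance_matrix(site_table(coords)))
    x <- pair_vector(dist)
    y <- pmin(1, pmax(0, -0.0004 * x + 0.8 + rnorm(length(x), 0, 0.03)))
    sim <- pairwise_matrix(pair_unvector_local(y, n, 1), "similarity",
                           site_ids = rownames(dist))
    f <- fit_decay(sim, dist, "linear")
    se <- summary(lm(y ~ x))$coefficients[, "Std. Error"]
    expect_lt(abs(f$a - (-0.0004)), 3 * se["x"])
    expect_lt(abs(f$b - 0.8), 3 * se["(Intercept)"])
  }
})

test_that("unusable pairs are excluded with a message and small fits error", {
  n <- 6
  dm <- matrix(0, n, n); dm[upper.tri(dm)] <- c(0, 1:14)  # one zero distance
  dm <- dm + t(dm)
  dist <- pairwise_matrix(dm, "distance")
  sim <- sim_from_curve(dist, function(x) 0.9 * exp(-0.05 * x))
  expect_message(f <- fit_decay(sim, dist, "logarithmic"), "excluded 1")
  expect_equal(f$n_used, f$n_pairs - 1L)
  expect_error(fit_decay(sim[1:2, 1:2], dist[1:2, 1:2], "linear"),
               "symmetric|fewer|sites")
  flat <- pairwise_matrix(matrix(1, 4, 4) - diag(1, 4) + diag(0, 4), "distance")
  simf <- random_pairmat(4, "similarity", seed = 3)
  expect_error(fit_decay(simf, flat, "linear"), "zero variance")
})

test_that("initial similarity defaults to the observed maximum", {
  sim <- random_pairmat(9, "similarity", seed = 4)
  expect_equal(initial_similarity(sim), max(pair_vector(sim)))
  expect_equal(initial_similarity(sim, "fixed", value = 0.967), 0.967)
  expect_error(initial_similarity(sim, "fixed", value = 1.2), "\\(0, 1]")
  expect_error(initial_similarity(sim, "fixed", value = 0), "\\(0, 1]")
  m <- diag(1, 3); m[1, 2] <- m[2, 1] <- 1; m[1, 3] <- m[3, 1] <- 0.4
  m[2, 3] <- m[3, 2] <- 0.3
  expect_equal(initial_similarity(pairwise_matrix(m, "similarity")), 1)
})

test_that("halving distance inverts each model form to machine precision", {
  set.seed(5)
  for (k in 1:50) {
    form <- sample(c("linear", "logarithmic", "exponential"), 1)
    a <- -runif(1, 1e-4, 1e-2)
    b <- runif(1, 0.55, 1)
    s0 <- runif(1, 0.6, 1)
    fit <- decay_fit(form, a = a, b = b)
    hd <- tryCatch(halving_distance(fit, s0), error = function(e) NA)
    if (is.na(hd)) next
    expect_equal(predict(fit, hd), s0 / 2, tolerance = 1e-9)
  }
  expect_equal(halving_distance(decay_fit("linear", -0.5, 1), 1), 1)
})

test_that("halving distance reports degenerate configurations", {
  expect_error(halving_distance(decay_fit("linear", 0.01, 0.5), 1), "no decay")
  expect_error(halving_distance(decay_fit("linear", -0.001, 0.3), 1),
               "not reached")
  expect_error(halving_distance(decay_fit("exponential", -0.001, 0.4), 1),
               "not reached")
  expect_error(halving_distance(decay_fit("linear", -0.001, 0.8), 1.5), "\\(0, 1]")
})

test_that("published-style coefficient sets give the expected halving distances", {
  expect_equal(round(halving_distance(decay_fit("linear", -0.00063, 0.7530), 1)), 402)
  expect_equal(round(halving_distance(decay_fit("logarithmic", -0.2490, 1.9401), 1)), 325)
  expect_equal(round(halving_distance(decay_fit("exponential", -0.0019, 0.9689), 1)), 348)
})

test_that("perfect decay attains the minimum permutation p", {
  n <- 20
  sites <- random_sites(n, seed = 6)
  dist <- geo_distance_matrix(sites)
  sim <- sim_from_curve(dist, function(x) pmin(1, 0.95 * exp(-0.003 * x)))
  f <- permutation_significance(sim, dist, "exponential", n_perm = 1000, seed = 1)
  expect_equal(f$p_perm, 1 / 1001)
})

test_that("exhaustive enumeration kicks in for tiny site sets and matches an oracle", {
  n <- 5
  sites <- random_sites(n, seed = 7)
  dist <- geo_distance_matrix(sites)
  set.seed(8)
  y <- runif(n_pairs(n), 0.2, 0.9)
  sim <- pairwise_matrix(pair_unvector_local(y, n, 1), "similarity",
                         site_ids = rownames(dist))
  expect_warning(f <- permutation_significance(sim, dist, "linear", n_perm = 1000),
                 "exhaustively")
  # oracle: enumerate all 120 relabelings by hand and recompute r2
  x <- as.numeric(pair_vector(dist))
  r2_obs <- summary(lm(as.numeric(pair_vector(sim)) ~ x))$r.squared
  r2s <- vapply(perms_of(n), function(p) {
    sp <- unclass(sim)[p, p]
    summary(lm(brute_pair_vector(sp) ~ x))$r.squared
  }, numeric(1))
  expect_equal(f$p_perm, mean(r2s >= r2_obs - 1e-12))
  expect_equal(length(r2s), 120L)
})

test_that("label permutation moves rows and columns together", {
  m <- unclass(random_pairmat(8, "similarity", seed = 9))
  set.seed(10)
  p <- sample(8)
  permuted <- m[p, p]
  expect_true(isSymmetric(permuted))
  expect_false(isSymmetric(m[p, ]))  # row-only scrambling breaks symmetry
  expect_equal(betadecay:::pair_vector_permuted(m, p),
               brute_pair_vector(permuted))
})

test_that("permutation p is invariant to site relabeling", {
  n <- 5
  sites <- random_sites(n, seed = 11)
  dist <- geo_distance_matrix(sites)
  set.seed(12)
  y <- runif(n_pairs(n), 0.2, 0.9)
  sim <- pairwise_matrix(pair_unvector_local(y, n, 1), "similarity",
                         site_ids = rownames(dist))
  p1 <- suppressWarnings(permutation_significance(sim, dist, "linear"))$p_perm
  perm <- c(3, 1, 5, 2, 4)
  sim2 <- pairwise_matrix(unclass(sim)[perm, perm], "similarity")
  dist2 <- pairwise_matrix(unclass(dist)[perm, perm], "distance")
  p2 <- suppressWarnings(permutation_significance(sim2, dist2, "linear"))$p_perm
  expect_equal(p1, p2)  # exhaustive, so exactly equal
})
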