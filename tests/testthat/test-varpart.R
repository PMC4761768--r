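test_that("single-predictor MRM R2 equals the squared simple Mantel r", {
  sim <- random_pairmat(10, "similarity", seed = 1)
  g <- random_pairmat(10, "distance", seed = 2)
  r <- mantel_simple(sim, g, n_perm = 9, seed = 1)$r
  fit <- mrm(sim, list(G = g), n_perm = 0)
  expect_equal(fit$r2, r^2, tolerance = 1e-12)
})

test_that("an exact linear mix of predictors is fit perfectly", {
  g <- random_pairmat(9, "distance", seed = 3)
  e <- random_pairmat(9, "distance", seed = 4)
  y <- 0.003 * pair_vector(g) + 0.002 * pair_vector(e) + 0.05
  sim <- pairwise_matrix(pair_unvector_local(pmin(y, 1), 9, 1), "similarity")
  fit <- mrm(sim, list(G = g, E = e), n_perm = 0)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients),
               c(0.05, 0.003, 0.002), tolerance = 1e-9)
})

test_that("MRM coefficients match the normal equations on small instances", {
  for (seed in 1:3) {
    n <- 6
    sim <- random_pairmat(n, "similarity", seed = seed * 30)
    g <- random_pairmat(n, "distance", seed = seed * 30 + 1)
    e <- random_pairmat(n, "distance", seed = seed * 30 + 2)
    fit <- mrm(sim, list(G = g, E = e), n_perm = 0)
    X <- cbind(1, brute_pair_vector(g), brute_pair_vector(e))
    beta <- brute_ols(X, brute_pair_vector(sim))
    expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-10)
  }
})

test_that("collinear predictors raise an error naming the dependency", {
  sim <- random_pairmat(8, "similarity", seed = 40)
  g <- random_pairmat(8, "distance", seed = 41)
  g2 <- pairwise_matrix(3 * unclass(g), "distance")
  expect_error(mrm(sim, list(G = g, G2 = g2), n_perm = 0), "collinear.*G2")
})

test_that("R2 never decreases as predictors are added", {
  set.seed(42)
  for (k in 1:5) {
    n <- sample(7:14, 1)
    sim <- random_pairmat(n, "similarity", seed = 50 + k)
    preds <- list(G = random_pairmat(n, "distance", seed = 60 + k),
                  E = random_pairmat(n, "distance", seed = 70 + k),
                  A = random_pairmat(n, "distance", seed = 80 + k))
    r2s <- vapply(1:3, function(m) mrm(sim, preds[1:m], n_perm = 0)$r2, numeric(1))
    expect_true(all(diff(r2s) >= -1e-12))
  }
})

test_that("the seven fractions obey the Venn algebra for any inputs", {
  for (k in 1:5) {
    n <- sample(7:12, 1)
    sim <- random_pairmat(n, "similarity", seed = 100 + k)
    g <- random_pairmat(n, "distance", seed = 110 + k)
    e <- random_pairmat(n, "distance", seed = 120 + k)
    a <- random_pairmat(n, "distance", seed = 130 + k)
    vp <- partition3(sim, g, e, a)
    fr_sum <- vp$pure_G + vp$pure_E + vp$pure_A + vp$joint_GE + vp$joint_GA +
      vp$joint_EA + vp$joint_GEA
    expect_equal(fr_sum, vp$total_explained, tolerance = 1e-10)
    expect_equal(vp$residual, 1 - vp$total_explained, tolerance = 1e-12)
    # every subset R2 reconstructs from its Venn cells
    expect_equal(vp$pure_G + vp$joint_GE + vp$joint_GA + vp$joint_GEA,
                 vp$r2[["G"]], tolerance = 1e-10)
    expect_equal(vp$pure_E + vp$joint_GE + vp$joint_EA + vp$joint_GEA,
                 vp$r2[["E"]], tolerance = 1e-10)
    expect_equal(vp$pure_A + vp$joint_GA + vp$joint_EA + vp$joint_GEA,
                 vp$r2[["A"]], tolerance = 1e-10)
  }
})

test_that("a response built from one matrix loads on that pure fraction", {
  n <- 20
  g <- random_pairmat(n, "distance", seed = 140)
  e <- random_pairmat(n, "distance", seed = 141)
  a <- random_pairmat(n, "distance", seed = 142)
  y <- 1 - pair_vector(g) / (1.1 * max(g))
  sim <- pairwise_matrix(pair_unvector_local(y, n, 1), "similarity")
  vp <- partition3(sim, g, e, a)
  # exact construction: total R2 is 1 and the non-G pure fractions vanish;
  # chance correlation with E and A leaks only into the joint cells
  expect_equal(vp$total_explained, 1, tolerance = 1e-10)
  expect_equal(vp$pure_G, vp$total_explained, tolerance = 0.05)
  expect_lt(abs(vp$pure_E), 1e-10)
  expect_lt(abs(vp$pure_A), 1e-10)
})

test_that("collinear explanatory matrices shift variance into the joint fraction", {
  n <- 14
  g <- random_pairmat(n, "distance", seed = 150)
  set.seed(151)
  e_vals <- pair_vector(g) + rnorm(n_pairs(n), 0, 0.02 * sd(pair_vector(g)))
  e <- pairwise_matrix(pair_unvector_local(pmax(e_vals, 0), n, 0), "distance")
  a <- random_pairmat(n, "distance", seed = 152)
  set.seed(153)
  y_vals <- 1 - (pair_vector(g) + pair_vector(e)) / (2.2 * max(g)) +
    rnorm(n_pairs(n), 0, 0.01)
  sim <- pairwise_matrix(pair_unvector_local(pmin(pmax(y_vals, 0), 1), n, 1),
                         "similarity")
  vp <- partition3(sim, g, e, a)
  expect_gt(vp$joint_GE, 0.5)
  expect_lt(vp$pure_G, 0.1)
  expect_lt(vp$pure_E, 0.1)
})

test_that("incremental R2 is zero for a duplicate and closes the gap for the signal", {
  n <- 10
  g <- random_pairmat(n, "distance", seed = 160)
  z <- random_pairmat(n, "distance", seed = 161)
  y <- 0.002 * pair_vector(g) + 0.004 * pair_vector(z)
  sim <- pairwise_matrix(pair_unvector_local(pmin(y / max(y), 1), n, 1),
                         "similarity")
  dup <- pairwise_matrix(unclass(g) * 1, "distance")
  expect_equal(incremental_r2(sim, list(G = g), dup), 0, tolerance = 1e-10)
  r2_base <- mrm(sim, list(G = g), n_perm = 0)$r2
  expect_equal(incremental_r2(sim, list(G = g), z), 1 - r2_base, tolerance = 1e-10)
})

test_that("MRM permutation p is small for a strong geographic signal", {
  sites <- random_sites(16, seed = 170)
  g <- geo_distance_matrix(sites)
  sim <- sim_from_curve(g, function(x) pmin(1, 0.9 * exp(-0.004 * x)))
  fit <- mrm(sim, list(G = g), n_perm = 199, seed = 3)
  expect_lt(fit$p_perm, 0.05)
})
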