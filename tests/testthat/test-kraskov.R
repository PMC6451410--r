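test_that("degenerate channels give zero and saturated channels give H(X)", {
  # all categories drawn from one identical distribution
  mix0 <- gauss_mixture(matrix(0, nrow = 4, ncol = 2), sd = 1)
  d0 <- sample_mixture(mix0, 1000, seed = 31)
  expect_lt(abs(estimate_mi(d0, knn = 15)), 0.02)
  # two 1-D Gaussians 20 SDs apart: fully separated, MI = H(X) = 1 bit
  mix2 <- gauss_mixture(matrix(c(0, 20), ncol = 1), sd = 1)
  d2 <- sample_mixture(mix2, 1000, seed = 32)
  expect_equal(estimate_mi(d2, knn = 15), 1, tolerance = 0.02)
  # non-uniform input: MI = H(X) of the weighting
  p <- c(g1 = 0.8, g2 = 0.2)
  expect_equal(estimate_mi(d2, p = p, knn = 15),
    -sum(p * log2(p)),
    tolerance = 0.03
  )
})

test_that("the estimator tracks the numerical oracle within 5% on mixture fixtures", {
  for (mix in list(mix_cube_vertices(), mix_s_curve())) {
    oracle <- mi_oracle_numeric(mix)
    est <- estimate_mi(sample_mixture(mix, 1000, seed = 33), knn = 15)
    expect_lt(abs(est - oracle) / oracle, 0.05)
    expect_gt(est, oracle * 0.99) # kNN estimator biases upward here
  }
})

test_that("estimates are invariant under translation and positive scaling", {
  mix <- mix_cube_vertices()
  d <- sample_mixture(mix, 300, seed = 34)
  base <- estimate_mi(d, knn = 10)
  d2 <- d
  for (cc in c("R_1", "R_2", "R_3")) d2[[cc]] <- 5.5 + 3.2 * d2[[cc]]
  expect_equal(estimate_mi(d2, knn = 10), base, tolerance = 1e-12)
})

test_that("estimates respect 0 <= MI <= H(X) on surrogate channels", {
  set.seed(35)
  configs <- list(
    list(T_min = 30, spec = surrogate_spec(cell_cv = 0.3, mu0 = 0.03)),
    list(T_min = 60, spec = surrogate_spec(cell_cv = 1, mu0 = 0.3)),
    list(T_min = 20, spec = surrogate_spec(cell_cv = 0, mu0 = 0.01))
  )
  for (cf in configs) {
    d <- generate_dataset(all_sequences(2), cf$T_min, cf$spec, M = 250,
      seed = sample.int(1e6, 1)
    )
    mi <- estimate_mi(d, knn = 15)
    expect_gte(mi, 0)
    expect_lte(mi, 2 + 0.05)
  }
})

test_that("projections never beat the joint MI and constants carry nothing", {
  d <- generate_dataset(all_sequences(2), 50,
    surrogate_spec(cell_cv = 0.3, mu0 = 0.03),
    M = 500, seed = 36
  )
  joint <- estimate_mi(d, knn = 15)
  for (cc in c("R_1", "R_2")) {
    expect_lte(marginal_mi(d, cc, knn = 15), joint + 0.05)
  }
  dconst <- d
  dconst$R_2 <- 1 # constant coordinate
  expect_lt(marginal_mi(dconst, "R_2", knn = 15), 0.02)
})

test_that("truncation pools suffixes into a shorter dataset", {
  d <- generate_dataset(all_sequences(3), 30, surrogate_spec(), M = 50, seed = 37)
  d2 <- truncate_dataset(d, 2)
  expect_setequal(unique(d2$sequence), all_sequences(2))
  expect_identical(names(d2), c("sequence", "cell_id", "R_1", "R_2"))
  expect_identical(sum(d2$sequence == "00"), 100L) # two suffixes pooled
})

test_that("invalid datasets are rejected", {
  d <- generate_dataset(all_sequences(2), 60, surrogate_spec(), M = 10, seed = 38)
  expect_error(estimate_mi(d, knn = 15), "knn")
  bad <- d
  bad$R_1[1] <- NaN
  expect_error(estimate_mi(bad, knn = 3), "finite")
  expect_error(estimate_mi(d, p = c(2, -1, 0, 0), knn = 3), "sum to 1|non-negative")
  expect_error(estimate_mi(dplyr::select(d, -R_1, -R_2), knn = 3), "R_1")
})
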