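test_that("the hard noise-free limit reduces to the deterministic transcoding map", {
  spec <- hard_spec()
  # T > tau: every pulse transmitted, responses exactly R_max * bits
  d <- generate_dataset(c("101", "111"), T_min = 60, spec = spec, M = 4, seed = 1)
  for (s in c("101", "111")) {
    bits <- as.integer(strsplit(s, "")[[1]])
    rows <- as.matrix(d[d$sequence == s, c("R_1", "R_2", "R_3")])
    expect_true(all(rows == matrix(bits * spec$R_max, 4, 3, byrow = TRUE)))
  }
  # T = 30 (k = 1): responses follow transcode(seq, 1)
  d30 <- generate_dataset(all_sequences(3), T_min = 30, spec = spec, M = 2, seed = 2)
  for (s in all_sequences(3)) {
    bits <- as.integer(strsplit(transcode(s, 1), "")[[1]])
    rows <- as.matrix(d30[d30$sequence == s, c("R_1", "R_2", "R_3")])
    expect_true(all(rows == matrix(bits * spec$R_max, 2, 3, byrow = TRUE)))
  }
})

test_that("hard-limit datasets reproduce the exact partition MI", {
  d <- generate_dataset(all_sequences(3), T_min = 30, spec = hard_spec(), M = 300, seed = 3)
  part <- enumerate_groups(3, 1)
  exact <- exact_mi_partition(part, scheme = "equal-all")$MI
  expect_equal(estimate_mi(d, knn = 15), exact, tolerance = 0.05 / exact)
})

test_that("per-cell gain induces within-cell correlation and bimodal responses", {
  spec <- surrogate_spec(miss_width = 0, cell_cv = 0.4, mu0 = 0.01)
  d <- generate_dataset("11", T_min = 60, spec = spec, M = 2000, seed = 4)
  expect_gt(stats::cor(d$R_1, d$R_2), 0.5)
  spec0 <- surrogate_spec(miss_width = 0, cell_cv = 0, mu0 = 0.5, sigma0 = 0.3)
  d0 <- generate_dataset("11", T_min = 60, spec = spec0, M = 2000, seed = 5)
  expect_lt(abs(stats::cor(d0$R_1, d0$R_2)), 0.1)
  # marginal of R_2 across '10' and '11' inputs is bimodal: low mode near the
  # additive floor, high mode near R_max
  dm <- generate_dataset(c("10", "11"), T_min = 60,
    spec = surrogate_spec(cell_cv = 0.1, mu0 = 0.03), M = 1000, seed = 6
  )
  lo <- mean(dm$R_2 < 0.25 * 2.65e9)
  hi <- mean(dm$R_2 > 0.5 * 2.65e9)
  expect_gt(lo, 0.3)
  expect_gt(hi, 0.3)
  expect_gt(lo + hi, 0.95)
})

test_that("fraction responding is a step at tau in the hard limit and matches the logistic law", {
  T_grid <- c(40, 48, 51, 52, 56, 60, 70)
  fr0 <- fraction_responding_surrogate(T_grid, hard_spec(), M = 50, seed = 7)
  expect_equal(fr0$fraction, as.numeric(T_grid >= 51.5))
  # soft boundary: empirical fraction within a binomial CI of the closed form
  spec <- surrogate_spec(miss_width = 5, cell_cv = 0, mu0 = 0)
  fr <- fraction_responding_surrogate(T_grid, spec, M = 2000, seed = 8)
  se <- sqrt(fr$p_transmit * (1 - fr$p_transmit) / fr$n_cells)
  expect_true(all(abs(fr$fraction - fr$p_transmit) < 4 * se + 1e-9))
  # strong cell noise keeps the curve away from 0 and 1
  spec_noisy <- surrogate_spec(miss_width = 5, cell_cv = 1, mu0 = 0.03)
  frn <- fraction_responding_surrogate(c(40, 60, 70), spec_noisy, M = 2000, seed = 9)
  expect_true(all(frn$fraction > 0.02 & frn$fraction < 0.98))
})
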