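test_that("resting model is silent and simulations are reproducible", {
  p <- mapk_params()
  prot <- protocol_spec("00", T_min = 40)
  traj <- simulate_mapk(p, prot, dt_out_s = 6)
  R <- integrated_response(traj, 40, 2)
  R_max <- 2.65e9
  expect_true(all(R < 0.01 * R_max))
  # state fractions stay in [0, 1] (conservation of each pool)
  states <- as.matrix(traj[, c("u", "s", "q", "r", "m", "e")])
  expect_true(all(states >= -1e-9 & states <= 1 + 1e-9))
  traj2 <- simulate_mapk(p, prot, dt_out_s = 6)
  expect_equal(traj$ERKpp, traj2$ERKpp, tolerance = 1e-10)
})

test_that("a single saturating pulse gives the calibrated reference response", {
  p <- mapk_params()
  traj <- simulate_mapk(p, protocol_spec("1", T_min = 90), t_end_min = 120, dt_out_s = 6)
  e <- traj$ERKpp
  tm <- traj$time_s / 60
  dur <- diff(range(tm[e > max(e) / 2]))
  expect_gt(dur, 20) # an ERK pulse of roughly half an hour
  expect_lt(dur, 35)
  R_max <- integrated_response(traj, 90, 1)
  expect_equal(R_max, 2.65e9, tolerance = 0.05)
  expect_equal(single_pulse_response(p, dt_out_s = 6), R_max, tolerance = 1e-6)
  # state fractions bounded during the response too
  states <- as.matrix(traj[, c("u", "s", "q", "r", "m", "e")])
  expect_true(all(states >= -1e-9 & states <= 1 + 1e-9))
})

test_that("the dose response is near-digital", {
  p <- mapk_params()
  ar <- amplitude_response(p, doses = c(0, 3, 10, 30, 100))
  expect_equal(ar$R_1[ar$dose == 0], 0)
  expect_lt(ar$R_rel[ar$dose == 3], 0.1)
  expect_true(all(ar$R_rel[ar$dose >= 10] > 0.7))
  # four-pulse protocol with amplitudes 3, 100, 10, 30 at T = 60:
  # no response to the first (sub-threshold) pulse, full responses after
  prot <- protocol_spec("1111", T_min = 60, doses = c(3, 100, 10, 30))
  traj <- simulate_mapk(p, prot, dt_out_s = 6)
  R <- integrated_response(traj, 60, 4)
  R_max <- 2.65e9
  expect_lt(R[1], 0.1 * R_max)
  expect_true(all(R[2:4] > 0.6 * R_max))
})

test_that("the second-pulse response recovers with the inter-pulse interval", {
  p <- mapk_params()
  ratio <- vapply(c(40, 45, 51.5, 60, 70, 80), function(T_min) {
    traj <- simulate_mapk(p, protocol_spec("11", T_min = T_min), dt_out_s = 6)
    R <- integrated_response(traj, T_min, 2)
    R[2] / R[1]
  }, numeric(1))
  expect_lt(ratio[1], 0.1) # T = 40: essentially no second response
  expect_lt(ratio[2], 0.2) # T = 45 still well below half
  expect_equal(ratio[3], 0.5, tolerance = 0.15) # half response near tau
  expect_gt(ratio[4], 0.6) # T = 60: substantial recovery
  expect_lt(ratio[4], 0.95)
  expect_true(all(diff(ratio) > 0)) # monotone recovery
})

test_that("the relaxation time is 51.5 minutes by bisection", {
  tau <- measure_relaxation_time(mapk_params())
  expect_equal(tau, 51.5, tolerance = 1 / 51.5)
})

test_that("constant EGF yields oscillations only in an intermediate dose window", {
  p <- mapk_params()
  expect_false(oscillates(p, 1)) # sub-threshold: silent
  expect_true(oscillates(p, 10)) # intermediate window: relaxation oscillations
  expect_true(oscillates(p, 15))
  # high dose: oscillations give way to a sustained (non-silent) response
  expect_false(oscillates(p, 100))
  traj <- simulate_mapk(p, 100, t_end_min = 1200, dt_out_s = 60)
  expect_gt(mean(traj$e[traj$time_s > 600 * 60]), 0.1)
})

test_that("weakening the ERK->SOS feedback shortens tau and kills oscillations", {
  p <- mapk_params()
  scan <- scan_feedback_strength(p, scale_grid = c(1, 0.5, 0.1))
  expect_equal(scan$tau_min[1], measure_relaxation_time(p), tolerance = 0.01)
  measured <- scan$tau_min[!is.na(scan$tau_min)]
  expect_true(all(diff(measured) <= 0.2)) # nonincreasing as feedback weakens
  expect_true(scan$oscillates[1])
  expect_false(scan$oscillates[3])
})

test_that("integrated responses validate their window coverage", {
  p <- mapk_params()
  traj <- simulate_mapk(p, protocol_spec("1", T_min = 40), t_end_min = 50, dt_out_s = 6)
  expect_error(integrated_response(traj, 40, 3), "cover")
  expect_equal(length(integrated_response(traj, 25, 2)), 2L)
})

test_that("parameter tables round-trip through CSV", {
  p <- mapk_params()
  path <- tempfile(fileext = ".csv")
  write_params(p, path)
  p2 <- read_params(path)
  expect_equal(p2$value, p$value)
  expect_equal(p2$cell_variable, p$cell_variable)
  traj <- simulate_mapk(p, protocol_spec("1", T_min = 60), t_end_min = 60, dt_out_s = 30)
  tpath <- tempfile(fileext = ".tsv")
  write_trajectory(traj, tpath)
  back <- utils::read.delim(tpath)
  expect_equal(back$ERKpp_molecules, traj$ERKpp)
  unlink(c(path, tpath))
})
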