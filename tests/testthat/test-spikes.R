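# Analytic piecewise-linear spike: rise at 100 mV/ms from -50 to +40,
# fall at -50 mV/ms to -60, recovery to -50. Sampled at 250 kHz.
make_triangle_spike <- function(dt = 4e-6) {
  dtms <- dt * 1000
  base <- rep(-50, round(0.002 / dt))
  rise <- seq(-50, 40, by = 100 * dtms)
  fall <- seq(40, -60, by = -50 * dtms)
  rec <- seq(-60, -50, by = 5 * dtms)
  tail <- rep(-50, round(0.002 / dt))
  trace(c(base, rise, fall, rec, tail), dt, "mV", "membrane_voltage")
}

test_that("features of an analytic spike match their constructed values", {
  tr <- make_triangle_spike()
  win <- c(0, length(tr$samples) * tr$dt)
  det <- detect_aps(tr, win, onset_blank = 0)
  expect_identical(nrow(det), 1L)
  f <- ap_features(tr, det, win)
  expect_equal(f$threshold_V, -50, tolerance = 0.05)
  expect_equal(f$peak_V, 40, tolerance = 0.01)
  expect_equal(f$amplitude, 90, tolerance = 0.05)
  # half level -5 mV: 45/100 ms left on the rise, 45/50 ms down the fall
  expect_equal(f$half_width, 45 / 100 + 45 / 50, tolerance = 0.01)
  expect_equal(f$ahp_V, -60, tolerance = 0.01)
  expect_equal(f$ahp_amplitude, 10, tolerance = 0.05)
})

test_that("detection equals the brute-force oracle on simulated sweeps", {
  set.seed(21)
  for (rep in 1:10) {
    p <- neuron_params(g_na = runif(1, 2200, 2600),
      g_kdr = runif(1, 600, 800), g_adapt = runif(1, 0.1, 0.6),
      noise_sd = runif(1, 0.05, 0.3))
    sim <- quick_cc(p, levels = round(runif(1, 60, 140)), seed = 100 + rep)
    tr <- sim$series$sweeps[[1]]
    win <- c(0.05, 0.55)
    det <- detect_aps(tr, win)
    orc <- oracle_detect_aps(tr$samples, tr$dt, win)
    expect_identical(nrow(det), nrow(orc))
    if (nrow(det)) {
      expect_identical(det$threshold_index, as.integer(orc[, 1]))
      expect_identical(det$peak_index, as.integer(orc[, 2]))
    }
  }
})

test_that("onset-coincident and out-of-window spikes are excluded", {
  p <- neuron_params(noise_sd = 0.1)
  sim <- quick_cc(p, levels = 120, seed = 3)
  tr <- sim$series$sweeps[[1]]
  st <- sim$truth$spike_times[[1]]
  # move the window start onto the first spike: it falls inside the
  # blanking interval and must be dropped
  w2 <- c(st[1] - 0.001, 0.55)
  det2 <- detect_aps(tr, w2)
  expect_equal(nrow(det2),
    sum(st >= w2[1] + 0.005 & st <= 0.55), tolerance = 0)
  # spikes before the window start are excluded as spontaneous
  w3 <- c(st[2] + 0.001, 0.55)
  expect_true(all(detect_aps(tr, w3)$threshold_time > st[2]))
  expect_error(detect_aps(tr, c(0.1, 5)), "window")
})

test_that("detection and time features are offset-invariant; voltages shift", {
  p <- neuron_params(noise_sd = 0.2)
  sim <- quick_cc(p, levels = 100, seed = 8)
  tr <- sim$series$sweeps[[1]]
  tr10 <- tr
  tr10$samples <- tr$samples - 10
  win <- c(0.05, 0.55)
  d1 <- detect_aps(tr, win)
  d2 <- detect_aps(tr10, win)
  expect_identical(d1, d2)
  f1 <- ap_features(tr, d1, win)
  f2 <- ap_features(tr10, d2, win)
  expect_equal(f2$threshold_V, f1$threshold_V - 10, tolerance = 1e-9)
  expect_equal(f2$peak_V, f1$peak_V - 10, tolerance = 1e-9)
  expect_equal(f2$amplitude, f1$amplitude, tolerance = 1e-9)
  expect_equal(f2$half_width, f1$half_width, tolerance = 1e-9)
  expect_equal(f2$ahp_delay, f1$ahp_delay, tolerance = 1e-9)
})

test_that("rheobase analysis finds the first spiking level or reports none", {
  p <- neuron_params(noise_sd = 0.2)
  proto <- step_protocol(0, 0.1, 1.1, seq(0, 120, 10))
  sim <- simulate_current_clamp(p, proto, seed = 2)
  ex <- rheobase_analysis(sim$series)
  truth_first <- proto$step_levels[which(sim$truth$spike_counts > 0)[1]]
  expect_equal(ex$rheobase, truth_first)
  expect_true(all(ex$io_curve$n_ap[ex$io_curve$injection < ex$rheobase] == 0))
  expect_false(is.null(ex$first_ap))
  # all-subthreshold family
  sub <- simulate_current_clamp(p, step_protocol(0, 0.05, 0.55, c(10, 20, 30)),
    sweep_duration = 0.7, seed = 2)
  exs <- rheobase_analysis(sub$series)
  expect_true(is.na(exs$rheobase))
  expect_null(exs$first_ap)
  # 5 pA increments accepted
  s5 <- simulate_current_clamp(p, step_protocol(0, 0.05, 0.55, seq(60, 80, 5)),
    sweep_duration = 0.7, seed = 2)
  expect_s3_class(rheobase_analysis(s5$series), "pk_excitability")
})

test_that("io curve is monotone in injection and matches ground truth", {
  p <- neuron_params(noise_sd = 0.2)
  proto <- step_protocol(0, 0.1, 1.1, seq(0, 120, 20))
  sim <- simulate_current_clamp(p, proto, seed = 6)
  ex <- rheobase_analysis(sim$series)
  expect_true(all(diff(ex$io_curve$n_ap) >= 0))
  for (i in seq_along(proto$step_levels)) {
    b <- truth_count_bounds(sim$truth, i, 0.1, 1.1)
    expect_gte(ex$io_curve$n_ap[i], b["lower"])
    expect_lte(ex$io_curve$n_ap[i], b["upper"])
  }
})

test_that("held-potential io curve flags baseline drift", {
  p <- neuron_params(noise_sd = 0.1)
  hold <- holding_current_for(p, -70)
  proto <- step_protocol(hold, 0.1, 1.1, c(40, 80))
  sim <- simulate_current_clamp(p, proto, seed = 4)
  io <- io_curve_from_held(sim$series, held_V = -70)
  expect_true(all(io$included))
  b <- truth_count_bounds(sim$truth, 2, 0.1, 1.1)
  expect_gte(io$n_ap[io$injection == 80], b["lower"])
  expect_lte(io$n_ap[io$injection == 80], b["upper"])
  # a target 10 mV away flags every sweep
  drift <- io_curve_from_held(sim$series, held_V = -60)
  expect_true(all(!drift$included))
  expect_true(all(is.na(drift$n_ap)))
})

test_that("accommodation index follows its defining arithmetic", {
  expect_equal(accommodation_index(seq(0, 0.9, 0.1)), 1.0, tolerance = 1e-12)
  expect_equal(accommodation_index(c(0, 0.01, 0.03, 0.07, 0.15, 0.31)), 16.0)
  expect_true(is.na(accommodation_index(c(0, 0.1, 0.2, 0.3, 0.4))))
  expect_equal(
    accommodation_index(c(0, 0.01, 0.03, 0.07, 0.15, 0.31),
      direction = "first_over_last"), 1 / 16)
})

test_that("accommodation index rises with the adaptation conductance", {
  ga <- c(0.1, 0.3, 0.8)
  ai <- vapply(ga, function(g) {
    p <- neuron_params(g_adapt = g, noise_sd = 0)
    sim <- simulate_current_clamp(p, step_protocol(0, 0.1, 1.1, 100), seed = 1)
    accommodation_index(sim$truth$spike_times[[1]])
  }, numeric(1))
  expect_identical(order(ai), seq_along(ai))
})
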