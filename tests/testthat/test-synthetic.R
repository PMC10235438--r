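test_that("identical seeds give bit-identical generator output", {
  p <- neuron_params()
  proto <- step_protocol(0, 0.05, 0.25, c(40, 80))
  a <- simulate_current_clamp(p, proto, sweep_duration = 0.3, seed = 5)
  b <- simulate_current_clamp(p, proto, sweep_duration = 0.3, seed = 5)
  expect_identical(a$series$sweeps[[1]]$samples, b$series$sweeps[[1]]$samples)
  protoV <- step_protocol(-60, 0.05, 0.55, seq(-60, -130, -10))
  va <- simulate_voltage_clamp(p, protoV, seed = 5)
  vb <- simulate_voltage_clamp(p, protoV, seed = 5)
  expect_identical(va$series$sweeps[[3]]$samples, vb$series$sweeps[[3]]$samples)
  ma <- simulate_mepsc(rate = 1, duration = 20, seed = 5)
  mb <- simulate_mepsc(rate = 1, duration = 20, seed = 5)
  expect_identical(ma$trace$samples, mb$trace$samples)
  expect_identical(ma$truth, mb$truth)
  ca <- simulate_calcium_field(seed = 5, duration = 120,
    event_times = c(30, 80))
  cb <- simulate_calcium_field(seed = 5, duration = 120,
    event_times = c(30, 80))
  expect_identical(ca$rois$traces[[7]]$samples, cb$rois$traces[[7]]$samples)
  ia <- simulate_cell_image(noise_sd = 5, seed = 5)
  ib <- simulate_cell_image(noise_sd = 5, seed = 5)
  expect_identical(ia$image, ib$image)
  ta <- simulate_ct_table(seed = 5)
  tb <- simulate_ct_table(seed = 5)
  expect_identical(ta$ct, tb$ct)
})

test_that("passive limit obeys charge balance: steady dV = dI / g_leak", {
  p <- neuron_params(g_na = 0, g_kdr = 0, g_kir = 0, g_hcn = 0, g_atype = 0,
    g_adapt = 0, g_leak = 5, e_leak = -70, noise_sd = 0)
  proto <- step_protocol(0, 0.05, 0.75, c(-50, -20, 20))
  sim <- simulate_current_clamp(p, proto, sweep_duration = 0.8)
  for (i in 1:3) {
    v <- sim$series$sweeps[[i]]$samples
    n <- length(v)
    steady <- v[round(0.74 / 2e-5)]   # end of 700 ms step, fully settled
    expect_equal(steady - (-70), proto$step_levels[i] / 5, tolerance = 1e-6)
  }
  expect_equal(sim$truth$resting_V, -70, tolerance = 1e-9)
})

test_that("model rests at its zero-current fixed point within 0.5 mV", {
  p <- neuron_params(noise_sd = 0)
  sim <- quick_cc(p, levels = c(0, 60))
  rv <- resting_potential(sim$series$sweeps[[1]], c(0, 0.05))
  expect_lt(abs(rv - true_resting_potential(p)), 0.5)
})

test_that("spiking conductances off gives zero spikes for any step", {
  # with 5 nS leak even a 200 pA step stays below 0 mV, so zero crossings
  # can only come from spikes
  p <- neuron_params(g_na = 0, g_kdr = 0, g_leak = 5, noise_sd = 0)
  sim <- quick_cc(p, levels = c(40, 120, 200))
  expect_identical(unname(sim$truth$spike_counts), c(0L, 0L, 0L))
  for (sw in sim$series$sweeps) {
    expect_identical(nrow(detect_aps(sw, c(0.05, 0.55))), 0L)
  }
})

test_that("too coarse an integration step is refused with dt in the message", {
  p <- neuron_params()
  expect_error(
    simulate_current_clamp(p, step_protocol(0, 0.05, 0.25, 50), dt = 1e-4),
    "dt")
})

test_that("voltage-clamp generator honors blockers and degenerate params", {
  # pure leak: I-V exactly linear with slope g_leak, instantaneous == steady
  p0 <- neuron_params(g_kir = 0, g_hcn = 0, g_atype = 0, noise_sd = 0)
  protoV <- step_protocol(-60, 0.05, 0.55, seq(-60, -130, -10))
  sv <- simulate_voltage_clamp(p0, protoV, noise_sd = 0)
  iv <- measure_step_currents(sv$series)
  expect_equal(nrow(iv), 8)
  # the instantaneous window starts right after the detected transient end,
  # so a sub-pA exponential tail remains even noise-free
  expect_lt(max(abs(iv$i_diff)), 1)
  expect_equal(as.numeric(slope_conductance(iv, "instantaneous", c(-130, -60))),
    p0$g_leak, tolerance = 0.01)
  # no HCN: steady equals instantaneous in the hyperpolarized range
  p1 <- neuron_params(g_hcn = 0)
  sv1 <- simulate_voltage_clamp(p1, protoV, noise_sd = 1, seed = 2)
  iv1 <- measure_step_currents(sv1$series)
  sel <- iv1$v_command <= -110
  expect_lt(max(abs(iv1$i_diff[sel])), 1.5)  # within noise
  expect_error(simulate_voltage_clamp(p1, protoV, blockers = "tea"),
    "unknown blocker")
})

test_that("mEPSC generator: Poisson counts, closed-form peaks, 200-event rule", {
  ms <- simulate_mepsc(rate = 0.5, duration = 600, seed = 3)
  n <- nrow(ms$truth)
  expect_lt(abs(n - 300), 3 * sqrt(300))
  expect_false(attr(ms$truth, "short_duration"))
  # noise-free isolated events peak exactly at their drawn amplitude
  m0 <- simulate_mepsc(rate = 0.05, duration = 100, noise_sd = 0, seed = 4)
  iso <- which(c(Inf, diff(m0$truth$time)) > 0.1 &
    c(diff(m0$truth$time), Inf) > 0.1)
  expect_gt(length(iso), 0)
  expect_equal(-min(m0$trace$samples), max(m0$truth$amplitude),
    tolerance = 0.01)
  expect_error(simulate_mepsc(rate = 0, duration = 10), "rate")
  expect_error(simulate_mepsc(rate = 1, tau_rise = 6, tau_decay = 5),
    "tau_rise")
  short <- simulate_mepsc(rate = 0.01, duration = 10, seed = 1)
  expect_true(attr(short$truth, "short_duration"))
})

test_that("calcium field generator enforces its preconditions and labels", {
  expect_error(simulate_calcium_field(n_rois = 5), "15..30")
  expect_error(simulate_calcium_field(event_times = c(10, 12)), "separated")
  sub <- simulate_calcium_field(event_amp = 0.05, seed = 2)
  expect_true(all(!sub$truth$supra_criterion))
  sup <- simulate_calcium_field(event_amp = 0.3, seed = 2)
  expect_true(all(sup$truth$supra_criterion))
  expect_equal(sup$truth$frequency_per_min,
    length(sup$truth$event_times) / 10)
})

test_that("cell image generator produces the planted ratio and errors", {
  im <- simulate_cell_image(nuc_intensity = 200, cyto_intensity = 100,
    noise_sd = 0)
  expect_equal(im$truth$ratio, 2)
  expect_error(simulate_cell_image(nucleus_radius = -1), "positive")
  expect_error(simulate_cell_image(nucleus_radius = 30, soma_radius = 20),
    "smaller")
})
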