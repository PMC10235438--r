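protoV <- step_protocol(-60, 0.05, 1.05, seq(-60, -130, -10))
protoA <- step_protocol(-100, 0.05, 0.55, seq(-60, 35, 5))

test_that("slope fits are exact on exact lines and offset-immune", {
  iv <- tibble::tibble(v_command = seq(-130, -60, 10))
  iv$i_inst <- 2 * (iv$v_command + 90)
  iv$i_ss <- iv$i_inst
  iv$i_diff <- iv$i_ss - iv$i_inst
  expect_equal(as.numeric(slope_conductance(iv, "instantaneous", c(-130, -60))),
    2, tolerance = 1e-12)
  iv2 <- iv
  iv2$i_inst <- iv$i_inst + 137.5
  expect_equal(as.numeric(slope_conductance(iv2, "instantaneous", c(-130, -60))),
    as.numeric(slope_conductance(iv, "instantaneous", c(-130, -60))),
    tolerance = 1e-12)
  expect_error(slope_conductance(iv, "steady", c(-65, -60)), "at least 2")
  # pure leak: Kir contrast is exactly zero
  iv$i_diff <- 0 * iv$i_diff
  expect_equal(as.numeric(kir_conductance(iv)), 0, tolerance = 1e-12)
})

test_that("window placement: leak-only family has instantaneous == steady", {
  p <- neuron_params(g_kir = 0, g_hcn = 0, g_atype = 0)
  sv <- simulate_voltage_clamp(p, protoV, noise_sd = 0)
  iv <- measure_step_currents(sv$series)
  expect_equal(iv$i_inst, iv$i_ss, tolerance = 0.01)
  expect_true(max(abs(iv$i_inst - iv$i_ss)) < 1)  # sub-pA transient tail
  expect_false(any(iv$flagged))
})

test_that("HCN produces a growing slow component with hyperpolarization", {
  p <- neuron_params(g_kir = 0, g_atype = 0)
  sv <- simulate_voltage_clamp(p, protoV, noise_sd = 0)
  iv <- measure_step_currents(sv$series)
  sel <- order(iv$v_command)                   # -130 first
  d <- iv$i_diff[sel][iv$v_command[sel] <= -90]
  expect_true(all(d < 0))                      # inward slow current
  expect_true(all(diff(abs(d)) < 0))           # magnitude grows with hyperpol.
})

test_that("Kir estimate ignores HCN and vice versa (cross-talk control)", {
  est <- function(g_kir, g_hcn, seed) {
    p <- neuron_params(g_kir = g_kir, g_hcn = g_hcn, g_atype = 0)
    iv <- measure_step_currents(
      simulate_voltage_clamp(p, protoV, seed = seed)$series)
    c(kir = as.numeric(kir_conductance(iv)),
      hcn = as.numeric(hcn_conductance(iv)))
  }
  e0 <- est(3, 1.5, 1)
  e_hcn2 <- est(3, 3, 1)
  e_kir2 <- est(6, 1.5, 1)
  expect_lt(abs(e_hcn2["kir"] - e0["kir"]) / e0["kir"], 0.05)
  expect_lt(abs(e_kir2["hcn"] - e0["hcn"]) / e0["hcn"], 0.05)
  # blocked Kir with HCN present leaves the instantaneous contrast at zero
  p0 <- neuron_params(g_kir = 0, g_atype = 0)
  iv0 <- measure_step_currents(
    simulate_voltage_clamp(p0, protoV, seed = 2)$series)
  expect_lt(abs(as.numeric(kir_conductance(iv0))), 0.3)
  p1 <- neuron_params(g_hcn = 0, g_atype = 0)
  iv1 <- measure_step_currents(
    simulate_voltage_clamp(p1, protoV, seed = 3)$series)
  expect_lt(abs(as.numeric(hcn_conductance(iv1))), 0.3)
})

test_that("A-type subtraction recovers the model slope and flags late peaks", {
  p <- neuron_params()
  ctrl <- simulate_voltage_clamp(p, protoA, seed = 4)
  blk <- simulate_voltage_clamp(p, protoA, blockers = "atype_blocker",
    seed = 5)
  g <- atype_conductance(ctrl$series, blk$series)
  expect_equal(as.numeric(g), ctrl$truth$g_atype, tolerance = 0.05)
  peaks <- attr(g, "peaks")
  infit <- peaks[peaks$v_command >= -20, ]
  expect_true(all(infit$peak_ms >= 3 & infit$peak_ms <= 13))
  # identical families: difference is zero
  g0 <- atype_conductance(ctrl$series, ctrl$series)
  expect_equal(as.numeric(g0), 0, tolerance = 1e-9)
  # slow A-type kinetics push the peak outside 3-13 ms and get flagged
  pslow <- neuron_params(atype_tau_act = 10, atype_tau_inact = 120)
  cs <- simulate_voltage_clamp(pslow, protoA, seed = 6)
  bs <- simulate_voltage_clamp(pslow, protoA, blockers = "atype_blocker",
    seed = 7)
  expect_error(atype_conductance(cs$series, bs$series), "unflagged")
  # protocol mismatch is refused
  other <- simulate_voltage_clamp(p,
    step_protocol(-100, 0.06, 0.56, seq(-60, 35, 5)), seed = 8)
  expect_error(atype_conductance(ctrl$series, other$series), "mismatch")
})

test_that("conductance_set summarizes all three estimates with diagnostics", {
  p <- neuron_params()
  hyper <- simulate_voltage_clamp(p, protoV, seed = 9)$series
  ctrl <- simulate_voltage_clamp(p, protoA, seed = 10)$series
  blk <- simulate_voltage_clamp(p, protoA, blockers = "atype_blocker",
    seed = 11)$series
  cs <- conductance_set(hyper, ctrl, blk)
  expect_identical(nrow(cs), 1L)
  expect_true(all(is.finite(c(cs$g_kir, cs$g_hcn, cs$g_atype))))
  expect_true(all(is.finite(c(cs$g_kir_residual_sd, cs$g_hcn_residual_sd,
    cs$g_atype_residual_sd))))
  cs2 <- conductance_set(hyper)
  expect_true(is.na(cs2$g_atype))
})
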