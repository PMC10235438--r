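# Steady-state gating curves of the subthreshold conductances.  These are
# the model definitions shared by the voltage-clamp generator and the
# ground-truth conductance calculators.
kir_gate <- function(v, params) 1 / (1 + exp((v - params$kir_vhalf) / params$kir_slope))
hcn_gate <- function(v, params) 1 / (1 + exp((v - params$hcn_vhalf) / params$hcn_slope))
atype_act_gate <- function(v) 1 / (1 + exp(-(v + 45) / 10))
atype_inact_gate <- function(v) 1 / (1 + exp((v + 70) / 6))

# Membrane current (pA) at clamped voltage v with HCN gate r, A-type gates
# a and b. Instantaneous components only; capacitive transient added by the
# caller.
vclamp_ionic <- function(v, r, a, b, params, g_atype) {
  params$g_leak * (v - params$e_leak) +
    params$g_kir * kir_gate(v, params) * (v - params$e_k) +
    params$g_hcn * r * (v - params$e_hcn) +
    g_atype * a * b * (v - params$e_k)
}

#' Simulate a voltage-clamp current family
#'
#' Generates the whole-cell current response to a family of voltage steps
#' from a holding potential, as the sum of a capacitive transient (single
#' exponential, time constant `tau_cap`), ohmic leak, instantaneous
#' Boltzmann-rectified Kir current, first-order activating HCN current, an
#' A-type K current with fast activation and slower inactivation (peaking a
#' few ms after depolarizing steps), and white Gaussian noise. All ionic
#' gating follows the model's closed-form relaxation between steady states,
#' so "instantaneous vs steady-state" separation is exact in the model.
#'
#' With `"atype_blocker"` in `blockers` (emulating 4-AP) the A-type term is
#' zero; spike conductances are absent throughout (TTX/TEA conditions).
#'
#' @param params A [neuron_params()].
#' @param protocol A [step_protocol()] with levels in mV.
#' @param blockers Character vector, subset of `"atype_blocker"`.
#' @param dt Sampling interval, s (default 5e-5: 20 kHz).
#' @param noise_sd Current noise s.d., pA.
#' @param tau_cap Capacitive transient time constant, ms (<= 2).
#' @param sweep_duration Sweep length, s (default: step offset + 0.2 s).
#' @param seed RNG seed.
#' @return A list with `series` (a [sweep_series()], role
#'   `membrane_current`) and `truth` (the definitional ground-truth slope
#'   conductances from [true_kir_conductance()], [true_hcn_conductance()],
#'   [true_atype_conductance()], plus model parameters).
#' @export
simulate_voltage_clamp <- function(params, protocol, blockers = character(),
                                   dt = 5e-5, noise_sd = 2, tau_cap = 1,
                                   sweep_duration = NULL, seed = params$seed) {
  stopifnot(inherits(params, "pk_neuron_params"), inherits(protocol, "pk_protocol"))
  if (!all(blockers %in% "atype_blocker")) {
    stop("unknown blocker(s): ", paste(setdiff(blockers, "atype_blocker"),
      collapse = ", "), call. = FALSE)
  }
  if (tau_cap > 2) stop("tau_cap must be <= 2 ms", call. = FALSE)
  g_atype <- if ("atype_blocker" %in% blockers) 0 else params$g_atype
  if (is.null(sweep_duration)) sweep_duration <- protocol$step_offset + 0.2
  n <- round(sweep_duration / dt)
  tt <- (seq_len(n) - 1) * dt
  v0 <- protocol$holding
  on_i <- which(tt >= protocol$step_onset & tt < protocol$step_offset)
  post_i <- which(tt >= protocol$step_offset)
  pre_i <- which(tt < protocol$step_onset)
  tau_hcn_s <- params$hcn_tau / 1000
  tau_a_s <- params$atype_tau_act / 1000
  tau_b_s <- params$atype_tau_inact / 1000
  tau_c_s <- tau_cap / 1000
  r0 <- hcn_gate(v0, params); a0 <- atype_act_gate(v0); b0 <- atype_inact_gate(v0)
  set.seed(seed)
  sweeps <- vector("list", length(protocol$step_levels))
  for (i in seq_along(protocol$step_levels)) {
    v <- protocol$step_levels[i]
    cur <- numeric(n)
    cur[pre_i] <- vclamp_ionic(v0, r0, a0, b0, params, g_atype)
    ts <- tt[on_i] - protocol$step_onset
    r_t <- hcn_gate(v, params) + (r0 - hcn_gate(v, params)) * exp(-ts / tau_hcn_s)
    a_t <- atype_act_gate(v) + (a0 - atype_act_gate(v)) * exp(-ts / tau_a_s)
    b_t <- atype_inact_gate(v) + (b0 - atype_inact_gate(v)) * exp(-ts / tau_b_s)
    cap <- params$C * (v - v0) / tau_cap * exp(-ts / tau_c_s)
    cur[on_i] <- vclamp_ionic(v, r_t, a_t, b_t, params, g_atype) + cap
    # step back to holding: gates relax from end-of-step values
    r_end <- r_t[length(r_t)]; a_end <- a_t[length(a_t)]; b_end <- b_t[length(b_t)]
    tp <- tt[post_i] - protocol$step_offset
    r_p <- r0 + (r_end - r0) * exp(-tp / tau_hcn_s)
    a_p <- a0 + (a_end - a0) * exp(-tp / tau_a_s)
    b_p <- b0 + (b_end - b0) * exp(-tp / tau_b_s)
    cap_p <- params$C * (v0 - v) / tau_cap * exp(-tp / tau_c_s)
    cur[post_i] <- vclamp_ionic(v0, r_p, a_p, b_p, params, g_atype) + cap_p
    cur <- cur + rnorm(n, sd = noise_sd)
    sweeps[[i]] <- trace(cur, dt = dt, units = "pA", role = "membrane_current",
      lowpass_cutoff = 2000)
  }
  series <- sweep_series(sweeps, protocol,
    metadata = list(junction_corrected = FALSE, blockers = blockers,
      seed = seed))
  truth <- list(
    g_kir = true_kir_conductance(params),
    g_hcn = true_hcn_conductance(params),
    g_atype = if (g_atype > 0) true_atype_conductance(params) else 0,
    params = params)
  list(series = series, truth = truth)
}

dense_slope <- function(v, i) unname(coef(lm(i ~ v))[2])

#' Ground-truth Kir slope conductance of the model
#'
#' Evaluates the model's noise-free instantaneous current on a dense 1 mV
#' grid and applies the definitional contrast: slope conductance over
#' -130..-110 mV minus slope conductance over -90..-70 mV (positive for an
#' inward rectifier).
#'
#' @param params A [neuron_params()].
#' @param holding Holding potential used for the instantaneous HCN level, mV.
#' @return Conductance, nS.
#' @export
true_kir_conductance <- function(params, holding = -60) {
  r0 <- hcn_gate(holding, params)
  inst <- function(v) params$g_leak * (v - params$e_leak) +
    params$g_kir * kir_gate(v, params) * (v - params$e_k) +
    params$g_hcn * r0 * (v - params$e_hcn)
  v_lo <- seq(-130, -110, 1); v_hi <- seq(-90, -70, 1)
  dense_slope(v_lo, inst(v_lo)) - dense_slope(v_hi, inst(v_hi))
}

#' Ground-truth HCN slope conductance of the model
#'
#' Slope, over -130..-110 mV on a dense grid, of the model's steady-state
#' minus instantaneous current (the slowly developing HCN component).
#'
#' @inheritParams true_kir_conductance
#' @return Conductance, nS.
#' @export
true_hcn_conductance <- function(params, holding = -60) {
  r0 <- hcn_gate(holding, params)
  v <- seq(-130, -110, 1)
  diff_i <- params$g_hcn * (hcn_gate(v, params) - r0) * (v - params$e_hcn)
  dense_slope(v, diff_i)
}

#' Ground-truth A-type slope conductance of the model
#'
#' Peak of the model's isolated A-type current after a depolarizing step
#' from `holding` (maximizing the activation-inactivation product over
#' time), evaluated densely in voltage; returns the slope of that peak
#' current vs voltage over -20..+35 mV.
#'
#' @param params A [neuron_params()].
#' @param holding Pre-step holding potential, mV (default -100, fully
#'   de-inactivated).
#' @return Conductance, nS.
#' @export
true_atype_conductance <- function(params, holding = -100) {
  a0 <- atype_act_gate(holding); b0 <- atype_inact_gate(holding)
  v <- seq(-20, 35, 1)
  peak <- vapply(v, function(vv) {
    ainf <- atype_act_gate(vv); binf <- atype_inact_gate(vv)
    f <- function(t_ms) -(ainf + (a0 - ainf) * exp(-t_ms / params$atype_tau_act)) *
      (binf + (b0 - binf) * exp(-t_ms / params$atype_tau_inact))
    opt <- stats::optimize(f, c(0, 100))
    params$g_atype * -opt$objective * (vv - params$e_k)
  }, numeric(1))
  dense_slope(v, peak)
}

#' Simulate a voltage-clamp membrane test pulse
#'
#' A small voltage step on an RC-like cell: capacitive charge `C * dV`
#' delivered as a single-exponential transient on top of the ohmic leak
#' step, plus white noise. Used to exercise capacitance and access QC
#' estimation.
#'
#' @param params A [neuron_params()] (only `C`, `g_leak`, `e_leak` and the
#'   subthreshold conductances at the holding level are used).
#' @param v_hold Holding potential, mV.
#' @param dv Step amplitude, mV.
#' @param tau_cap Transient time constant, ms.
#' @param dt Sampling interval, s.
#' @param duration Sweep length, s; the step spans the middle half.
#' @param noise_sd Current noise s.d., pA.
#' @param seed RNG seed.
#' @return A list with `trace` (current [trace()]), `protocol` (the voltage
#'   [step_protocol()]), and `truth` (`C` pF, `dv` mV).
#' @export
simulate_test_pulse <- function(params, v_hold = -70, dv = 10, tau_cap = 1,
                                dt = 5e-5, duration = 0.4, noise_sd = 2,
                                seed = params$seed) {
  n <- round(duration / dt)
  tt <- (seq_len(n) - 1) * dt
  onset <- duration / 4; offset <- 3 * duration / 4
  on <- tt >= onset & tt < offset
  base_i <- vclamp_ionic(v_hold, hcn_gate(v_hold, params),
    atype_act_gate(v_hold), atype_inact_gate(v_hold), params, 0)
  step_i <- vclamp_ionic(v_hold + dv, hcn_gate(v_hold, params),
    atype_act_gate(v_hold), atype_inact_gate(v_hold), params, 0)
  cur <- rep(base_i, n)
  ts <- tt[on] - onset
  cur[on] <- step_i + params$C * dv / tau_cap * exp(-ts / (tau_cap / 1000))
  tp <- tt[tt >= offset] - offset
  cur[tt >= offset] <- base_i - params$C * dv / tau_cap * exp(-tp / (tau_cap / 1000))
  set.seed(seed)
  cur <- cur + rnorm(n, sd = noise_sd)
  list(
    trace = trace(cur, dt = dt, units = "pA", role = "membrane_current",
      lowpass_cutoff = 2000),
    protocol = step_protocol(v_hold, onset, offset, v_hold + dv),
    truth = list(C = params$C, dv = dv))
}
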