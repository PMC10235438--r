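#' Biophysical parameters of the synthetic neuron
#'
#' Parameter set for the single-compartment conductance-based model used by
#' [simulate_current_clamp()] and (for its passive and subthreshold
#' conductances) [simulate_voltage_clamp()]. The model carries fast Na and
#' delayed-rectifier K spike conductances with Hodgkin-Huxley kinetics, an
#' instantaneous Boltzmann-rectified inward-rectifier K (Kir) conductance, a
#' first-order hyperpolarization-activated (HCN) conductance, a rapidly
#' activating/inactivating A-type K conductance, and a slow adaptation K
#' conductance that produces spike-frequency accommodation.
#'
#' Defaults describe a small cultured hippocampal neuron: 30 pF, resting
#' near -74 mV, rheobase of several tens of pA under 1 s steps.
#'
#' @param C Membrane capacitance, pF.
#' @param g_leak Leak conductance, nS. @param e_leak Leak reversal, mV.
#' @param g_na,e_na Fast Na conductance (nS) and reversal (mV).
#' @param na_shift Depolarizing shift of the Na activation/inactivation
#'   kinetics, mV; positive values raise the spike threshold.
#' @param g_kdr,e_k Delayed-rectifier K conductance (nS) and K reversal (mV).
#' @param g_kir Kir conductance, nS; `kir_vhalf`, `kir_slope` (mV) set its
#'   instantaneous Boltzmann rectification.
#' @param kir_vhalf,kir_slope Kir rectification midpoint and slope, mV.
#' @param g_hcn HCN conductance, nS; `e_hcn` its reversal (mV), `hcn_tau`
#'   its single-exponential activation time constant (ms), `hcn_vhalf` /
#'   `hcn_slope` its activation curve (mV).
#' @param e_hcn,hcn_tau,hcn_vhalf,hcn_slope See `g_hcn`.
#' @param g_atype A-type K conductance, nS; `atype_tau_act` and
#'   `atype_tau_inact` (ms) set its kinetics so the isolated current peaks a
#'   few ms after a depolarizing step.
#' @param atype_tau_act,atype_tau_inact See `g_atype`.
#' @param g_adapt,adapt_tau Slow adaptation K conductance (nS) and its time
#'   constant (ms); larger values give stronger spike-frequency adaptation.
#' @param noise_sd Measurement noise s.d. on recorded samples (mV in current
#'   clamp, pA in voltage clamp), band-limited to the acquisition filter.
#' @param seed Default RNG seed threaded through the generators.
#' @return A named list of class `pk_neuron_params`.
#' @export
neuron_params <- function(C = 30, g_leak = 1.5, e_leak = -65,
                          g_na = 2400, e_na = 55, na_shift = 0,
                          g_kdr = 700, e_k = -90,
                          g_kir = 3, kir_vhalf = -100, kir_slope = 8,
                          g_hcn = 1.5, e_hcn = -30, hcn_tau = 200,
                          hcn_vhalf = -95, hcn_slope = 6,
                          g_atype = 10, atype_tau_act = 2, atype_tau_inact = 25,
                          g_adapt = 0.3, adapt_tau = 300,
                          noise_sd = 0.2, seed = 1L) {
  p <- list(C = C, g_leak = g_leak, e_leak = e_leak, g_na = g_na, e_na = e_na,
    na_shift = na_shift, g_kdr = g_kdr, e_k = e_k, g_kir = g_kir, kir_vhalf = kir_vhalf,
    kir_slope = kir_slope, g_hcn = g_hcn, e_hcn = e_hcn, hcn_tau = hcn_tau,
    hcn_vhalf = hcn_vhalf, hcn_slope = hcn_slope, g_atype = g_atype,
    atype_tau_act = atype_tau_act, atype_tau_inact = atype_tau_inact,
    g_adapt = g_adapt, adapt_tau = adapt_tau,
    noise_sd = noise_sd, seed = as.integer(seed))
  gs <- c("C", "g_leak", "g_na", "g_kdr", "g_kir", "g_hcn", "g_atype",
    "g_adapt")
  bad <- vapply(p[gs], function(x) !is.finite(x) || x < 0, logical(1))
  if (any(bad)) stop("conductances must be >= 0 and capacitance > 0",
    call. = FALSE)
  if (p$C <= 0) stop("capacitance must be > 0", call. = FALSE)
  structure(p, class = "pk_neuron_params")
}

cpp_params <- function(p) {
  unlist(p[c("C", "g_leak", "e_leak", "g_na", "e_na", "na_shift", "g_kdr", "e_k",
    "g_kir", "kir_vhalf", "kir_slope", "g_hcn", "e_hcn", "hcn_tau",
    "hcn_vhalf", "hcn_slope", "g_atype", "atype_tau_act", "atype_tau_inact",
    "g_adapt", "adapt_tau")])
}

#' Resting potential of the model (zero-current fixed point)
#'
#' Solves for the membrane potential at which the total steady-state
#' membrane current equals the holding current. This is the exact fixed
#' point of the deterministic model and the ground truth for resting-
#' potential recovery tests.
#'
#' @param params A [neuron_params()].
#' @param holding_pA Constant injected current, pA (default 0).
#' @return Membrane potential, mV.
#' @export
true_resting_potential <- function(params, holding_pA = 0) {
  f <- function(v) .hh_steady_current(v, cpp_params(params)) - holding_pA
  uniroot(f, c(-120, -30), tol = 1e-10)$root
}

#' Holding current needed to keep the model at a target potential
#'
#' @param params A [neuron_params()].
#' @param v_target Target membrane potential, mV.
#' @return Injected current, pA.
#' @export
holding_current_for <- function(params, v_target) {
  .hh_steady_current(v_target, cpp_params(params))
}

band_limited_noise <- function(n, dt, sd, cutoff) {
  if (sd <= 0 || n == 0) return(numeric(n))
  w <- rnorm(n)
  nyq <- 0.5 / dt
  if (!is.null(cutoff) && is.finite(cutoff) && cutoff < nyq) {
    bf <- signal::butter(2, cutoff / nyq, type = "low")
    w <- signal::filtfilt(bf, w)
  }
  as.numeric(w * sd / stats::sd(w))
}

upward_crossings <- function(v, tt, level = 0) {
  i <- which(v[-length(v)] < level & v[-1] >= level)
  if (!length(i)) return(numeric(0))
  frac <- (level - v[i]) / (v[i + 1] - v[i])
  tt[i] + frac * (tt[i + 1] - tt[i])
}

#' Simulate a current-clamp step family
#'
#' Integrates the conductance-based model (fixed-step RK4, Rcpp backend)
#' for each step level of a current-clamp protocol, then adds band-limited
#' Gaussian measurement noise to the voltage. The deterministic (noise-free)
#' trajectory defines the ground truth: spike times are its upward 0 mV
#' crossings and the resting potential is the model's zero-current fixed
#' point.
#'
#' @param params A [neuron_params()].
#' @param protocol A [step_protocol()] with levels in pA. `holding` is the
#'   constant bias current (pA) injected throughout the sweep.
#' @param dt Integration/sampling interval, s (must be <= 25 us).
#' @param sweep_duration Sweep length in s (default: step offset + 0.3 s).
#' @param lowpass_cutoff Acquisition filter applied to the noise, Hz.
#' @param seed RNG seed (default `params$seed`).
#' @return A list with `series` (a [sweep_series()]) and `truth` (a list
#'   with per-sweep `spike_times`, `spike_counts`, `resting_V`, and the
#'   parameter set).
#' @export
simulate_current_clamp <- function(params, protocol, dt = 2e-5,
                                   sweep_duration = NULL,
                                   lowpass_cutoff = 10000,
                                   seed = params$seed) {
  stopifnot(inherits(params, "pk_neuron_params"), inherits(protocol, "pk_protocol"))
  if (dt > 2.5e-5 + 1e-12) {
    stop("integration requires dt <= 25 us; got dt = ", dt, call. = FALSE)
  }
  if (is.null(sweep_duration)) sweep_duration <- protocol$step_offset + 0.3
  n <- round(sweep_duration / dt)
  tt <- (seq_len(n) - 1) * dt
  on <- tt >= protocol$step_onset & tt < protocol$step_offset
  v0 <- true_resting_potential(params, holding_pA = protocol$holding)
  pv <- cpp_params(params)
  dt_ms <- dt * 1000
  set.seed(seed)
  sweeps <- vector("list", length(protocol$step_levels))
  spike_times <- vector("list", length(protocol$step_levels))
  for (i in seq_along(protocol$step_levels)) {
    i_inj <- rep(protocol$holding, n)
    i_inj[on] <- protocol$holding + protocol$step_levels[i]
    v <- .hh_integrate(pv, dt_ms, v0, i_inj, numeric(n))
    if (!isTRUE(attr(v, "finite"))) {
      stop("integration unstable (non-finite state) at dt = ", dt,
        call. = FALSE)
    }
    spike_times[[i]] <- upward_crossings(v, tt, 0)
    noisy <- v + band_limited_noise(n, dt, params$noise_sd, lowpass_cutoff)
    sweeps[[i]] <- trace(noisy, dt = dt, units = "mV",
      role = "membrane_voltage", lowpass_cutoff = lowpass_cutoff)
  }
  series <- sweep_series(sweeps, protocol,
    metadata = list(junction_corrected = FALSE,
      holding_current = protocol$holding, seed = seed))
  truth <- list(spike_times = spike_times,
    spike_counts = lengths(spike_times), resting_V = v0, params = params,
    protocol = protocol)
  list(series = series, truth = truth)
}

#' Ground-truth rheobase by dense current scan
#'
#' Finds the minimum step current that evokes at least one spike (an upward
#' 0 mV crossing of the deterministic model trajectory during the step), by
#' scanning step amplitudes at `resolution` pA from `lo` upward. This is the
#' simulator-side oracle for rheobase-recovery tests; it never calls the
#' analysis-side spike detector.
#'
#' @param params A [neuron_params()].
#' @param lo,hi Scan range, pA.
#' @param resolution Scan increment, pA (default 1).
#' @param holding Bias current, pA.
#' @param step_onset,step_offset Step timing, s (1 s step by default).
#' @param dt Integration interval, s.
#' @return The minimum spiking level (pA), or `NA` if no level in range
#'   spikes.
#' @export
true_rheobase <- function(params, lo = 0, hi = 200, resolution = 1,
                          holding = 0, step_onset = 0.1, step_offset = 1.1,
                          dt = 2e-5) {
  n <- round((step_offset + 0.1) / dt)
  tt <- (seq_len(n) - 1) * dt
  on <- tt >= step_onset & tt < step_offset
  v0 <- true_resting_potential(params, holding_pA = holding)
  pv <- cpp_params(params)
  for (lev in seq(lo, hi, by = resolution)) {
    i_inj <- rep(holding, n)
    i_inj[on] <- holding + lev
    v <- .hh_integrate(pv, dt * 1000, v0, i_inj, numeric(n))
    if (!isTRUE(attr(v, "finite"))) {
      stop("integration unstable (non-finite state) at dt = ", dt,
        call. = FALSE)
    }
    if (length(upward_crossings(v, tt, 0))) return(lev)
  }
  NA_real_
}
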