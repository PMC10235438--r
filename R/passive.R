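#' Resting membrane potential from a quiescent baseline window
#'
#' Mean voltage over a window that must contain no detected APs; callers
#' pick a clean pre-stimulus window. If the parent series was junction-
#' corrected the samples already carry the correction.
#'
#' @param tr A voltage [trace()].
#' @param baseline_window `(start, end)` in seconds.
#' @param dvdt_threshold,peak_floor AP screening parameters, as in
#'   [detect_aps()].
#' @return Mean membrane potential, mV.
#' @export
resting_potential <- function(tr, baseline_window, dvdt_threshold = 20,
                              peak_floor = -10) {
  stopifnot(inherits(tr, "pk_trace"))
  aps <- detect_aps(tr, baseline_window, dvdt_threshold = dvdt_threshold,
    peak_floor = peak_floor, onset_blank = 0)
  if (nrow(aps)) {
    stop("APs detected inside the baseline window; choose a window without spikes",
      call. = FALSE)
  }
  idx <- trace_time(tr) >= baseline_window[1] & trace_time(tr) < baseline_window[2]
  mean(tr$samples[idx])
}

#' Input resistance from subthreshold hyperpolarizing steps
#'
#' Least-squares slope of the steady-state voltage deflection against
#' injected current, over the hyperpolarizing (negative) step levels of a
#' current-clamp family. Depolarizing or spiking sweeps are excluded
#' automatically and reported in the `excluded_levels` attribute.
#'
#' @param series A current-clamp [sweep_series()] (levels in pA).
#' @param ss_fraction Final fraction of the step averaged as the steady
#'   state (default 0.25).
#' @return Input resistance in MOhm, with attributes `n_used` and
#'   `excluded_levels`.
#' @export
input_resistance <- function(series, ss_fraction = 0.25) {
  stopifnot(inherits(series, "pk_sweeps"))
  p <- series$protocol
  dt <- sweep_dt(series)
  tt <- trace_time(series$sweeps[[1]])
  base_i <- tt < p$step_onset
  ss_start <- p$step_offset - (p$step_offset - p$step_onset) * ss_fraction
  ss_i <- tt >= ss_start & tt < p$step_offset
  win <- c(p$step_onset, p$step_offset)
  usable <- logical(length(p$step_levels))
  dV <- numeric(length(p$step_levels))
  for (i in seq_along(p$step_levels)) {
    if (p$step_levels[i] >= 0) next
    tr <- series$sweeps[[i]]
    if (nrow(detect_aps(tr, win, onset_blank = 0))) next
    dV[i] <- mean(tr$samples[ss_i]) - mean(tr$samples[base_i])
    usable[i] <- TRUE
  }
  if (sum(usable) < 2) {
    stop("need at least 2 usable subthreshold hyperpolarizing sweeps",
      call. = FALSE)
  }
  slope <- unname(coef(lm(dV[usable] ~ p$step_levels[usable]))[2])  # mV/pA = GOhm
  structure(slope * 1000, n_used = sum(usable),
    excluded_levels = p$step_levels[!usable])
}

estimate_noise_sd <- function(x) {
  # robust noise scale from first differences (insensitive to slow drift)
  median(abs(diff(x))) / (sqrt(2) * 0.6744898)
}

#' Whole-cell capacitance from a voltage-clamp test-pulse transient
#'
#' Charge-integral method: after subtracting the post-transient steady
#' (leak) current, the capacitive charge delivered by a voltage step `dv`
#' is the time integral of the transient current, and `C = Q / dv`. The
#' transient end is the first point where the current stays within
#' `3 * noise sd` of the steady level for 1 ms.
#'
#' @param tr A current [trace()] containing a test pulse.
#' @param protocol The voltage [step_protocol()] of the pulse (levels mV).
#' @return Capacitance in pF.
#' @export
capacitance_from_transient <- function(tr, protocol) {
  stopifnot(inherits(tr, "pk_trace"), inherits(protocol, "pk_protocol"))
  if (tr$role != "membrane_current") {
    stop("capacitance estimation requires a current trace", call. = FALSE)
  }
  dv <- protocol$step_levels[1] - protocol$holding
  dt <- tr$dt
  tt <- trace_time(tr)
  on_i <- which(tt >= protocol$step_onset & tt < protocol$step_offset)
  if (!length(on_i) || max(tt) < protocol$step_offset - 1e-9) {
    stop("transient clipped: step not fully contained in sweep", call. = FALSE)
  }
  i_on <- tr$samples[on_i]
  nss <- max(round(length(on_i) * 0.25), 10L)
  steady <- mean(i_on[(length(i_on) - nss + 1L):length(i_on)])
  noise_sd <- estimate_noise_sd(i_on[(length(i_on) - nss + 1L):length(i_on)])
  run <- max(round(0.001 / dt), 1L)
  quiet <- abs(i_on - steady) < 3 * max(noise_sd, 1e-12)
  cs <- cumsum(quiet)
  runsum <- cs[(run + 1):length(cs)] - cs[seq_len(length(cs) - run)]
  end_rel <- which(runsum == run)[1]
  if (is.na(end_rel)) end_rel <- length(i_on) - run
  trans <- i_on[seq_len(end_rel)] - steady
  q <- (sum(trans) - trans[1] / 2 - trans[length(trans)] / 2) * dt  # pA s
  q / dv * 1e3  # (pA s / mV) = nF -> pF
}

#' Access-resistance estimate from a test-pulse transient
#'
#' Peak-current method: `Ra = dv / I_peak`, with the peak measured as the
#' largest baseline-subtracted excursion right after the step onset.
#'
#' @inheritParams capacitance_from_transient
#' @return Access resistance, MOhm.
#' @export
access_resistance_estimate <- function(tr, protocol) {
  stopifnot(inherits(tr, "pk_trace"))
  dv <- protocol$step_levels[1] - protocol$holding
  tt <- trace_time(tr)
  base <- mean(tr$samples[tt < protocol$step_onset])
  on_i <- which(tt >= protocol$step_onset & tt < protocol$step_offset)
  ipk <- max(abs(tr$samples[on_i] - base))
  abs(dv) / ipk * 1000  # mV/pA = GOhm -> MOhm
}

#' Passive membrane properties of a cell
#'
#' Combines the resting potential (from the pre-step baseline of a
#' current-clamp family), the input resistance (steady-state Ohmic fit over
#' hyperpolarizing steps), and the whole-cell capacitance (charge-integral
#' over one or more test pulses; the median across pulses is reported as
#' the stabilized value).
#'
#' @param cc_series A current-clamp [sweep_series()].
#' @param test_pulses A list of `list(trace =, protocol =)` test pulses
#'   (e.g. from [simulate_test_pulse()]), or `NULL`.
#' @return A one-row tibble: `resting_V` (mV), `input_resistance` (MOhm),
#'   `capacitance` (pF), `access_resistance` (MOhm).
#' @export
passive_properties <- function(cc_series, test_pulses = NULL) {
  rv <- resting_potential(cc_series$sweeps[[1]],
    c(0, cc_series$protocol$step_onset))
  rin <- input_resistance(cc_series)
  cap <- ra <- NA_real_
  if (!is.null(test_pulses)) {
    cap <- median(vapply(test_pulses, function(tp)
      capacitance_from_transient(tp$trace, tp$protocol), numeric(1)))
    ra <- median(vapply(test_pulses, function(tp)
      access_resistance_estimate(tp$trace, tp$protocol), numeric(1)))
  }
  tibble(resting_V = rv, input_resistance = as.numeric(rin),
    capacitance = cap, access_resistance = ra)
}
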