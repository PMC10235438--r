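boxcar_smooth <- function(x, k) {
  if (k <= 1) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}

detect_transient_end <- function(i_on, dt) {
  # first time after step onset where the smoothed |dI/dt| settles below a
  # floor set by the larger of the noise-derivative scale and 0.2% of the
  # transient's own peak slope (so slow ionic relaxation does not keep the
  # window open)
  k <- max(round(5e-4 / dt), 1L)
  s <- boxcar_smooth(i_on, k)
  n <- length(s)
  lag <- k
  ds <- abs(s[(1 + 2 * lag):n] - s[1:(n - 2 * lag)]) / (2 * lag * dt * 1000)
  nss <- max(round(length(ds) * 0.25), 10L)
  tail_d <- ds[(length(ds) - nss + 1L):length(ds)]
  floor_lvl <- max(0.002 * max(ds), median(tail_d) + 6 * stats::mad(tail_d),
    1e-12)
  run <- max(round(5e-4 / dt), 2L)
  quiet <- ds < floor_lvl
  cs <- cumsum(quiet)
  runsum <- cs[(run + 1):length(cs)] - cs[seq_len(length(cs) - run)]
  hit <- which(runsum == run)[1]
  if (is.na(hit)) hit <- 1L
  min(hit + lag, length(i_on))  # index into i_on
}

#' Measure instantaneous and steady-state step currents
#'
#' For each sweep of a voltage-clamp family: the instantaneous current is
#' the mean over a window placed directly after the detected end of the
#' capacitive transient, and the steady-state current is the mean over the
#' final part of the step. Sweeps whose transient ends unusually late
#' (overlapping the nominal instantaneous window position) are flagged and
#' their window shifted accordingly.
#'
#' @param series A voltage-clamp [sweep_series()] (current traces, levels
#'   in mV).
#' @param inst_width Instantaneous window width, ms (default 5).
#' @param ss_width Steady-state window width at the end of the step, ms
#'   (default 100).
#' @return An `iv_table` tibble with one row per sweep: `v_command`,
#'   `i_inst`, `i_ss`, `i_diff` (= `i_ss - i_inst`), `transient_end_ms`,
#'   `flagged`.
#' @export
measure_step_currents <- function(series, inst_width = 5, ss_width = 100) {
  stopifnot(inherits(series, "pk_sweeps"))
  if (series$sweeps[[1]]$role != "membrane_current") {
    stop("voltage-clamp analysis requires current traces", call. = FALSE)
  }
  p <- series$protocol
  dt <- sweep_dt(series)
  tt <- trace_time(series$sweeps[[1]])
  on_idx <- which(tt >= p$step_onset & tt < p$step_offset)
  step_ms <- (p$step_offset - p$step_onset) * 1000
  if (inst_width + ss_width > step_ms) {
    stop("analysis windows exceed step duration", call. = FALSE)
  }
  n_inst <- max(round(inst_width / 1000 / dt), 2L)
  n_ss <- max(round(ss_width / 1000 / dt), 2L)
  rows <- purrr::map2_dfr(series$sweeps, p$step_levels, function(tr, v) {
    i_on <- tr$samples[on_idx]
    te <- detect_transient_end(i_on, dt)
    flagged <- (te * dt * 1000) > 20
    i_inst <- mean(i_on[te:min(te + n_inst - 1L, length(i_on))])
    i_ss <- mean(i_on[(length(i_on) - n_ss + 1L):length(i_on)])
    tibble(v_command = v, i_inst = i_inst, i_ss = i_ss,
      i_diff = i_ss - i_inst, transient_end_ms = te * dt * 1000,
      flagged = flagged)
  })
  rows <- dplyr::arrange(rows, .data$v_command)
  class(rows) <- c("iv_table", class(rows))
  rows
}

#' Slope conductance by linear fit of an I-V relation
#'
#' Least-squares slope (pA/mV = nS) of the chosen current column against
#' command voltage over `v_range`. Adding a constant to all currents leaves
#' the slope unchanged.
#'
#' @param iv An I-V table from [measure_step_currents()], or any data frame
#'   with `v_command` and the current columns.
#' @param column `"instantaneous"`, `"steady"` or `"difference"`
#'   (steady minus instantaneous).
#' @param v_range `(lo, hi)` command-voltage range, mV; at least two rows
#'   must fall inside.
#' @return Slope conductance in nS, with attribute `residual_sd` (pA).
#' @export
slope_conductance <- function(iv, column = c("instantaneous", "steady", "difference"),
                              v_range) {
  column <- match.arg(column)
  col <- switch(column, instantaneous = "i_inst", steady = "i_ss",
    difference = "i_diff")
  sel <- iv$v_command >= min(v_range) & iv$v_command <= max(v_range)
  if (sum(sel) < 2) {
    stop(sprintf("need at least 2 I-V rows inside [%g, %g] mV", min(v_range),
      max(v_range)), call. = FALSE)
  }
  fit <- lm(iv[[col]][sel] ~ iv$v_command[sel])
  structure(unname(coef(fit)[2]), residual_sd = sd(stats::residuals(fit)))
}

#' Kir slope conductance from an I-V table
#'
#' Difference of instantaneous slope conductances between the strongly
#' hyperpolarized range (-130..-110 mV) and the near-resting range
#' (-90..-70 mV). The subtraction order is chosen so that an inward
#' rectifier yields a positive value; the magnitude is what is compared
#' across cells.
#'
#' @param iv An I-V table from [measure_step_currents()].
#' @param range_hyper,range_rest The two voltage ranges, mV.
#' @return Kir conductance, nS (attribute `residual_sd` from the
#'   hyperpolarized fit).
#' @export
kir_conductance <- function(iv, range_hyper = c(-130, -110),
                            range_rest = c(-90, -70)) {
  g_lo <- slope_conductance(iv, "instantaneous", range_hyper)
  g_hi <- slope_conductance(iv, "instantaneous", range_rest)
  structure(as.numeric(g_lo) - as.numeric(g_hi),
    residual_sd = attr(g_lo, "residual_sd"))
}

#' HCN slope conductance from an I-V table
#'
#' Slope of the difference between steady-state and instantaneous currents
#' over -130..-110 mV, capturing the slowly activating hyperpolarization-
#' activated component; leak and Kir are instantaneous and cancel in the
#' subtraction.
#'
#' @param iv An I-V table from [measure_step_currents()].
#' @param v_range Voltage range, mV.
#' @return HCN conductance, nS (with `residual_sd` attribute).
#' @export
hcn_conductance <- function(iv, v_range = c(-130, -110)) {
  g <- slope_conductance(iv, "difference", v_range)
  structure(as.numeric(g), residual_sd = attr(g, "residual_sd"))
}

#' A-type conductance by digital subtraction
#'
#' Subtracts the blocked family (recorded with the A-type current blocked,
#' emulating 4-AP) from the control family sweep-by-sweep, pairing sweeps
#' by identical command level. The isolated rapidly inactivating outward
#' current must peak within `peak_window` ms of the step onset; sweeps
#' peaking outside it are flagged and excluded. The conductance is the
#' least-squares slope of peak current vs command voltage over `fit_range`.
#'
#' @param control,blocked Voltage-clamp [sweep_series()] sharing a protocol.
#' @param peak_window Accepted peak latency window, ms (default 3..13).
#' @param fit_range Voltage range for the slope fit, mV (default -20..+35).
#' @param smooth_ms Boxcar smoothing for peak localization, ms.
#' @return A-type conductance in nS, with attributes `residual_sd` and
#'   `peaks` (per-sweep tibble: `v_command`, `peak_pA`, `peak_ms`,
#'   `flagged`).
#' @export
atype_conductance <- function(control, blocked, peak_window = c(3, 13),
                              fit_range = c(-20, 35), smooth_ms = 0.5) {
  stopifnot(inherits(control, "pk_sweeps"), inherits(blocked, "pk_sweeps"))
  pc <- control$protocol; pb <- blocked$protocol
  if (!isTRUE(all.equal(pc$step_onset, pb$step_onset)) ||
      !isTRUE(all.equal(pc$step_offset, pb$step_offset)) ||
      abs(sweep_dt(control) - sweep_dt(blocked)) > 1e-12) {
    stop("protocol mismatch between control and blocked families", call. = FALSE)
  }
  common <- intersect(pc$step_levels, pb$step_levels)
  if (!length(common)) stop("no shared command levels", call. = FALSE)
  dt <- sweep_dt(control)
  tt <- trace_time(control$sweeps[[1]])
  on_idx <- which(tt >= pc$step_onset & tt < pc$step_offset)
  pre_idx <- which(tt < pc$step_onset)
  k <- max(round(smooth_ms / 1000 / dt), 1L)
  peaks <- purrr::map_dfr(common, function(v) {
    ic <- control$sweeps[[match(v, pc$step_levels)]]$samples
    ib <- blocked$sweeps[[match(v, pb$step_levels)]]$samples
    di <- ic - ib
    di_s <- boxcar_smooth(di, k)
    base <- mean(di_s[pre_idx])
    seg <- di_s[on_idx] - base
    ipk <- which.max(seg)
    # the latency rule only applies to real currents: sub-noise peaks keep
    # their (near-zero) amplitude so a null difference fits a zero slope.
    # The floor tracks the expected maximum of the smoothed noise over the
    # whole search span (extreme-value scaling), not its pointwise sd.
    n_eff <- max(length(seg) / k, 2)
    noise_floor <- sd(di_s[pre_idx]) * (sqrt(2 * log(n_eff)) + 1.5)
    in_window <- ipk * dt * 1000 >= peak_window[1] &
      ipk * dt * 1000 <= peak_window[2]
    tibble(v_command = v, peak_pA = seg[ipk], peak_ms = ipk * dt * 1000,
      flagged = seg[ipk] > noise_floor && !in_window)
  })
  fit_rows <- peaks[!peaks$flagged &
    peaks$v_command >= fit_range[1] & peaks$v_command <= fit_range[2], ]
  if (nrow(fit_rows) < 2) {
    stop("fewer than 2 unflagged sweeps in the fit range", call. = FALSE)
  }
  fit <- lm(peak_pA ~ v_command, data = fit_rows)
  structure(unname(coef(fit)[2]), residual_sd = sd(stats::residuals(fit)),
    peaks = peaks)
}

#' Kir/HCN/A-type conductance set for one cell
#'
#' Convenience wrapper running [measure_step_currents()] on the
#' hyperpolarizing family and, when the depolarizing control/blocked pair
#' is given, [atype_conductance()].
#'
#' @param hyper_series Hyperpolarizing voltage-clamp family.
#' @param control,blocked Optional depolarizing families for the A-type
#'   subtraction.
#' @return A one-row tibble: `g_kir`, `g_hcn`, `g_atype` (nS; `g_atype` is
#'   `NA` without the subtraction pair) and their fit residual s.d.s.
#' @export
conductance_set <- function(hyper_series, control = NULL, blocked = NULL) {
  iv <- measure_step_currents(hyper_series)
  gk <- kir_conductance(iv)
  gh <- hcn_conductance(iv)
  ga <- NA_real_; ga_sd <- NA_real_
  if (!is.null(control) && !is.null(blocked)) {
    g <- atype_conductance(control, blocked)
    ga <- as.numeric(g); ga_sd <- attr(g, "residual_sd")
  }
  tibble(g_kir = as.numeric(gk), g_kir_residual_sd = attr(gk, "residual_sd"),
    g_hcn = as.numeric(gh), g_hcn_residual_sd = attr(gh, "residual_sd"),
    g_atype = ga, g_atype_residual_sd = ga_sd)
}
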