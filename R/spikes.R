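central_dvdt <- function(v, dt_ms) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  d
}

#' Detect action potentials by the dV/dt threshold criterion
#'
#' An AP is detected at each upward crossing of the voltage-trace first
#' derivative through `dvdt_threshold`, paired with the subsequent voltage
#' maximum reached before dV/dt returns below zero; the detection is kept
#' only if that peak reaches `peak_floor` (discarding subthreshold noise
#' deflections). Detections whose threshold falls before the analysis
#' window (spontaneous APs) or within `onset_blank` ms of the window start
#' (APs coinciding with current injection onset) are excluded. The
#' derivative is a central difference on the raw, acquisition-filtered
#' trace.
#'
#' @param tr A voltage [trace()].
#' @param window Numeric `(start, end)` in seconds: the current injection
#'   window.
#' @param dvdt_threshold Threshold on dV/dt, mV/ms (default 20).
#' @param peak_floor Minimum AP peak voltage, mV (default -10).
#' @param onset_blank Blanking interval after window start, ms (default 5).
#' @return A tibble with one row per AP: `threshold_index`, `peak_index`
#'   (sample indices), `threshold_time`, `peak_time` (s, derivative-
#'   crossing time interpolated between samples). Sorted, non-overlapping.
#' @export
detect_aps <- function(tr, window, dvdt_threshold = 20, peak_floor = -10,
                       onset_blank = 5) {
  stopifnot(inherits(tr, "pk_trace"))
  if (tr$role != "membrane_voltage") {
    stop("`tr` must have role membrane_voltage", call. = FALSE)
  }
  dur <- length(tr$samples) * tr$dt
  if (window[1] < 0 || window[2] > dur + 1e-9 || window[1] >= window[2]) {
    stop("analysis window outside trace bounds", call. = FALSE)
  }
  v <- tr$samples
  dt_ms <- tr$dt * 1000
  d <- central_dvdt(v, dt_ms)
  n <- length(v)
  tt <- trace_time(tr)
  cross <- which(d[-1] >= dvdt_threshold & d[-n] < dvdt_threshold) + 1L
  neg <- which(d < 0)
  end_idx <- min(n, floor(window[2] / tr$dt) + 1L)
  out <- list()
  last_end <- 0L
  t_min <- window[1] + onset_blank / 1000
  for (i in cross) {
    if (i <= last_end || i > end_idx) next
    k <- findInterval(i, neg) + 1L
    j <- if (k <= length(neg)) min(neg[k], end_idx) else end_idx
    if (j <= i) next
    peak <- (i - 1L) + which.max(v[i:j])
    last_end <- j
    if (v[peak] < peak_floor) next
    frac <- if (d[i] != d[i - 1L]) (dvdt_threshold - d[i - 1L]) / (d[i] - d[i - 1L]) else 1
    thr_t <- tt[i - 1L] + frac * tr$dt
    if (thr_t < t_min || thr_t > window[2]) next
    out[[length(out) + 1L]] <- c(i, peak, thr_t, tt[peak])
  }
  if (!length(out)) {
    return(tibble(threshold_index = integer(0), peak_index = integer(0),
      threshold_time = numeric(0), peak_time = numeric(0)))
  }
  m <- do.call(rbind, out)
  tibble(threshold_index = as.integer(m[, 1]), peak_index = as.integer(m[, 2]),
    threshold_time = m[, 3], peak_time = m[, 4])
}

#' Measure action-potential waveform features
#'
#' For each detection from [detect_aps()], measures the AP feature set with
#' all amplitudes referenced to the AP threshold: the membrane potential at
#' the dV/dt threshold crossing (linearly interpolated between bracketing
#' samples). Half width is the interpolated trace width at threshold plus
#' half the amplitude. The afterhyperpolarization (AHP) is the voltage
#' minimum between the AP peak and the next AP's threshold (or the window
#' end); its amplitude is threshold minus trough and its delay is measured
#' from the threshold crossing. When the trace is still falling at the
#' search boundary the AHP fields are `NA` and `ahp_flagged` is set.
#'
#' @param tr A voltage [trace()].
#' @param detections Tibble from [detect_aps()].
#' @param window Analysis window `(start, end)`, s; bounds the AHP search
#'   for the last AP.
#' @param dvdt_threshold Must match the value used for detection.
#' @return A tibble with one row per AP: `threshold_time`, `threshold_V`,
#'   `peak_time`, `peak_V`, `amplitude`, `half_width` (ms), `ahp_V`,
#'   `ahp_amplitude`, `ahp_delay` (ms), `ahp_flagged`.
#' @export
ap_features <- function(tr, detections, window, dvdt_threshold = 20) {
  stopifnot(inherits(tr, "pk_trace"))
  v <- tr$samples
  dt_ms <- tr$dt * 1000
  tt <- trace_time(tr)
  d <- central_dvdt(v, dt_ms)
  end_idx <- min(length(v), floor(window[2] / tr$dt) + 1L)
  nr <- nrow(detections)
  rows <- vector("list", nr)
  for (k in seq_len(nr)) {
    i <- detections$threshold_index[k]
    peak <- detections$peak_index[k]
    frac <- if (d[i] != d[i - 1L]) (dvdt_threshold - d[i - 1L]) / (d[i] - d[i - 1L]) else 1
    thr_t <- tt[i - 1L] + frac * tr$dt
    thr_v <- v[i - 1L] + frac * (v[i] - v[i - 1L])
    peak_v <- v[peak]
    amp <- peak_v - thr_v
    half_level <- thr_v + amp / 2
    # rising crossing of the half-amplitude level
    seg <- i:peak
    ri <- seg[which(v[seg] >= half_level)[1]]
    t_rise <- if (ri > 1 && v[ri] != v[ri - 1L]) {
      tt[ri - 1L] + (half_level - v[ri - 1L]) / (v[ri] - v[ri - 1L]) * tr$dt
    } else tt[ri]
    # falling crossing after the peak
    stop_idx <- if (k < nr) detections$threshold_index[k + 1L] else end_idx
    seg2 <- peak:stop_idx
    fi_rel <- which(v[seg2] <= half_level)[1]
    if (is.na(fi_rel)) {
      t_fall <- NA_real_
    } else {
      fi <- seg2[fi_rel]
      t_fall <- tt[fi - 1L] + (half_level - v[fi - 1L]) / (v[fi] - v[fi - 1L]) * tr$dt
    }
    half_width <- (t_fall - t_rise) * 1000
    # AHP trough between peak and next threshold / window end
    trough_rel <- which.min(v[seg2])
    trough <- seg2[trough_rel]
    ahp_flagged <- trough == stop_idx && k == nr
    if (ahp_flagged) {
      ahp_v <- ahp_amp <- ahp_delay <- NA_real_
    } else {
      ahp_v <- v[trough]
      ahp_amp <- thr_v - ahp_v
      ahp_delay <- (tt[trough] - thr_t) * 1000
    }
    rows[[k]] <- tibble(threshold_time = thr_t, threshold_V = thr_v,
      peak_time = tt[peak], peak_V = peak_v, amplitude = amp,
      half_width = half_width, ahp_V = ahp_v, ahp_amplitude = ahp_amp,
      ahp_delay = ahp_delay, ahp_flagged = ahp_flagged)
  }
  if (!nr) {
    return(tibble(threshold_time = numeric(0), threshold_V = numeric(0),
      peak_time = numeric(0), peak_V = numeric(0), amplitude = numeric(0),
      half_width = numeric(0), ahp_V = numeric(0), ahp_amplitude = numeric(0),
      ahp_delay = numeric(0), ahp_flagged = logical(0)))
  }
  dplyr::bind_rows(rows)
}

#' Rheobase and excitability analysis of a current-clamp step family
#'
#' Rheobase is the lowest step current whose sweep yields at least one
#' valid AP detection; the AP feature set is measured from the first AP of
#' that sweep. The input/output curve counts APs per injection level. The
#' accommodation index is computed from the lowest injection evoking at
#' least `min_aps` APs.
#'
#' @param series A current-clamp [sweep_series()] with increasing step
#'   levels (pA).
#' @param min_aps Minimum APs for the accommodation index (default 6).
#' @param ... Passed to [detect_aps()].
#' @return An object of class `pk_excitability`: a list with `rheobase`
#'   (pA, `NA` if no sweep spikes), `io_curve` (tibble `injection`,
#'   `n_ap`), `first_ap` (one-row feature tibble or `NULL`),
#'   `accommodation_index`, `accommodation_injection`,
#'   `accommodation_index_inverse` (the first-over-last ordering), and
#'   `accommodation_index_top` (same ratio at the strongest injection).
#' @export
rheobase_analysis <- function(series, min_aps = 6, ...) {
  stopifnot(inherits(series, "pk_sweeps"))
  if (series$sweeps[[1]]$role != "membrane_voltage") {
    stop("rheobase analysis requires a current-clamp (voltage) series",
      call. = FALSE)
  }
  win <- c(series$protocol$step_onset, series$protocol$step_offset)
  lev <- series$protocol$step_levels
  dets <- lapply(series$sweeps, detect_aps, window = win, ...)
  counts <- vapply(dets, nrow, integer(1))
  io <- tibble(injection = lev, n_ap = counts)
  spiking <- which(counts >= 1L)
  rheobase <- if (length(spiking)) lev[spiking[1]] else NA_real_
  first_ap <- NULL
  if (length(spiking)) {
    s1 <- spiking[1]
    first_ap <- ap_features(series$sweeps[[s1]], dets[[s1]][1, ], win, ...)
  }
  acc <- NA_real_; acc_inv <- NA_real_; acc_inj <- NA_real_
  acc_sweep <- which(counts >= min_aps)
  if (length(acc_sweep)) {
    st <- dets[[acc_sweep[1]]]$threshold_time
    acc <- accommodation_index(st, min_aps = min_aps)
    acc_inv <- accommodation_index(st, min_aps = min_aps,
      direction = "first_over_last")
    acc_inj <- lev[acc_sweep[1]]
  }
  # accommodation at the strongest common injection (useful for cohort
  # comparisons where the lowest >= min_aps sweep differs between cells)
  acc_top <- accommodation_index(dets[[length(dets)]]$threshold_time,
    min_aps = min_aps)
  structure(list(rheobase = rheobase, io_curve = io, first_ap = first_ap,
    accommodation_index = acc, accommodation_index_inverse = acc_inv,
    accommodation_injection = acc_inj, accommodation_index_top = acc_top,
    detections = dets, window = win),
    class = "pk_excitability")
}

#' @export
print.pk_excitability <- function(x, ...) {
  cat("<pk_excitability>\n")
  cat("  rheobase:", if (is.na(x$rheobase)) "none (no sweep spiked)" else
    paste0(x$rheobase, " pA"), "\n")
  cat("  max AP count:", max(x$io_curve$n_ap), "\n")
  if (!is.na(x$accommodation_index)) {
    cat(sprintf("  accommodation index: %.3f (at %g pA)\n",
      x$accommodation_index, x$accommodation_injection))
  }
  invisible(x)
}

#' @method tidy pk_excitability
#' @export
tidy.pk_excitability <- function(x, ...) x$io_curve

#' @method glance pk_excitability
#' @export
glance.pk_excitability <- function(x, ...) {
  fa <- x$first_ap
  tibble(rheobase = x$rheobase,
    max_n_ap = max(x$io_curve$n_ap),
    n_ap_total = sum(x$io_curve$n_ap),
    threshold_V = if (is.null(fa)) NA_real_ else fa$threshold_V,
    amplitude = if (is.null(fa)) NA_real_ else fa$amplitude,
    half_width = if (is.null(fa)) NA_real_ else fa$half_width,
    ahp_amplitude = if (is.null(fa)) NA_real_ else fa$ahp_amplitude,
    ahp_delay = if (is.null(fa)) NA_real_ else fa$ahp_delay,
    accommodation_index = x$accommodation_index,
    accommodation_index_top = x$accommodation_index_top)
}

#' @method autoplot pk_excitability
#' @export
autoplot.pk_excitability <- function(object, ...) {
  ggplot2::ggplot(object$io_curve, ggplot2::aes(.data$injection, .data$n_ap)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "AP count") +
    ggplot2::theme_minimal()
}

#' Input/output curve from a held membrane potential
#'
#' AP counts per injection for families recorded from a potential
#' maintained near `held_V` by constant current injection. Sweeps whose
#' pre-step baseline deviates from `held_V` by more than `tolerance` mV are
#' flagged and excluded from the curve.
#'
#' @param series A current-clamp [sweep_series()].
#' @param held_V Target held potential, mV (default -70).
#' @param tolerance Allowed baseline deviation, mV (default 3).
#' @param ... Passed to [detect_aps()].
#' @return A tibble with `injection`, `n_ap`, `baseline_V`, `included`.
#' @export
io_curve_from_held <- function(series, held_V = -70, tolerance = 3, ...) {
  stopifnot(inherits(series, "pk_sweeps"))
  win <- c(series$protocol$step_onset, series$protocol$step_offset)
  base_win <- floor(series$protocol$step_onset / sweep_dt(series))
  purrr::map2_dfr(series$sweeps, series$protocol$step_levels, function(tr, lev) {
    baseline <- mean(tr$samples[seq_len(max(base_win, 1))])
    ok <- abs(baseline - held_V) <= tolerance
    tibble(injection = lev,
      n_ap = if (ok) nrow(detect_aps(tr, win, ...)) else NA_integer_,
      baseline_V = baseline, included = ok)
  })
}

#' Accommodation index of a spike train
#'
#' Ratio of the time interval between the last pair of APs to the interval
#' between the first pair, for trains of at least `min_aps` APs evoked by a
#' sustained current injection. Values above 1 indicate spike-frequency
#' adaptation. The text definition leaves the ratio's orientation open;
#' `direction = "first_over_last"` gives the reciprocal.
#'
#' @param ap_times AP threshold times, s (sorted).
#' @param min_aps Minimum number of APs (default 6).
#' @param direction `"last_over_first"` (default) or `"first_over_last"`.
#' @return Dimensionless ratio, or `NA` if fewer than `min_aps` APs.
#' @export
accommodation_index <- function(ap_times, min_aps = 6,
                                direction = c("last_over_first", "first_over_last")) {
  direction <- match.arg(direction)
  n <- length(ap_times)
  if (n < min_aps) return(NA_real_)
  r <- (ap_times[n] - ap_times[n - 1]) / (ap_times[2] - ap_times[1])
  if (direction == "first_over_last") 1 / r else r
}
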