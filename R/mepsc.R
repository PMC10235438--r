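rolling_baseline <- function(x, dt, window_ms = 50) {
  # running median over ~window_ms, computed on a decimated grid for speed
  dec <- max(1L, round(5e-4 / dt))          # ~0.5 ms grid
  xd <- x[seq(1L, length(x), by = dec)]
  k <- max(3L, round(window_ms / 1000 / (dt * dec)))
  if (k %% 2L == 0L) k <- k + 1L
  bd <- stats::runmed(xd, k, endrule = "median")
  if (dec == 1L) return(bd)
  approx(seq(1L, length(x), by = dec), bd, xout = seq_along(x), rule = 2)$y
}

#' Classify events under the 10 ms summation rule
#'
#' Events occurring less than 10 ms after the previous event show
#' summation and are excluded from amplitude (but not frequency) analysis.
#'
#' @param onsets Sorted event onset times, s.
#' @param min_interval Exclusion interval, s (default 0.010).
#' @return Logical vector: `TRUE` where the event's amplitude is included.
#' @export
mark_summation <- function(onsets, min_interval = 0.010) {
  if (!length(onsets)) return(logical(0))
  c(TRUE, diff(onsets) >= min_interval)
}

#' Detect miniature EPSCs
#'
#' Threshold-based event detection on a voltage-clamp current trace held at
#' a fixed potential: the trace is lightly smoothed, a running-median
#' baseline is subtracted, and inward deflections exceeding `threshold`
#' below baseline become candidate events. A candidate is kept when its
#' onset-to-peak rise time falls within `rise_bounds`. Onset is the last
#' baseline crossing before the peak (or the inter-event minimum for
#' summated events). The 10 ms summation rule populates
#' `amplitude_included`.
#'
#' @param tr A current [trace()].
#' @param threshold Detection threshold below baseline, pA (default 5).
#' @param rise_bounds Accepted onset-to-peak rise time, ms (default 0.3..5).
#' @param smooth_ms Boxcar width for peak detection, ms.
#' @param baseline_ms Running-baseline window, ms.
#' @param slope_threshold Onset-candidate threshold on the rising slope of
#'   the deflection, pA/ms; defaults to `threshold` per ms. The slope gate
#'   is what separates new events (sharp rise) from noise ripples on the
#'   decay of a previous event.
#' @return A `pk_minis` tibble: `onset`, `peak` (s), `amplitude` (pA,
#'   positive magnitude), `rise_ms`, `preceding_interval` (s, `NA` for the
#'   first event), `amplitude_included`.
#' @export
detect_minis <- function(tr, threshold = 5, rise_bounds = c(0.3, 5),
                         smooth_ms = 1, baseline_ms = 50,
                         slope_threshold = threshold) {
  stopifnot(inherits(tr, "pk_trace"))
  if (tr$role != "membrane_current") {
    stop("mEPSC detection requires a current trace", call. = FALSE)
  }
  dt <- tr$dt
  x <- tr$samples
  n <- length(x)
  k <- max(round(smooth_ms / 1000 / dt), 1L)
  xs <- boxcar_smooth(x, k)
  base <- rolling_baseline(xs, dt, baseline_ms)
  defl <- base - xs                       # positive for inward events
  # fine-smoothed deflection for amplitude measurement
  kf <- max(round(0.25e-3 / dt), 1L)
  defl_f <- base - boxcar_smooth(x, kf)
  # rising slope of the deflection (pA/ms) over a ~0.25 ms lag
  lag <- max(round(0.25e-3 / dt), 1L)
  slope <- c(rep(0, lag), (defl[(1 + lag):n] - defl[1:(n - lag)]) /
    (lag * dt * 1000))
  cand <- which(slope[-1] >= slope_threshold & slope[-n] < slope_threshold) + 1L
  if (!length(cand)) return(empty_minis())
  wpk <- round(5e-3 / dt)                 # peak search span, 5 ms
  rows <- vector("list", length(cand))
  prev_peak <- 1L
  for (e in seq_along(cand)) {
    i <- cand[e]
    if (i <= prev_peak + lag) next
    hi <- min(i + wpk, n)
    p <- (i - 1L) + which.max(defl[i:hi])
    if (p == prev_peak || defl[p] < threshold) next
    lo <- max(prev_peak, p - round(0.02 / dt))
    seg <- defl[lo:p]
    below <- which(seg <= 0)
    onset_idx <- if (length(below)) lo + below[length(below)] - 1L else
      lo + which.min(seg) - 1L
    rise_ms <- (p - onset_idx) * dt * 1000
    prev_peak <- p
    if (rise_ms < rise_bounds[1] || rise_ms > rise_bounds[2]) next
    # amplitude from the lightly smoothed trace near the located peak
    w <- max(round(0.5e-3 / dt), 1L)
    amp <- max(defl_f[max(1L, p - w):min(length(defl_f), p + w)])
    rows[[e]] <- c(onset_idx, p, amp, rise_ms)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_minis())
  m <- do.call(rbind, rows)
  onset_t <- (m[, 1] - 1) * dt
  out <- tibble(onset = onset_t, peak = (m[, 2] - 1) * dt,
    amplitude = m[, 3], rise_ms = m[, 4],
    preceding_interval = c(NA_real_, diff(onset_t)),
    amplitude_included = mark_summation(onset_t))
  class(out) <- c("pk_minis", class(out))
  out
}

empty_minis <- function() {
  out <- tibble(onset = numeric(0), peak = numeric(0), amplitude = numeric(0),
    rise_ms = numeric(0), preceding_interval = numeric(0),
    amplitude_included = logical(0))
  class(out) <- c("pk_minis", class(out))
  out
}

#' Summarize a miniature EPSC recording
#'
#' Frequency and inter-event statistics use all events; amplitude
#' statistics use only events passing the 10 ms summation rule. The
#' `sufficient` flag marks recordings with at least `min_events` events.
#'
#' @param events A `pk_minis` tibble from [detect_minis()] (sorted).
#' @param duration Recording duration, s.
#' @param min_events Sufficiency rule (default 200).
#' @return A one-row tibble: `n_events`, `frequency` (Hz, event span
#'   based), `mean_iei`, `median_iei` (s), `n_amplitude`,
#'   `amplitude_mean`, `amplitude_median`, `amplitude_sd` (pA),
#'   `sufficient`.
#' @export
mini_summary <- function(events, duration, min_events = 200) {
  n <- nrow(events)
  iei <- diff(events$onset)
  freq <- if (n >= 2) (n - 1) / (events$onset[n] - events$onset[1]) else
    n / duration
  amps <- events$amplitude[events$amplitude_included]
  tibble(n_events = n, frequency = freq,
    mean_iei = if (length(iei)) mean(iei) else NA_real_,
    median_iei = if (length(iei)) median(iei) else NA_real_,
    n_amplitude = length(amps),
    amplitude_mean = if (length(amps)) mean(amps) else NA_real_,
    amplitude_median = if (length(amps)) median(amps) else NA_real_,
    amplitude_sd = if (length(amps) > 1) sd(amps) else NA_real_,
    sufficient = n >= min_events)
}

#' @method autoplot pk_minis
#' @export
autoplot.pk_minis <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$amplitude)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey40") +
    ggplot2::labs(x = "mEPSC amplitude (pA)", y = "events") +
    ggplot2::theme_minimal()
}
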