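#' Construct a recording trace
#'
#' A trace is one uniformly sampled channel of a recording: membrane voltage
#' (mV), membrane current (pA), a command waveform, or a fluorescence signal.
#'
#' @param samples Numeric vector of sampled values (at least 2).
#' @param dt Sampling interval in seconds (e.g. `4e-6` for 250 kHz).
#' @param units One of `"mV"`, `"pA"`, `"dF/F"`, `"AU"`.
#' @param role One of `"membrane_voltage"`, `"membrane_current"`,
#'   `"command"`, `"fluorescence"`. Units must be consistent with the role
#'   (voltage traces are in mV, current traces in pA).
#' @param lowpass_cutoff Acquisition low-pass filter cutoff in Hz, or `NULL`
#'   if unknown/unfiltered.
#' @return An object of class `pk_trace`.
#' @examples
#' tr <- trace(rep(-70, 1000), dt = 1e-4, units = "mV", role = "membrane_voltage")
#' tr
#' @export
trace <- function(samples, dt, units, role, lowpass_cutoff = NULL) {
  units <- match.arg(units, c("mV", "pA", "dF/F", "AU"))
  role <- match.arg(role,
    c("membrane_voltage", "membrane_current", "command", "fluorescence"))
  if (!is.numeric(samples) || length(samples) < 2) {
    stop("`samples` must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  ok_units <- switch(role,
    membrane_voltage = "mV",
    membrane_current = "pA",
    command = c("mV", "pA"),
    fluorescence = c("dF/F", "AU"))
  if (!units %in% ok_units) {
    stop(sprintf("units '%s' inconsistent with role '%s'", units, role),
      call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), dt = as.numeric(dt),
      units = units, role = role,
      lowpass_cutoff = if (is.null(lowpass_cutoff)) NULL else as.numeric(lowpass_cutoff)),
    class = "pk_trace")
}

#' @export
print.pk_trace <- function(x, ...) {
  cat(sprintf("<pk_trace> %s [%s], %d samples @ %.6g s (%.3g s total)\n",
    x$role, x$units, length(x$samples), x$dt, length(x$samples) * x$dt))
  invisible(x)
}

#' Sample times of a trace
#'
#' Time of each sample in seconds, with t = 0 at the first sample.
#'
#' @param tr A `pk_trace`.
#' @return Numeric vector of times (s).
#' @export
trace_time <- function(tr) {
  stopifnot(inherits(tr, "pk_trace"))
  (seq_along(tr$samples) - 1) * tr$dt
}

#' @method as_tibble pk_trace
#' @export
as_tibble.pk_trace <- function(x, ...) {
  tibble(time = trace_time(x), value = x$samples)
}

#' Construct a step protocol
#'
#' Describes a family of square command steps: a holding level, the step
#' onset and offset times, and the ordered step levels (pA in current clamp,
#' mV in voltage clamp).
#'
#' @param holding Holding level in native units.
#' @param step_onset,step_offset Step start and end, seconds from sweep start.
#' @param step_levels Ordered numeric vector of step levels, one per sweep.
#'   Must be strictly monotone for families used in slope fits.
#' @return An object of class `pk_protocol`.
#' @export
step_protocol <- function(holding, step_onset, step_offset, step_levels) {
  if (!(step_onset >= 0 && step_onset < step_offset)) {
    stop("require 0 <= step_onset < step_offset", call. = FALSE)
  }
  if (length(step_levels) < 1 || anyNA(step_levels)) {
    stop("`step_levels` must be a non-empty numeric vector", call. = FALSE)
  }
  d <- diff(step_levels)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("`step_levels` must be strictly monotone", call. = FALSE)
  }
  structure(
    list(holding = as.numeric(holding), step_onset = as.numeric(step_onset),
      step_offset = as.numeric(step_offset),
      step_levels = as.numeric(step_levels)),
    class = "pk_protocol")
}

#' Construct a sweep series
#'
#' An ordered set of sweeps acquired under a shared step protocol, one sweep
#' per protocol step level, plus recording-condition metadata.
#'
#' @param sweeps List of [trace()] objects sharing `dt` and length.
#' @param protocol A [step_protocol()] with one level per sweep.
#' @param metadata Named list of recording conditions. Recognized fields:
#'   `temperature` (deg C), `blockers` (character), `junction_corrected`
#'   (logical, default `FALSE`), `access_resistance` (MOhm),
#'   `holding_current` (pA).
#' @return An object of class `pk_sweeps`.
#' @export
sweep_series <- function(sweeps, protocol, metadata = list()) {
  if (!length(sweeps)) stop("`sweeps` must be a non-empty list", call. = FALSE)
  if (!all(vapply(sweeps, inherits, logical(1), "pk_trace"))) {
    stop("all sweeps must be pk_trace objects", call. = FALSE)
  }
  stopifnot(inherits(protocol, "pk_protocol"))
  dts <- vapply(sweeps, `[[`, numeric(1), "dt")
  lens <- vapply(sweeps, function(s) length(s$samples), integer(1))
  if (length(unique(dts)) != 1L || length(unique(lens)) != 1L) {
    stop("all sweeps must share dt and length", call. = FALSE)
  }
  if (length(sweeps) != length(protocol$step_levels)) {
    stop("need exactly one sweep per protocol step level", call. = FALSE)
  }
  dur <- lens[1] * dts[1]
  if (protocol$step_offset > dur + 1e-12) {
    stop("protocol step_offset exceeds sweep duration", call. = FALSE)
  }
  if (is.null(metadata$junction_corrected)) metadata$junction_corrected <- FALSE
  structure(list(sweeps = sweeps, protocol = protocol, metadata = metadata),
    class = "pk_sweeps")
}

#' @export
print.pk_sweeps <- function(x, ...) {
  cat(sprintf(
    "<pk_sweeps> %d sweeps of %s [%s], dt = %.6g s\n  steps %s to %s (%d levels), onset %.3g s, offset %.3g s\n",
    length(x$sweeps), x$sweeps[[1]]$role, x$sweeps[[1]]$units,
    x$sweeps[[1]]$dt, format(min(x$protocol$step_levels)),
    format(max(x$protocol$step_levels)), length(x$protocol$step_levels),
    x$protocol$step_onset, x$protocol$step_offset))
  if (isTRUE(x$metadata$junction_corrected)) cat("  junction-corrected\n")
  invisible(x)
}

#' Tidy a sweep series into a long table
#'
#' @param x A `pk_sweeps`.
#' @param ... Unused.
#' @return A tibble with columns `sweep`, `step_level`, `time`, `value`.
#' @method as_tibble pk_sweeps
#' @export
as_tibble.pk_sweeps <- function(x, ...) {
  tt <- trace_time(x$sweeps[[1]])
  purrr::map2_dfr(seq_along(x$sweeps), x$protocol$step_levels, function(i, lev) {
    tibble(sweep = i, step_level = lev, time = tt,
      value = x$sweeps[[i]]$samples)
  })
}

#' @method autoplot pk_sweeps
#' @export
autoplot.pk_sweeps <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
      group = .data$sweep, colour = .data$step_level)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
      y = sprintf("%s (%s)", object$sweeps[[1]]$role, object$sweeps[[1]]$units),
      colour = "step") +
    ggplot2::theme_minimal()
}

sweep_dt <- function(series) series$sweeps[[1]]$dt
sweep_len <- function(series) length(series$sweeps[[1]]$samples)
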