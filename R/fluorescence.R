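#' Compute dF/F0 for a fluorescence trace
#'
#' `(F - F0) / F0` with `F` the background-subtracted fluorescence and `F0`
#' a baseline estimate: either a rolling low percentile (robust to sparse
#' transients; the default, 10th percentile over a trailing 60 s window) or
#' the mean over a fixed window.
#'
#' @param tr A fluorescence [trace()].
#' @param background Scalar background level, or a vector/trace of the same
#'   length.
#' @param f0_method `"rolling_percentile"` or `"fixed_window"`.
#' @param f0_window Rolling window length, s.
#' @param percentile Rolling percentile in (0, 1).
#' @param fixed_window `(start, end)` s for `f0_method = "fixed_window"`.
#' @return A [trace()] with units `dF/F`.
#' @export
dff <- function(tr, background = 0,
                f0_method = c("rolling_percentile", "fixed_window"),
                f0_window = 60, percentile = 0.1, fixed_window = c(0, 60)) {
  stopifnot(inherits(tr, "pk_trace"))
  f0_method <- match.arg(f0_method)
  bg <- if (inherits(background, "pk_trace")) background$samples else background
  f <- tr$samples - bg
  if (f0_method == "rolling_percentile") {
    w <- max(3L, round(f0_window / tr$dt))
    f0 <- zoo::rollapplyr(zoo::zoo(f), width = w, FUN = quantile,
      probs = percentile, names = FALSE, partial = TRUE)
    f0 <- as.numeric(f0)
  } else {
    tt <- trace_time(tr)
    sel <- tt >= fixed_window[1] & tt < fixed_window[2]
    f0 <- rep(mean(f[sel]), length(f))
  }
  if (any(f0 <= 0)) {
    stop("F0 <= 0: background over-subtraction or empty baseline", call. = FALSE)
  }
  trace((f - f0) / f0, dt = tr$dt, units = "dF/F", role = "fluorescence")
}

#' Across-ROI mean dF/F trace
#'
#' @param rois A `pk_rois` set (see [simulate_calcium_field()]).
#' @param ... Passed to [dff()].
#' @return A [trace()] holding the mean dF/F over all ROIs.
#' @export
population_dff <- function(rois, ...) {
  stopifnot(inherits(rois, "pk_rois"))
  mats <- vapply(rois$traces,
    function(tr) dff(tr, background = rois$background, ...)$samples,
    numeric(length(rois$traces[[1]]$samples)))
  trace(rowMeans(mats), dt = 1 / rois$fps, units = "dF/F", role = "fluorescence")
}

find_transients <- function(x, fps, min_separation, floor_level) {
  # peaks measured baseline-to-peak: the segment median removes the common
  # offset left by percentile-based F0 estimation
  xc <- x - median(x)
  pk <- pracma::findpeaks(xc, minpeakheight = floor_level,
    minpeakdistance = max(round(min_separation * fps), 1L))
  if (is.null(pk)) return(tibble(index = integer(0), peak = numeric(0)))
  ord <- order(pk[, 2])
  tibble(index = as.integer(pk[ord, 2]), peak = pk[ord, 1])
}

#' Reference transient peak after stimulation
#'
#' Population-mean dF/F peak of the first calcium transient after the
#' stimulation marker (the first transient after bicuculline addition, the
#' reference for the synchrony criterion).
#'
#' @param rois A `pk_rois` set with `bic_start` set.
#' @param min_separation Minimum peak separation, s.
#' @param noise_mult Detection floor in multiples of the pre-stimulation
#'   noise scale.
#' @param ... Passed to [dff()].
#' @return Peak dF/F of the first post-marker transient.
#' @export
reference_peak <- function(rois, min_separation = 2, noise_mult = 5, ...) {
  stopifnot(inherits(rois, "pk_rois"))
  if (is.null(rois$bic_start)) {
    stop("no stimulation marker (`bic_start`) in this ROI set", call. = FALSE)
  }
  pop <- population_dff(rois, ...)
  pre <- pop$samples[seq_len(rois$bic_start - 1L)]
  post <- pop$samples[rois$bic_start:length(pop$samples)]
  floor_level <- noise_mult * stats::mad(pre)
  tp <- find_transients(post, rois$fps, min_separation, floor_level)
  if (!nrow(tp)) {
    stop("no transient detected after the stimulation marker", call. = FALSE)
  }
  tp$peak[1]
}

#' Detect synchronous population calcium events
#'
#' Candidate transients are prominence-screened peaks of the across-ROI
#' mean dF/F trace over the unstimulated segment, at least `min_separation`
#' apart; a candidate is a synchronous event when its population peak is at
#' least `ratio` (default 1/10) of the reference transient peak. Frequency
#' is accepted events per minute of the unstimulated segment.
#'
#' @param rois A `pk_rois` set.
#' @param reference Reference peak dF/F (see [reference_peak()]).
#' @param ratio Acceptance criterion as a fraction of `reference`.
#' @param min_separation Minimum event separation, s.
#' @param ... Passed to [dff()].
#' @return A `pk_synchrony` object: `event_times` (s), `event_peaks`,
#'   `frequency_per_min`, `reference_peak`, `criterion_ratio`, `segment_s`.
#' @export
detect_synchronous_events <- function(rois, reference, ratio = 0.1,
                                      min_separation = 2, ...) {
  stopifnot(inherits(rois, "pk_rois"))
  if (!is.finite(reference) || reference <= 0) {
    stop("`reference` must be a positive dF/F peak", call. = FALSE)
  }
  pop <- population_dff(rois, ...)
  end <- if (is.null(rois$bic_start)) length(pop$samples) else rois$bic_start - 1L
  seg <- pop$samples[seq_len(end)]
  if (end / rois$fps < 60) {
    stop("pre-stimulation segment must be at least 60 s", call. = FALSE)
  }
  tp <- find_transients(seg, rois$fps, min_separation,
    floor_level = ratio * reference / 2)
  keep <- tp$peak >= ratio * reference
  structure(list(
    event_times = (tp$index[keep] - 1) / rois$fps,
    event_peaks = tp$peak[keep],
    frequency_per_min = sum(keep) / (end / rois$fps / 60),
    reference_peak = reference, criterion_ratio = ratio,
    segment_s = end / rois$fps), class = "pk_synchrony")
}

#' @export
print.pk_synchrony <- function(x, ...) {
  cat(sprintf(
    "<pk_synchrony> %d events in %.1f min (%.3g per min); criterion %.2g x reference %.3g dF/F\n",
    length(x$event_times), x$segment_s / 60, x$frequency_per_min,
    x$criterion_ratio, x$reference_peak))
  invisible(x)
}

#' @method tidy pk_synchrony
#' @export
tidy.pk_synchrony <- function(x, ...) {
  tibble(event_time = x$event_times, peak_dff = x$event_peaks)
}

#' @method glance pk_synchrony
#' @export
glance.pk_synchrony <- function(x, ...) {
  tibble(n_events = length(x$event_times),
    frequency_per_min = x$frequency_per_min,
    reference_peak = x$reference_peak, criterion_ratio = x$criterion_ratio,
    segment_s = x$segment_s)
}

#' Nuclear-to-cytoplasmic intensity ratio of a cell
#'
#' The nucleus is segmented on the nuclear-stain channel (Otsu threshold,
#' holes filled, largest connected component); the cytoplasm is the soma
#' region minus the nucleus, with the soma taken as a fixed-radius dilation
#' of the nucleus when no mask is supplied. Mean marker intensities over
#' the two masks give the ratio.
#'
#' @param image `h x w x 2` array: marker channel, nuclear-stain channel.
#' @param soma_mask Optional logical matrix delimiting the soma.
#' @param dilate_px Dilation radius for the automatic soma region, px.
#' @return A one-row tibble: `nuclear_mean`, `cytoplasmic_mean`, `ratio`.
#' @export
nuc_cyto_ratio <- function(image, soma_mask = NULL, dilate_px = 10) {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 2)
  marker <- image[, , 1]
  stain <- image[, , 2]
  rng <- range(stain)
  if (diff(rng) <= 0) stop("nuclear-stain channel is constant", call. = FALSE)
  stain01 <- (stain - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(stain01))
  nuc <- EBImage::fillHull(stain01 > thr)
  lab <- EBImage::bwlabel(nuc)
  if (max(lab) == 0) stop("empty nucleus mask", call. = FALSE)
  areas <- tabulate(lab[lab > 0])
  nuc_mask <- lab == which.max(areas)
  if (is.null(soma_mask)) {
    brush <- EBImage::makeBrush(2 * dilate_px + 1, shape = "disc")
    soma_mask <- EBImage::dilate(nuc_mask, brush) > 0
  }
  cyto_mask <- soma_mask & !(nuc_mask > 0)
  if (!any(cyto_mask)) stop("empty cytoplasm mask", call. = FALSE)
  nm <- mean(marker[nuc_mask > 0])
  cm <- mean(marker[cyto_mask])
  if (cm <= 0) stop("non-positive cytoplasmic mean", call. = FALSE)
  tibble(nuclear_mean = nm, cytoplasmic_mean = cm, ratio = nm / cm)
}
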