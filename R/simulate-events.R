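biexp_peak_factor <- function(tau_rise, tau_decay) {
  tstar <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  exp(-tstar / tau_decay) - exp(-tstar / tau_rise)
}

#' Simulate a miniature EPSC recording
#'
#' A homogeneous Poisson train of biexponential inward current deflections
#' on a zero-pA baseline with white Gaussian noise, as recorded under
#' action-potential blockade at a fixed holding potential. Event kernels
#' are normalized so each event's true baseline-to-peak amplitude equals
#' its drawn amplitude.
#'
#' @param rate Event rate, Hz.
#' @param amp_mean,amp_sd Amplitude distribution (pA, positive magnitudes;
#'   draws are truncated at 20% of the mean).
#' @param tau_rise,tau_decay Kernel time constants, ms (`tau_rise <
#'   tau_decay`).
#' @param duration Recording length, s.
#' @param noise_sd Baseline noise s.d., pA.
#' @param dt Sampling interval, s (default 5e-5: 20 kHz).
#' @param seed RNG seed.
#' @return A list with `trace` (current [trace()]) and `truth`: a tibble of
#'   event `time` (s), `amplitude` (pA) and `amplitude_included` (FALSE for
#'   events < 10 ms after the previous one), plus attribute
#'   `"short_duration"` when fewer than one event is expected.
#' @export
simulate_mepsc <- function(rate, amp_mean = 20, amp_sd = 5, tau_rise = 0.5,
                           tau_decay = 5, duration = 600, noise_sd = 2,
                           dt = 5e-5, seed = 1L) {
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (tau_rise >= tau_decay) stop("need tau_rise < tau_decay", call. = FALSE)
  set.seed(seed)
  n_ev <- rpois(1, rate * duration)
  times <- sort(runif(n_ev, 0, max(duration - 0.05, 0)))
  amps <- rnorm(n_ev, amp_mean, amp_sd)
  amps <- pmax(amps, 0.2 * amp_mean)
  n <- round(duration / dt)
  cur <- rnorm(n, sd = noise_sd)
  pk <- biexp_peak_factor(tau_rise, tau_decay)
  span <- round(8 * tau_decay / 1000 / dt)
  for (k in seq_len(n_ev)) {
    i0 <- floor(times[k] / dt) + 1
    idx <- i0:min(i0 + span, n)
    ts <- ((idx - i0) * dt) * 1000
    cur[idx] <- cur[idx] -
      amps[k] * (exp(-ts / tau_decay) - exp(-ts / tau_rise)) / pk
  }
  truth <- tibble(time = times, amplitude = amps,
    amplitude_included = if (n_ev) c(TRUE, diff(times) >= 0.010) else logical(0))
  attr(truth, "short_duration") <- rate * duration < 1
  list(
    trace = trace(cur, dt = dt, units = "pA", role = "membrane_current",
      lowpass_cutoff = 2000),
    truth = truth)
}

#' Simulate a multi-ROI calcium-imaging field
#'
#' Each region of interest (ROI, one cell soma) carries every synchronous
#' population event: a single-exponential calcium kernel (decay 1 s),
#' jittered in time and amplitude-scaled per cell, riding on an ROI-specific
#' baseline with Gaussian noise. A trailing segment after `duration`
#' contains one large reference transient emulating the first transient
#' after bicuculline, with population-mean dF/F peak `bic_peak`. The
#' calcium kernel has a 0.25 s rise and 1 s exponential decay, normalized
#' to unit peak, so sampled peak amplitudes are robust to frame timing.
#'
#' @param n_rois Number of ROIs (15-30, the typical cells per field).
#' @param event_times Synchronous event onsets, s (must be > 5 s apart and
#'   inside `duration`).
#' @param event_amp Population-mean event amplitude, dF/F units.
#' @param jitter_sd Per-cell onset jitter s.d., s.
#' @param noise_sd Fluorescence noise s.d. in dF/F units of each ROI's
#'   baseline.
#' @param bic_peak Reference transient population-mean peak, dF/F.
#' @param fps Frame rate, Hz. @param duration Unstimulated segment, s.
#' @param amp_scale_sd Per-cell amplitude scaling s.d. (mean 1).
#' @param background Additive background fluorescence, AU.
#' @param seed RNG seed.
#' @return A list with `rois` (a `pk_rois` object: fluorescence traces, the
#'   background level, and `bic_start`, the sample index where stimulation
#'   begins) and `truth` (event times, population amplitudes, a
#'   `supra_criterion` flag per event under the 1/10 rule, `bic_peak`, and
#'   the planted event frequency per minute).
#' @export
simulate_calcium_field <- function(n_rois = 20, event_times = c(60, 200, 350, 500),
                                   event_amp = 0.5, jitter_sd = 0.1,
                                   noise_sd = 0.02, bic_peak = 1.0, fps = 2,
                                   duration = 600, amp_scale_sd = 0.2,
                                   background = 10, seed = 1L) {
  if (n_rois < 15 || n_rois > 30) {
    stop("`n_rois` must be within 15..30 (cells per imaging field)", call. = FALSE)
  }
  if (length(event_times) && any(diff(sort(event_times)) <= 5)) {
    stop("event times must be separated by more than 5 s", call. = FALSE)
  }
  post <- 60
  n <- round((duration + post) * fps)
  if (n < 10) stop("fps * duration must give at least 10 samples", call. = FALSE)
  tt <- (seq_len(n) - 1) / fps
  bic_start <- round(duration * fps) + 1
  bic_time <- duration + 20
  set.seed(seed)
  event_times <- sort(event_times)
  all_times <- c(event_times, bic_time)
  all_amps <- c(rep(event_amp, length(event_times)), bic_peak)
  tau_r <- 0.25; tau_d <- 1
  tstar <- tau_r * log(1 + tau_d / tau_r)
  kpeak <- exp(-tstar / tau_d) - exp(-tstar / tau_r)
  ca_kernel <- function(ts) (exp(-ts / tau_d) - exp(-ts / tau_r)) / kpeak
  baselines <- runif(n_rois, 80, 120)
  scale_mat <- matrix(pmax(rnorm(n_rois * length(all_times), 1, amp_scale_sd), 0.3),
    nrow = n_rois)
  traces <- vector("list", n_rois)
  for (i in seq_len(n_rois)) {
    dff_i <- numeric(n)
    for (j in seq_along(all_times)) {
      t0 <- all_times[j] + rnorm(1, 0, jitter_sd)
      act <- tt >= t0
      dff_i[act] <- dff_i[act] + all_amps[j] * scale_mat[i, j] * ca_kernel(tt[act] - t0)
    }
    f <- baselines[i] * (1 + dff_i) + background +
      rnorm(n, sd = noise_sd * baselines[i])
    traces[[i]] <- trace(f, dt = 1 / fps, units = "AU", role = "fluorescence")
  }
  pop_amp <- colMeans(scale_mat) * all_amps
  rois <- structure(list(traces = traces, background = background, fps = fps,
    bic_start = bic_start), class = "pk_rois")
  truth <- list(event_times = event_times,
    pop_amplitudes = pop_amp[seq_along(event_times)],
    bic_peak = pop_amp[length(pop_amp)],
    supra_criterion = pop_amp[seq_along(event_times)] >=
      0.1 * pop_amp[length(pop_amp)],
    frequency_per_min = length(event_times) / (duration / 60))
  list(rois = rois, truth = truth)
}

#' @export
print.pk_rois <- function(x, ...) {
  cat(sprintf("<pk_rois> %d ROIs, %d frames @ %g Hz%s\n", length(x$traces),
    length(x$traces[[1]]$samples), x$fps,
    if (!is.null(x$bic_start)) sprintf(", stimulation from frame %d", x$bic_start)
    else ""))
  invisible(x)
}

#' @method as_tibble pk_rois
#' @export
as_tibble.pk_rois <- function(x, ...) {
  purrr::imap_dfr(x$traces, function(tr, i) {
    tibble(roi = i, time = trace_time(tr), F = tr$samples)
  })
}

#' Simulate a two-channel cell image
#'
#' A centered circular cell: the marker channel has `nuc_intensity` on the
#' nuclear disk and `cyto_intensity` on the surrounding cytoplasmic
#' annulus over zero background; the nuclear-stain channel is bright on the
#' nucleus only. Gaussian noise is added to both channels.
#'
#' @param nuc_intensity,cyto_intensity Marker intensities, AU.
#' @param nucleus_radius,soma_radius Geometry in pixels
#'   (`nucleus_radius < soma_radius`).
#' @param noise_sd Pixel noise s.d., AU.
#' @param size Image side, px.
#' @param seed RNG seed.
#' @return A list with `image` (a `size x size x 2` array: marker, nuclear
#'   stain) and `truth` (intensities and the true nuclear/cytoplasmic
#'   ratio).
#' @export
simulate_cell_image <- function(nuc_intensity = 200, cyto_intensity = 100,
                                nucleus_radius = 8, soma_radius = 20,
                                noise_sd = 0, size = 64, seed = 1L) {
  if (nucleus_radius <= 0 || soma_radius <= 0) {
    stop("radii must be positive", call. = FALSE)
  }
  if (nucleus_radius >= soma_radius) {
    stop("nucleus_radius must be smaller than soma_radius", call. = FALSE)
  }
  cx <- (size + 1) / 2
  d <- sqrt(outer((seq_len(size) - cx)^2, (seq_len(size) - cx)^2, `+`))
  nuc <- d <= nucleus_radius
  soma <- d <= soma_radius
  marker <- matrix(0, size, size)
  marker[soma] <- cyto_intensity
  marker[nuc] <- nuc_intensity
  stain <- matrix(0, size, size)
  stain[nuc] <- 200
  set.seed(seed)
  if (noise_sd > 0) {
    marker <- marker + matrix(rnorm(size^2, sd = noise_sd), size, size)
    stain <- stain + matrix(rnorm(size^2, sd = noise_sd), size, size)
  }
  img <- array(c(marker, stain), dim = c(size, size, 2),
    dimnames = list(NULL, NULL, c("marker", "nuclear_stain")))
  list(image = img,
    truth = list(nuc_intensity = nuc_intensity, cyto_intensity = cyto_intensity,
      ratio = nuc_intensity / cyto_intensity))
}

#' Simulate a nuclear/cytoplasmic qPCR Ct table
#'
#' For each gene, draws replicate Ct values for the nuclear and cytoplasmic
#' cDNA fractions consistent with a planted nuclear proportion under
#' perfect-doubling amplification: relative abundance is proportional to
#' `2^-Ct`, so `ct_nuc - ct_cyt = -log2(p / (1 - p))`.
#'
#' @param proportions Named numeric vector of true nuclear proportions in
#'   (0, 1), one per gene.
#' @param base_ct Mean total-abundance Ct scale.
#' @param ct_sd Replicate Ct noise s.d., cycles.
#' @param n_replicates Replicates per gene.
#' @param seed RNG seed.
#' @return A list with `ct` (tibble: `gene`, `replicate`, `fraction`, `ct`)
#'   and `truth` (the planted proportions).
#' @export
simulate_ct_table <- function(proportions = c(gene_a = 0.8, gene_b = 0.3),
                              base_ct = 24, ct_sd = 0.15, n_replicates = 4,
                              seed = 1L) {
  stopifnot(all(proportions > 0 & proportions < 1), !is.null(names(proportions)))
  set.seed(seed)
  rows <- purrr::imap_dfr(as.list(proportions), function(p, g) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble(gene = g, replicate = r,
        fraction = c("nuclear", "cytoplasmic"),
        ct = c(base_ct - log2(p), base_ct - log2(1 - p)) +
          rnorm(2, sd = ct_sd))
    })
  })
  list(ct = rows, truth = list(proportions = proportions))
}
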