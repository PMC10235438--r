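# Independent brute-force oracles. These reimplement the contested logic
# with explicit sample-by-sample scans and loops, sharing no code with the
# package internals they check.

# Spike detection: upward dV/dt threshold crossing paired with the
# subsequent voltage maximum before dV/dt returns below zero; peak must
# reach peak_floor; threshold time must fall inside the window past the
# onset blanking interval.
oracle_detect_aps <- function(v, dt, window, thr = 20, peak_floor = -10,
                              blank_ms = 5) {
  n <- length(v)
  dtms <- dt * 1000
  d <- numeric(n)
  for (i in 2:(n - 1)) d[i] <- (v[i + 1] - v[i - 1]) / (2 * dtms)
  d[1] <- (v[2] - v[1]) / dtms
  d[n] <- (v[n] - v[n - 1]) / dtms
  end_idx <- min(n, floor(window[2] / dt) + 1)
  t_min <- window[1] + blank_ms / 1000
  res <- list()
  i <- 2
  while (i <= end_idx) {
    if (d[i] >= thr && d[i - 1] < thr) {
      j <- i
      while (j < end_idx && d[j] >= 0) j <- j + 1
      # j is now the first index > i with d < 0 (or end_idx)
      if (d[j] >= 0) j <- end_idx
      if (j > i) {
        peak <- i
        for (q in i:j) if (v[q] > v[peak]) peak <- q
        frac <- if (d[i] != d[i - 1]) (thr - d[i - 1]) / (d[i] - d[i - 1]) else 1
        thr_t <- (i - 2 + frac) * dt
        if (v[peak] >= peak_floor && thr_t >= t_min && thr_t <= window[2]) {
          res[[length(res) + 1]] <- c(i, peak)
        }
        i <- j + 1
        next
      }
    }
    i <- i + 1
  }
  if (!length(res)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, res)
}

# Step-up / step-down adjustments straight from their definitions.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

oracle_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    worst <- 0
    for (j in 1:i) worst <- max(worst, (m - j + 1) * ps[j])
    adj[i] <- min(1, worst)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    worst <- 0
    for (j in 1:i) worst <- max(worst, 1 - (1 - ps[j])^(m - j + 1))
    adj[i] <- min(1, worst)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# BH rejection set from the raw step-up definition at level alpha.
oracle_bh_rejections <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * alpha) k <- i
  if (k == 0) return(rep(FALSE, m))
  p <= ps[k]
}

# Short current-clamp family for fast unit tests.
quick_cc <- function(params = neuron_params(), levels = c(0, 60, 120),
                     seed = 1) {
  simulate_current_clamp(params,
    step_protocol(0, 0.05, 0.55, levels),
    sweep_duration = 0.7, seed = seed)
}

# Ground-truth spike count inside the detection window, with a 2 ms
# boundary tolerance: truth records 0 mV-crossing times while detection
# windows apply to threshold-crossing times, so spikes within ~2 ms of the
# window edges can legitimately fall on either side.
truth_count_bounds <- function(truth, sweep, onset, offset, blank_ms = 5) {
  st <- truth$spike_times[[sweep]]
  lo <- sum(st >= onset + blank_ms / 1000 + 0.002 & st <= offset - 0.002)
  hi <- sum(st >= onset + blank_ms / 1000 - 0.002 & st <= offset + 0.002)
  c(lower = lo, upper = hi)
}
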