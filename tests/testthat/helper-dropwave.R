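# Independent brute-force oracle for peak/trough detection. Implements the
# same rules as detect_peaks() — strict local maxima with plateau midpoints,
# topographic prominence against the nearest strictly taller sample, a
# relative prominence threshold, greedy minimum-distance thinning by height
# (ties to the earlier peak) — but as plain nested loops over the array,
# sharing no code with the implementation.
oracle_peaks <- function(x, period_hint, dt, prominence_frac = 0.1,
                         distance_frac = 0.35, min_prominence = 0) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      # walk across a possible plateau
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        cand <- c(cand, i + (j - i) %/% 2L)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(cand) > 0L) {
    proms <- numeric(length(cand))
    for (k in seq_along(cand)) {
      i <- cand[k]
      h <- x[i]
      lmin <- h
      j <- i - 1L
      found <- FALSE
      while (j >= 1L) {
        if (x[j] > h) { found <- TRUE; break }
        lmin <- min(lmin, x[j])
        j <- j - 1L
      }
      if (!found && i > 1L) lmin <- min(x[1:(i - 1L)])
      rmin <- h
      j <- i + 1L
      found <- FALSE
      while (j <= n) {
        if (x[j] > h) { found <- TRUE; break }
        rmin <- min(rmin, x[j])
        j <- j + 1L
      }
      if (!found && i < n) rmin <- min(x[(i + 1L):n])
      proms[k] <- h - max(lmin, rmin)
    }
    thr <- max(prominence_frac * as.numeric(quantile(x, 0.9)), min_prominence)
    cand <- cand[proms >= thr & proms > 0]
  }
  min_dist <- if (is.na(period_hint)) 1L else {
    max(1L, floor(distance_frac * period_hint / dt))
  }
  if (length(cand) > 1L && min_dist > 0L) {
    ord <- cand[order(-x[cand], cand)]
    kept <- integer(0)
    for (i in ord) {
      ok <- TRUE
      for (k in kept) if (abs(k - i) < min_dist) { ok <- FALSE; break }
      if (ok) kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  cand
}

# random test trace: smooth oscillation + drift + noise, rounded to force
# plateaus and ties
random_trace <- function(n) {
  t <- seq_len(n)
  period <- runif(1, 4, 30)
  x <- runif(1, 0, 5) + runif(1, 0.5, 3) * (1 + sin(2 * pi * t / period)) +
    cumsum(rnorm(n, 0, 0.05)) + rnorm(n, 0, runif(1, 0, 0.3))
  x <- x - cummin(x)  # keep non-negative like a corrected trace
  round(x, 2)
}

# a trace tibble wrapper around a plain corrected vector
as_corrected_trace <- function(x, dt = 2.5) {
  tibble::tibble(time_s = (seq_along(x) - 1) * dt, raw = x,
                 filtered = x, baseline = 0, corrected = x)
}

# linear array whose only active droplets are the listed sources; all other
# droplets are silent relays
relay_array <- function(n_droplets, source_idx, main_duration_s,
                        freq = 0.04, droplet_px = 108L) {
  lay <- linear_layout(n_droplets, droplet_px = droplet_px)
  md <- rep(0, n_droplets)
  md[source_idx] <- main_duration_s
  sched <- lifecycle_schedule(
    n_droplets, droplet_id = lay$droplets$droplet_id,
    induction_s = 0, initial_duration_s = 0, late_duration_s = 0,
    main_duration_s = md, main_freq_start = freq, main_freq_end = freq
  )
  list(layout = lay, schedule = sched)
}

no_noise <- function() noise_config(sd_frac = 0, drift_frac = 0)

# per-interface agreement between scheduled and detected propagation events
propagation_agreement <- function(truth_crossings, interfaces) {
  tot <- 0L
  hit <- 0L
  for (i in seq_len(nrow(interfaces))) {
    ifc <- interfaces$interface[i]
    sp <- sum(truth_crossings$crossed[truth_crossings$interface == ifc])
    sb <- sum(!truth_crossings$crossed[truth_crossings$interface == ifc])
    tot <- tot + sp + sb
    hit <- hit + min(sp, interfaces$propagated[i]) +
      min(sb, interfaces$blocked[i])
  }
  list(total = tot, matched = hit,
       accuracy = if (tot == 0L) 1 else hit / tot)
}

# random lifecycle schedule for parameter-recovery checks: constant
# within-stage frequencies, stage ordering as in the lifecycle taxonomy.
# Initial-period frequencies stay at or below 0.1 per s: at the 0.4 fps
# acquisition rate faster pulse trains fall below the sampling resolution
# (successive pulses merge under the anti-noise smoother), for this
# pipeline just as for the camera the acquisition emulates.
random_schedule <- function() {
  f_main <- runif(1, 0.03, 0.05)
  lifecycle_schedule(
    1L,
    induction_s = 0,
    initial_duration_s = runif(1, 120, 300),
    initial_freq = runif(1, 0.08, 0.10),
    initial_amp = runif(1, 24, 36),
    main_duration_s = runif(1, 1800, 3600),
    main_freq_start = f_main, main_freq_end = f_main,
    main_amp = runif(1, 50, 70),
    late_duration_s = runif(1, 300, 600),
    late_freq = 2 * f_main,
    late_amp = runif(1, 30, 40),
    spiral_start_probability = 0
  )
}

# scheduled analogue of the detected feature set, from ground-truth wave times
scheduled_features <- function(sim) {
  w <- sim$truth$waves
  tt <- sort(w$time_s)
  list(
    wave_count = length(tt),
    median_frequency = median_low(1 / diff(tt)),
    boundaries = sim$truth$boundaries
  )
}

# strip all S3 classes recursively so configs compare by value
unclass_flat <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_flat)
    attr(x, "class") <- NULL
  }
  x
}
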