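#' @keywords internal
# column carrying the raw intensity of a trace tibble
raw_col <- function(trace) {
  if ("raw" %in% names(trace)) "raw" else if ("intensity" %in% names(trace)) {
    "intensity"
  } else {
    stop_dropwave("trace has neither a 'raw' nor an 'intensity' column",
                  "dropwave_validation_error")
  }
}

trace_dt <- function(trace) {
  t <- trace$time_s
  if (length(t) < 2L) return(NA_real_)
  median(diff(t))
}

# zero-phase centred moving average; window truncated symmetrically at the
# edges so a constant series is reproduced exactly
ma_smooth <- function(x, width) {
  n <- length(x)
  width <- as.integer(width)
  if (width <= 1L || n < 3L) return(x)
  half <- (width - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)   # shrink symmetrically near edges
    out[i] <- mean(x[(i - h):(i + h)])
  }
  out
}

#' Low-pass filter an intensity trace
#'
#' Applies a zero-phase moving-average smoother to the raw intensity. The
#' default width is one eighth of the dominant oscillation period (rounded up
#' to an odd number of samples, minimum 3), wide enough to suppress
#' photometric noise while leaving the oscillation peaks in place; a constant
#' trace passes through unchanged.
#'
#' @param trace A trace tibble with `time_s` and `intensity` (or `raw`).
#' @param width Filter width in samples; odd. `NULL` (default) sizes it from
#'   [estimate_period()].
#' @param period_hint Dominant period in seconds, used to size the default
#'   width; estimated from the data when `NULL`.
#' @return The trace with a `filtered` column added (and the raw column
#'   duplicated as `raw` if absent).
#' @export
lowpass <- function(trace, width = NULL, period_hint = NULL) {
  trace <- as_tibble(trace)
  rc <- raw_col(trace)
  x <- trace[[rc]]
  if (length(x) < 3L) {
    stop_dropwave("low-pass filtering needs at least 3 samples",
                  "dropwave_validation_error")
  }
  dt <- trace_dt(trace)
  if (is.null(width)) {
    if (is.null(period_hint)) period_hint <- estimate_period(x, dt = dt)
    width <- if (is.na(period_hint)) 3L else {
      w <- ceiling(period_hint / dt / 8)
      as.integer(max(3, w + (1 - w %% 2)))  # next odd, >= 3
    }
  }
  width <- as.integer(width)
  if (width %% 2L == 0L) {
    stop_dropwave("low-pass width must be odd for a zero-phase filter",
                  "dropwave_config_error")
  }
  if (width > length(x)) {
    stop_dropwave("low-pass width exceeds the series length", "dropwave_config_error")
  }
  if (!"raw" %in% names(trace)) trace$raw <- x
  trace$filtered <- ma_smooth(x, width)
  attr(trace, "lowpass_width") <- width
  trace
}

#' Estimate the dominant oscillation period
#'
#' Returns the lag of the first prominent maximum of the autocorrelation
#' function, in seconds. Used to size the baseline window ("one period wide")
#' and the minimum peak separation. If the series has no oscillatory
#' structure (e.g. a constant trace) the estimate is `NA` and callers fall
#' back to their configured default.
#'
#' @param x A trace tibble (uses `filtered` if present, else the raw column)
#'   or a numeric vector.
#' @param dt Sampling interval in seconds (taken from the tibble when given).
#' @param min_acf Minimum autocorrelation for a maximum to count as
#'   prominent (default 0.2).
#' @param max_lag_frac Longest lag searched, as a fraction of the series
#'   length (default 0.5).
#' @return Dominant period in seconds, or `NA_real_` ("no period").
#' @export
estimate_period <- function(x, dt = NULL, min_acf = 0.2, max_lag_frac = 0.5) {
  if (is.data.frame(x)) {
    if (is.null(dt)) dt <- trace_dt(x)
    x <- if ("filtered" %in% names(x)) x$filtered else x[[raw_col(x)]]
  }
  if (is.null(dt) || is.na(dt)) dt <- 1
  n <- length(x)
  if (n < 4L || stats::sd(x) == 0) return(NA_real_)
  lag_max <- max(3L, floor(n * max_lag_frac))
  r <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                             demean = TRUE)$acf)[-1L]
  m <- length(r)
  if (m < 3L) return(NA_real_)
  for (k in 2L:(m - 1L)) {
    if (r[k] > r[k - 1L] && r[k] >= r[k + 1L] && r[k] >= min_acf) {
      return(k * dt)
    }
  }
  NA_real_
}

#' Running-minimum baseline correction
#'
#' The baseline at each sample is the minimum of the filtered intensity
#' within a one-period-wide window. Windows keep their full width and are
#' clamped inside the record near the edges, so every window contains the
#' sample it serves and the corrected trace (`filtered - baseline`) is
#' non-negative everywhere. Slow drift (wide compared with the window) is
#' absorbed into the baseline; for a periodic signal with the window equal to
#' its period the baseline is flat at the signal minimum.
#'
#' @param trace A trace tibble; [lowpass()] is applied first if there is no
#'   `filtered` column.
#' @param window_s Window width in seconds; `NULL` (default) uses the
#'   estimated dominant period, falling back to `default_window_s`.
#' @param default_window_s Fallback window when no period is detectable
#'   (default 60 s).
#' @return The trace with `baseline` and `corrected` columns added.
#' @export
subtract_baseline <- function(trace, window_s = NULL, default_window_s = 60) {
  trace <- as_tibble(trace)
  if (!"filtered" %in% names(trace)) trace <- lowpass(trace)
  dt <- trace_dt(trace)
  if (is.null(window_s)) {
    p <- estimate_period(trace$filtered, dt = dt)
    window_s <- if (is.na(p)) default_window_s else p
  }
  w <- max(3L, round_half_up(window_s / dt))
  trace$baseline <- running_min(trace$filtered, w)
  trace$corrected <- trace$filtered - trace$baseline
  attr(trace, "baseline_window_s") <- w * dt
  trace
}

# --- peak detection -------------------------------------------------------

# indices of strict local maxima; plateaus count once at their midpoint;
# series endpoints are never maxima
local_maxima <- function(x) {
  r <- rle(x)
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (i in 2L:(k - 1L)) {
    if (r$values[i] > r$values[i - 1L] && r$values[i] > r$values[i + 1L]) {
      out <- c(out, starts[i] + (ends[i] - starts[i]) %/% 2L)
    }
  }
  out
}

# topographic prominence of the candidate at index i: height above the
# higher of the two minima separating it from the nearest strictly taller
# samples (or the record ends)
peak_prominence <- function(x, i) {
  h <- x[i]
  left <- h
  if (i > 1L) {
    left <- min(x[1:(i - 1L)])
    j <- i - 1L
    m <- x[j]
    while (j >= 1L && x[j] <= h) {
      m <- min(m, x[j])
      j <- j - 1L
    }
    if (j >= 1L) left <- m
  }
  right <- h
  if (i < length(x)) {
    right <- min(x[(i + 1L):length(x)])
    j <- i + 1L
    m <- x[j]
    while (j <= length(x) && x[j] <= h) {
      m <- min(m, x[j])
      j <- j + 1L
    }
    if (j <= length(x)) right <- m
  }
  h - max(left, right)
}

# greedy minimum-distance thinning: taller peaks win, ties to the earlier
# sample; returns the surviving subset of candidate indices, sorted
enforce_min_distance <- function(idx, x, min_dist) {
  if (length(idx) <= 1L || min_dist <= 0L) return(sort(idx))
  ord <- idx[order(-x[idx], idx)]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# sub-sample apex refinement by a parabola through the three samples around
# the peak; the offset is clamped to half a sample
refine_peak_time <- function(x, i, t, dt) {
  n <- length(x)
  if (i <= 1L || i >= n) return(t[i])
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(t[i])
  delta <- 0.5 * (x[i - 1L] - x[i + 1L]) / denom
  t[i] + max(-0.5, min(0.5, delta)) * dt
}

#' Detect oscillation peaks and troughs
#'
#' Finds local maxima of the baseline-corrected trace whose topographic
#' prominence reaches a configured fraction of the trace's amplitude scale
#' (the 90th percentile of the corrected intensity) and which are separated
#' by at least a configured fraction of the dominant period. Each oscillation
#' peak corresponds to one oxidation wavefront passing the trace region.
#' Troughs are the minima between consecutive surviving peaks, so peaks and
#' troughs strictly interleave. Peak times are refined to sub-sample
#' precision by a parabolic fit around the apex. Optional manual curation
#' edits (mirroring the manual verification step of the original workflow)
#' are applied last.
#'
#' @param trace A trace tibble with a `corrected` column (see
#'   [subtract_baseline()]).
#' @param period_hint Dominant period in seconds; estimated when `NULL`.
#' @param prominence_frac Minimum prominence as a fraction of the
#'   90th-percentile corrected amplitude (default 0.1: low enough to retain the genuinely low-amplitude initial-period oscillations, while several standard deviations above the photometric noise floor).
#' @param distance_frac Minimum peak separation as a fraction of the
#'   dominant period (default 0.35; below half a period so that the faster
#'   initial- and late-period oscillations are retained).
#' @param min_prominence Absolute prominence floor in intensity units
#'   (default 0: only the relative threshold applies).
#' @param curation Optional curation edits: a data frame with columns
#'   `action` (`"add"` or `"remove"`) and `time_s`, or a path to a JSON
#'   sidecar file readable by [read_curation()].
#' @return A tibble of class `bz_peaks` with columns `kind` (`"peak"` /
#'   `"trough"`), `index` (1-based sample), `time_s` (refined for peaks) and
#'   `value` (corrected intensity). An empty result is valid.
#' @export
detect_peaks <- function(trace, period_hint = NULL, prominence_frac = 0.1,
                         distance_frac = 0.35, min_prominence = 0,
                         curation = NULL) {
  trace <- as_tibble(trace)
  if (!"corrected" %in% names(trace)) {
    stop_dropwave("trace has no 'corrected' column; run subtract_baseline() first",
                  "dropwave_validation_error")
  }
  x <- trace$corrected
  if (any(x < -1e-9, na.rm = TRUE)) {
    stop_dropwave("corrected trace must be non-negative", "dropwave_validation_error")
  }
  t <- trace$time_s
  dt <- trace_dt(trace)
  if (is.null(period_hint)) period_hint <- estimate_period(x, dt = dt)
  min_dist <- if (is.na(period_hint)) 1L else {
    max(1L, floor(distance_frac * period_hint / dt))
  }
  cand <- local_maxima(x)
  if (length(cand) > 0L) {
    thr <- max(prominence_frac * as.numeric(quantile(x, 0.9)), min_prominence)
    proms <- vapply(cand, function(i) peak_prominence(x, i), numeric(1))
    cand <- cand[proms >= thr & proms > 0]
  }
  kept <- enforce_min_distance(cand, x, min_dist)
  if (!is.null(curation)) {
    kept <- apply_curation(kept, x, t, dt, curation,
                           tol_s = max(2 * dt, ifelse(is.na(period_hint), 2 * dt,
                                                      period_hint / 4)))
  }
  build_peak_train(kept, x, t, dt, period_hint)
}

build_peak_train <- function(kept, x, t, dt, period_hint) {
  rows <- list()
  if (length(kept) > 0L) {
    for (j in seq_along(kept)) {
      i <- kept[j]
      rows[[length(rows) + 1L]] <- tibble(
        kind = "peak", index = i,
        time_s = refine_peak_time(x, i, t, dt), value = x[i]
      )
      if (j < length(kept)) {
        seg <- (kept[j] + 1L):(kept[j + 1L] - 1L)
        if (length(seg) == 0L) seg <- kept[j]  # adjacent peaks: degenerate
        ti <- seg[which.min(x[seg])]
        rows[[length(rows) + 1L]] <- tibble(
          kind = "trough", index = ti, time_s = t[ti], value = x[ti]
        )
      }
    }
  }
  out <- if (length(rows) == 0L) {
    tibble(kind = character(), index = integer(),
           time_s = numeric(), value = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  structure(out, class = c("bz_peaks", class(out)),
            dt = dt, period_hint = period_hint)
}

apply_curation <- function(kept, x, t, dt, curation, tol_s) {
  if (is.character(curation)) curation <- read_curation(curation)
  curation <- as_tibble(curation)
  if (nrow(curation) == 0L) return(kept)
  if (!all(c("action", "time_s") %in% names(curation))) {
    stop_dropwave("curation needs 'action' and 'time_s' columns",
                  "dropwave_parse_error")
  }
  for (i in seq_len(nrow(curation))) {
    act <- curation$action[i]
    ts <- curation$time_s[i]
    if (act == "remove") {
      if (length(kept) > 0L) {
        d <- abs(t[kept] - ts)
        if (min(d) <= tol_s) kept <- kept[-which.min(d)]
      }
    } else if (act == "add") {
      win <- which(abs(t - ts) <= tol_s)
      if (length(win) > 0L) {
        idx <- win[which.max(x[win])]
        if (!idx %in% kept) kept <- sort(c(kept, idx))
      }
    } else {
      stop_dropwave(sprintf("unknown curation action '%s'", act),
                    "dropwave_parse_error")
    }
  }
  sort(unique(kept))
}

#' Read a peak-curation sidecar file
#'
#' The sidecar is a JSON array of edit objects, each with an `action`
#' (`"add"` or `"remove"`) and a `time_s`; edits are applied in order after
#' automatic detection, replacing the manual peak verification of the
#' original workflow with a reproducible record.
#'
#' @param path Path to the JSON sidecar.
#' @return A tibble with columns `action` and `time_s`.
#' @export
read_curation <- function(path) {
  if (!file.exists(path)) {
    stop_dropwave(sprintf("curation file not found: %s", path), "dropwave_io_error")
  }
  as_tibble(jsonlite::fromJSON(path, simplifyDataFrame = TRUE))
}

#' Per-oscillation frequency series
#'
#' The frequency at a given time is the inverse of the peak-to-peak time
#' difference, assigned to the later peak of each consecutive pair.
#'
#' @param peaks A [detect_peaks()] result (or any data frame with `kind` and
#'   `time_s`).
#' @return A tibble with columns `time_s` and `frequency_per_s`; empty when
#'   fewer than two peaks exist.
#' @export
instantaneous_frequency <- function(peaks) {
  pt <- peaks$time_s[peaks$kind == "peak"]
  if (length(pt) < 2L) {
    return(tibble(time_s = numeric(), frequency_per_s = numeric()))
  }
  tibble(time_s = pt[-1L], frequency_per_s = 1 / diff(pt))
}

#' Trough-to-trough area of each oscillation peak
#'
#' Integrates the baseline-corrected intensity between the troughs flanking
#' each peak (trapezoidal rule on the sample grid), the per-wave "area" in
#' arbitrary units. The first and last peaks lack a flanking trough; they are
#' kept in the output with `area = NA` and excluded from area statistics.
#'
#' @param trace A trace tibble with `corrected`.
#' @param peaks A [detect_peaks()] result.
#' @return A tibble with one row per peak: `peak_index`, `peak_time_s`,
#'   `area` (intensity-seconds, `NA` where a flanking trough is missing).
#' @export
peak_area <- function(trace, peaks) {
  trace <- as_tibble(trace)
  x <- trace$corrected
  t <- trace$time_s
  p <- peaks[peaks$kind == "peak", ]
  tr <- peaks[peaks$kind == "trough", ]
  if (nrow(p) == 0L) {
    return(tibble(peak_index = integer(), peak_time_s = numeric(),
                  area = numeric()))
  }
  areas <- rep(NA_real_, nrow(p))
  for (i in seq_len(nrow(p))) {
    before <- tr$index[tr$index < p$index[i]]
    after <- tr$index[tr$index > p$index[i]]
    if (length(before) == 0L || length(after) == 0L) next  # edge peak: excluded
    a <- max(before)
    b <- min(after)
    areas[i] <- trapz_integral(t[a:b], x[a:b])
  }
  tibble(peak_index = p$index, peak_time_s = p$time_s, area = areas)
}
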