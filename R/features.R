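#' Segmentation configuration
#'
#' Thresholds of the lifecycle segmenter, all relative so they transfer
#' across intensity scales and compositions.
#'
#' @param initial_drop_frac Initial-to-main boundary: the first
#'   per-oscillation frequency below this fraction of the initial-period
#'   median (estimated from the first `initial_ref_n` oscillations) ends the
#'   initial period ("rapid decrease in frequency"). Default 0.6.
#' @param initial_ref_n Number of leading oscillations whose median defines
#'   the initial-period frequency. Default 5.
#' @param initial_max_s The frequency drop must occur within this many
#'   seconds of the first peak for an initial period to be declared at all;
#'   otherwise the record is treated as starting in its main period.
#'   Default 900.
#' @param late_step_frac Main-to-late boundary: a 3-oscillation rolling
#'   median frequency exceeding this multiple of the trailing main-period
#'   median ("sudden increase in frequency") starts the late period.
#'   Default 1.5.
#' @param late_trail_n Number of trailing main-period oscillations in the
#'   reference median. Default 10.
#' @param exhausted_after_periods The exhausted state starts this many
#'   oscillation periods after the last peak (refractory margin). Default 3.
#' @return A list of class `bz_segment_config`.
#' @export
segment_config <- function(initial_drop_frac = 0.6, initial_ref_n = 5L,
                           initial_max_s = 900, late_step_frac = 1.5,
                           late_trail_n = 10L, exhausted_after_periods = 3) {
  structure(list(initial_drop_frac = initial_drop_frac,
                 initial_ref_n = as.integer(initial_ref_n),
                 initial_max_s = initial_max_s,
                 late_step_frac = late_step_frac,
                 late_trail_n = as.integer(late_trail_n),
                 exhausted_after_periods = exhausted_after_periods),
            class = "bz_segment_config")
}

period_levels <- c("induction", "initial", "main", "late", "exhausted")

#' Segment a trace into lifecycle periods
#'
#' Labels contiguous intervals of the record with the oscillation lifecycle
#' stages: *induction* (quiescent, before the first detected peak),
#' *initial* (fast, low-amplitude oscillations), *main* (long stretch of
#' slower large-amplitude waves, entered by a rapid frequency decrease),
#' *late* (sudden frequency increase) and *exhausted* (no oscillations
#' detectable, after the last peak plus a refractory margin). Any stage may
#' be absent; a boundary between oscillatory stages is placed at the earlier
#' peak of the first interval that crosses the frequency threshold (the
#' straddling interval can be short, or span a wave lost in the transition,
#' so its midpoint is biased). A peakless record is labelled
#' induction-then-exhausted with the transition pinned (indeterminately) to
#' the record end.
#'
#' @param freqs Per-oscillation frequency series from
#'   [instantaneous_frequency()].
#' @param peaks The [detect_peaks()] result the frequencies came from.
#' @param extent_s Length-2 numeric: start and end time of the record, in
#'   seconds from mixing.
#' @param config A [segment_config()].
#' @return A tibble of class `bz_segments` with columns `period` (ordered
#'   factor), `start_s`, `end_s`; intervals are contiguous, non-overlapping
#'   and ordered, with exhausted (if present) last.
#' @export
segment_periods <- function(freqs, peaks, extent_s, config = segment_config()) {
  stopifnot(length(extent_s) == 2L, extent_s[2L] >= extent_s[1L])
  t0 <- extent_s[1L]
  t1 <- extent_s[2L]
  pt <- sort(peaks$time_s[peaks$kind == "peak"])
  m <- length(pt)
  seg <- function(period, a, b) tibble(period = period, start_s = a, end_s = b)
  finish <- function(df) {
    df <- df[df$end_s > df$start_s | df$period == "exhausted", ]
    df$period <- factor(df$period, levels = period_levels, ordered = TRUE)
    structure(df, class = c("bz_segments", class(df)))
  }
  if (m == 0L) {
    return(finish(dplyr::bind_rows(seg("induction", t0, t1),
                                   seg("exhausted", t1, t1))))
  }
  f <- freqs$frequency_per_s
  # exhausted: refractory margin after the final peak
  last_period <- if (length(f) > 0L) 1 / f[length(f)] else (t1 - t0) / 4
  t_ex <- pt[m] + config$exhausted_after_periods * last_period
  has_exhausted <- t_ex < t1
  if (!has_exhausted) t_ex <- t1

  t_im <- NA_real_  # initial -> main
  t_ml <- NA_real_  # main -> late
  if (length(f) >= config$initial_ref_n + 1L) {
    f_init <- median(f[seq_len(config$initial_ref_n)])
    below <- f < config$initial_drop_frac * f_init
    # the drop must be sustained: a single long interval (e.g. around a
    # missed or spurious peak) does not end the initial period
    sustained <- below & c(below[-1L], TRUE)
    drop <- which(sustained)
    drop <- drop[freqs$time_s[drop] - pt[1L] <= config$initial_max_s]
    if (length(drop) > 0L) {
      k <- drop[1L]  # f[k] spans peaks k and k+1 (freq at the later peak)
      # onset = the earlier peak of the first slow pair; the straddling
      # interval may be short or span a wave lost in the transition
      t_im <- pt[k]
    }
  }
  main_from <- if (is.na(t_im)) 1L else {
    which(pt > t_im)[1L]  # first peak inside the main period
  }
  # late: sustained frequency up-step against the trailing main median
  n_f <- length(f)
  if (!is.na(main_from) && n_f >= main_from + 4L) {
    for (k in (main_from + 4L):n_f) {
      if (k < 3L) next
      roll3 <- median(f[(k - 2L):k])
      trail_idx <- seq(max(main_from, k - 2L - config$late_trail_n), k - 3L)
      if (length(trail_idx) < 3L) next
      trail <- median(f[trail_idx])
      if (roll3 > config$late_step_frac * trail) {
        j <- (k - 2L):k
        j <- j[f[j] > config$late_step_frac * trail][1L]
        if (is.na(j)) j <- k - 2L
        # onset = the earlier peak of the first fast pair (the straddling
        # interval may span a wave lost in the transition)
        t_ml <- pt[j]
        break
      }
    }
  }
  out <- seg("induction", t0, pt[1L])
  osc_start <- pt[1L]
  if (!is.na(t_im)) {
    out <- dplyr::bind_rows(out, seg("initial", osc_start, t_im))
    osc_start <- t_im
  }
  main_end <- if (!is.na(t_ml)) t_ml else t_ex
  out <- dplyr::bind_rows(out, seg("main", osc_start, main_end))
  if (!is.na(t_ml)) out <- dplyr::bind_rows(out, seg("late", t_ml, t_ex))
  if (has_exhausted) out <- dplyr::bind_rows(out, seg("exhausted", t_ex, t1))
  finish(out)
}

#' Summarise the wave features of one droplet
#'
#' Computes the five per-droplet wave features: **lifetime** (completion of
#' mixing to the start of the exhausted state; `NA` when the record ends
#' before exhaustion), **frequency** (median of the per-oscillation
#' frequencies over the lifetime), **wave count** (peak count over the
#' lifetime; each peak is one wavefront), **amplitude** (median
#' baseline-corrected peak height) and **area** (median trough-to-trough
#' integral of each peak, arbitrary units). Medians use the lower-of-two
#' convention ([median_low()]); with no peaks the count is zero and the
#' medians are `NA`.
#'
#' @param trace A trace tibble with `corrected`.
#' @param peaks A [detect_peaks()] result.
#' @param segments A [segment_periods()] result from the same trace.
#' @return A one-row tibble: `lifetime_s`, `median_frequency_per_s`,
#'   `wave_count`, `median_amplitude`, `median_area`.
#' @export
summarize_features <- function(trace, peaks, segments) {
  ex <- segments[segments$period == "exhausted", ]
  lifetime <- if (nrow(ex) > 0L) ex$start_s[1L] else NA_real_
  horizon <- if (is.na(lifetime)) Inf else lifetime
  p <- peaks[peaks$kind == "peak" & peaks$time_s <= horizon, ]
  f <- instantaneous_frequency(peaks)
  f <- f$frequency_per_s[f$time_s <= horizon]
  areas <- peak_area(trace, peaks)
  areas <- areas$area[areas$peak_time_s <= horizon]
  tibble(
    lifetime_s = lifetime,
    median_frequency_per_s = median_low(f),
    wave_count = nrow(p),
    median_amplitude = median_low(p$value),
    median_area = median_low(areas)
  )
}

#' Analysis configuration
#'
#' Bundles every tunable of the trace pipeline with its documented default.
#'
#' @param lowpass_width Samples; `NULL` = one eighth of the dominant period.
#' @param baseline_window_s Seconds; `NULL` = one dominant period.
#' @param default_window_s Baseline fallback when no period is found.
#' @param prominence_frac,distance_frac,min_prominence See [detect_peaks()].
#' @param segmentation A [segment_config()].
#' @return A list of class `bz_trace_config`.
#' @export
trace_config <- function(lowpass_width = NULL, baseline_window_s = NULL,
                         default_window_s = 60, prominence_frac = 0.1,
                         distance_frac = 0.35, min_prominence = 0,
                         segmentation = segment_config()) {
  structure(list(lowpass_width = lowpass_width,
                 baseline_window_s = baseline_window_s,
                 default_window_s = default_window_s,
                 prominence_frac = prominence_frac,
                 distance_frac = distance_frac,
                 min_prominence = min_prominence,
                 segmentation = segmentation),
            class = "bz_trace_config")
}

#' Run the full single-trace analysis pipeline
#'
#' Chains [lowpass()], [subtract_baseline()], [detect_peaks()],
#' [instantaneous_frequency()], [segment_periods()] and
#' [summarize_features()] on one droplet's raw intensity trace.
#'
#' @param trace A trace tibble with `time_s` and `intensity` (or `raw`).
#' @param config A [trace_config()].
#' @param curation Optional curation edits, see [detect_peaks()].
#' @return An object of class `bz_trace_analysis`: a list with the augmented
#'   `$trace`, `$peaks`, `$frequencies`, `$segments`, `$features`, and
#'   `$params`. [tidy()] returns the peak table, [glance()] the one-row
#'   feature summary, [autoplot()] a diagnostic figure.
#' @export
analyze_trace <- function(trace, config = trace_config(), curation = NULL) {
  trace <- as_tibble(trace)
  period0 <- estimate_period(trace)
  trace <- lowpass(trace, width = config$lowpass_width, period_hint = period0)
  period <- estimate_period(trace)
  if (is.na(period)) period <- period0
  trace <- subtract_baseline(
    trace,
    window_s = config$baseline_window_s %||%
      (if (is.na(period)) NULL else period),
    default_window_s = config$default_window_s
  )
  peaks <- detect_peaks(trace, period_hint = period,
                        prominence_frac = config$prominence_frac,
                        distance_frac = config$distance_frac,
                        min_prominence = config$min_prominence,
                        curation = curation)
  freqs <- instantaneous_frequency(peaks)
  segments <- segment_periods(freqs, peaks, range(trace$time_s),
                              config = config$segmentation)
  features <- summarize_features(trace, peaks, segments)
  droplet_id <- if ("droplet_id" %in% names(trace)) trace$droplet_id[1L] else NA_character_
  structure(
    list(droplet_id = droplet_id, trace = trace, peaks = peaks,
         frequencies = freqs, segments = segments, features = features,
         params = list(period_s = period, config = config)),
    class = "bz_trace_analysis"
  )
}

#' Analyse every droplet trace in a long table
#'
#' @param traces A long tibble of traces (`droplet_id`, `time_s`,
#'   `intensity`).
#' @inheritParams analyze_trace
#' @return A named list of `bz_trace_analysis`, one per droplet.
#' @export
analyze_traces <- function(traces, config = trace_config()) {
  traces <- as_tibble(traces)
  ids <- unique(traces$droplet_id)
  setNames(lapply(ids, function(id) {
    analyze_trace(traces[traces$droplet_id == id, ], config = config)
  }), ids)
}

#' @export
print.bz_trace_analysis <- function(x, ...) {
  f <- x$features
  cat(sprintf("<bz_trace_analysis%s: %d samples, %d peaks>\n",
              if (is.na(x$droplet_id)) "" else paste0(" ", x$droplet_id),
              nrow(x$trace), f$wave_count))
  segs <- paste(sprintf("%s [%.0f, %.0f)", x$segments$period,
                        x$segments$start_s, x$segments$end_s), collapse = ", ")
  cat("  periods: ", segs, "\n", sep = "")
  cat(sprintf("  lifetime %.0f s, median frequency %.4g /s, median amplitude %.3g, median area %.4g AU\n",
              f$lifetime_s, f$median_frequency_per_s, f$median_amplitude,
              f$median_area))
  invisible(x)
}

#' @rdname analyze_trace
#' @param x A `bz_trace_analysis`.
#' @param ... Unused.
#' @export
tidy.bz_trace_analysis <- function(x, ...) {
  out <- as_tibble(x$peaks)
  out$droplet_id <- x$droplet_id
  dplyr::relocate(out, "droplet_id")
}

#' @rdname analyze_trace
#' @export
glance.bz_trace_analysis <- function(x, ...) {
  dplyr::bind_cols(tibble(droplet_id = x$droplet_id), x$features)
}
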