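trace_of <- function(x, dt = 2.5) {
  tibble::tibble(time_s = (seq_along(x) - 1) * dt, intensity = x)
}

test_that("the low-pass filter is zero-phase: constants pass, slow waves survive, Nyquist dies", {
  const <- trace_of(rep(5, 50))
  expect_equal(lowpass(const, width = 3)$filtered, rep(5, 50))
  # sinusoid far below the cutoff: < 1% attenuation
  t <- (0:399) * 2.5
  slow <- trace_of(10 + sin(2 * pi * t / 250))
  out <- lowpass(slow, width = 3)$filtered
  expect_gt((max(out) - min(out)) / 2, 0.99)
  # alternating +-1 at Nyquist: > 90% attenuation for an 11-sample window
  nyq <- trace_of(rep(c(1, -1), 50))
  outn <- lowpass(nyq, width = 11)$filtered
  expect_lt(max(abs(outn[20:80])), 0.1)
  expect_error(lowpass(trace_of(c(1, 2)), width = 3),
               class = "dropwave_validation_error")
  expect_error(lowpass(trace_of(rep(1, 10)), width = 4),
               class = "dropwave_config_error")
})

test_that("the period estimate finds the dominant autocorrelation lag", {
  t <- (0:199) * 2.5
  expect_equal(estimate_period(trace_of(sin(2 * pi * t / 25))), 25,
               tolerance = 2.5 / 25)
  expect_true(is.na(estimate_period(trace_of(rep(3, 100)))))
  mix <- 3 * sin(2 * pi * t / 25) + sin(2 * pi * t / 250)
  expect_equal(estimate_period(trace_of(mix)), 25, tolerance = 2.5 / 25)
})

test_that("the running-minimum baseline satisfies its closed forms", {
  # constant trace: baseline = the constant, corrected = 0
  const <- lowpass(trace_of(rep(7, 60)), width = 3)
  out <- subtract_baseline(const, window_s = 60)
  expect_equal(out$baseline, rep(7, 60))
  expect_equal(out$corrected, rep(0, 60))
  # C + A sin with a one-period window: baseline C - A everywhere,
  # corrected peaks 2A (period = 8 samples, so the minimum phase is hit)
  dt <- 2.5; P <- 8 * dt; C <- 50; A <- 4
  t <- (0:159) * dt
  x <- trace_of(C + A * sin(2 * pi * t / P))
  x$filtered <- x$intensity  # bypass smoothing: test the baseline alone
  out2 <- subtract_baseline(x, window_s = P)
  expect_equal(out2$baseline, rep(C - A, length(t)))
  expect_equal(max(out2$corrected), 2 * A)
  # slow drift is absorbed: corrected peak heights vary at most drift x window
  slope <- 0.01
  xd <- trace_of(C + A * sin(2 * pi * t / P) + slope * t)
  xd$filtered <- xd$intensity
  out3 <- subtract_baseline(xd, window_s = P)
  pk <- detect_peaks(out3, period_hint = P)
  heights <- pk$value[pk$kind == "peak"]
  expect_lt(max(heights) - min(heights), slope * P + 1e-9)
  expect_error(subtract_baseline(x, window_s = 1e6),
               class = "dropwave_config_error")
})

test_that("baseline correction is non-negative and period-preserving", {
  set.seed(42)
  for (i in 1:20) {
    x <- as_corrected_trace(random_trace(150))
    out <- subtract_baseline(x[, c("time_s", "raw", "filtered")], window_s = 25)
    expect_true(all(out$corrected >= 0))
  }
  # periodic input, window = exact period: corrected is periodic too
  dt <- 2.5; P <- 10 * dt
  t <- (0:149) * dt
  x <- trace_of(30 + 5 * sin(2 * pi * t / P) + 2 * cos(4 * pi * t / P))
  x$filtered <- x$intensity
  cor <- subtract_baseline(x, window_s = P)$corrected
  expect_equal(cor[31:140], cor[(31:140) - 10], tolerance = 1e-9)
})

test_that("peak detection matches the exhaustive scan on canonical shapes", {
  # monotone ramp: no peaks
  ramp <- as_corrected_trace(seq(0, 10, length.out = 40))
  expect_equal(nrow(detect_peaks(ramp, period_hint = 25)), 0L)
  # 3-cycle triangle wave: 3 peaks with interleaved troughs
  tri <- as_corrected_trace(rep(c(0, 1, 2, 3, 2, 1), 3))
  pk <- detect_peaks(tri, period_hint = 15)
  expect_equal(sum(pk$kind == "peak"), 3L)
  expect_equal(sum(pk$kind == "trough"), 2L)
  expect_equal(pk$kind, c("peak", "trough", "peak", "trough", "peak"))
  idx <- oracle_peaks(tri$corrected, 15, 2.5)
  expect_equal(pk$index[pk$kind == "peak"], idx)
  # peaks interleave and dominate their flanking troughs
  expect_true(all(diff(pk$time_s) > 0))
})

test_that("peak detection equals the brute-force oracle on random traces", {
  set.seed(101)
  for (i in 1:200) {
    x <- random_trace(sample(20:200, 1))
    tr <- as_corrected_trace(x)
    hint <- sample(c(NA, 10, 25, 50), 1)
    hint_used <- if (is.na(hint)) estimate_period(x, dt = 2.5) else hint
    pk <- detect_peaks(tr, period_hint = hint_used)
    got <- pk$index[pk$kind == "peak"]
    want <- oracle_peaks(x, hint_used, 2.5)
    expect_equal(got, want)
    # invariants: interleaving, troughs below both neighbours
    kinds <- pk$kind
    if (nrow(pk) > 0) {
      expect_true(all(kinds[seq(1, length(kinds), by = 2)] == "peak"))
      expect_true(all(diff(pk$index) > 0))
      v <- pk$value
      tr_i <- which(kinds == "trough")
      if (length(tr_i) > 0) {
        expect_true(all(v[tr_i] <= v[tr_i - 1] & v[tr_i] <= v[tr_i + 1]))
      }
    }
  }
})

test_that("curation edits add and remove peaks after detection", {
  tri <- as_corrected_trace(rep(c(0, 2, 4, 6, 4, 2), 4))
  pk0 <- detect_peaks(tri, period_hint = 15)
  expect_equal(sum(pk0$kind == "peak"), 4L)
  rm1 <- detect_peaks(tri, period_hint = 15,
                      curation = data.frame(action = "remove",
                                            time_s = pk0$time_s[1]))
  expect_equal(sum(rm1$kind == "peak"), 3L)
  # a JSON sidecar behaves identically
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(data.frame(action = "remove", time_s = pk0$time_s[1]),
                       path, auto_unbox = TRUE)
  rm2 <- detect_peaks(tri, period_hint = 15, curation = path)
  expect_equal(rm2$index, rm1$index)
  add1 <- detect_peaks(tri, period_hint = 15,
                       curation = data.frame(
                         action = c("remove", "add"),
                         time_s = c(pk0$time_s[1], pk0$time_s[1])))
  expect_equal(sum(add1$kind == "peak"), 4L)
  expect_error(detect_peaks(tri, period_hint = 15,
                            curation = data.frame(action = "zap", time_s = 1)),
               class = "dropwave_parse_error")
})

test_that("per-oscillation frequency is the inverse peak-to-peak interval", {
  peaks25 <- tibble::tibble(kind = "peak", index = 1:10,
                            time_s = seq(0, by = 25, length.out = 10),
                            value = 1)
  f <- instantaneous_frequency(peaks25)
  expect_equal(f$frequency_per_s, rep(0.04, 9))  # 25 s waves: 0.04 per s
  expect_equal(f$time_s, peaks25$time_s[-1])
  single <- peaks25[1, ]
  expect_equal(nrow(instantaneous_frequency(single)), 0L)
  p3 <- tibble::tibble(kind = "peak", index = 1:3, time_s = c(0, 10, 30),
                       value = 1)
  expect_equal(instantaneous_frequency(p3)$frequency_per_s, c(0.1, 0.05))
})

test_that("trough-to-trough areas follow the trapezoid closed form and scale linearly", {
  # triangular peak, base 10 s, height 1, zero at its troughs; flanking
  # peaks on both sides so the trough-to-trough span is defined
  x <- c(0.001, 2, 0.001, 0, 0.5, 1, 0.5, 0, 0.001, 2, 0.001)
  tr <- as_corrected_trace(x, dt = 2.5)
  pk <- detect_peaks(tr, period_hint = 10)
  ar <- peak_area(tr, pk)
  expect_equal(nrow(ar), sum(pk$kind == "peak"))
  tri_area <- ar$area[!is.na(ar$area)][1]
  expect_equal(tri_area, 5)  # 1/2 x base 10 s x height 1
  # zero trace segment integrates to zero
  z <- as_corrected_trace(rep(0, 20))
  expect_equal(nrow(peak_area(z, detect_peaks(z, period_hint = 10))), 0L)
  # scaling the corrected trace scales each area by the same factor
  tr3 <- tr
  tr3$corrected <- tr3$corrected * 3
  tr3$filtered <- tr3$filtered * 3
  ar3 <- peak_area(tr3, detect_peaks(tr3, period_hint = 10))
  expect_equal(ar3$area, ar$area * 3)
  # edge peaks without both flanking troughs are excluded (NA), and noted
  expect_true(any(is.na(ar$area)))
})

test_that("wave-feature medians use the lower-of-two convention", {
  expect_equal(median_low(c(1, 2, 3, 4)), 2)
  expect_equal(median_low(c(4, 1, 3, 2, 100)), 3)
  expect_true(is.na(median_low(numeric(0))))
  pk <- tibble::tibble(kind = "peak", index = c(10, 20, 30, 40, 50),
                       time_s = c(25, 50, 75, 100, 125),
                       value = c(1, 2, 3, 4, 100))
  tr <- as_corrected_trace(rep(0, 60))
  seg <- segment_periods(instantaneous_frequency(pk), pk, c(0, 150))
  feats <- summarize_features(tr, pk, seg)
  expect_equal(feats$median_amplitude, 3)
  expect_equal(feats$wave_count, 5L)
  # empty peak train: zero count, absent medians
  none <- detect_peaks(as_corrected_trace(rep(0, 30)), period_hint = 10)
  seg0 <- segment_periods(instantaneous_frequency(none), none, c(0, 72.5))
  f0 <- summarize_features(tr, none, seg0)
  expect_equal(f0$wave_count, 0L)
  expect_true(is.na(f0$median_amplitude))
})

test_that("features are invariant under adding a constant to the raw trace", {
  sim <- simulate_traces(lifecycle_schedule(1), seed = 3)
  a1 <- analyze_trace(sim$traces)
  shifted <- sim$traces
  shifted$intensity <- shifted$intensity + 57
  a2 <- analyze_trace(shifted)
  expect_equal(a2$features$wave_count, a1$features$wave_count)
  expect_equal(a2$features$median_frequency_per_s,
               a1$features$median_frequency_per_s)
  expect_equal(a2$features$median_amplitude, a1$features$median_amplitude)
  expect_equal(a2$features$median_area, a1$features$median_area)
})
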