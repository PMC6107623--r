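---
title: "Quantifying chemical oscillations and wave propagation in droplet arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemical oscillations and wave propagation in droplet arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropwave)
```

## The measurement model

A droplet-in-oil BZ experiment is recorded as a fixed-camera time-lapse of
an acrylic template whose slots hold rows of aqueous droplets. With the
ferroin catalyst, the reduced medium absorbs in the blue, so each oxidation
wave sweeping a droplet appears as a transient rise of the blue-channel
intensity. Everything this package computes derives from that one signal:

1. **Kymograph.** For every frame a strip of `strip_width` pixels (default
   15, the standard calibration) is cropped along the slot centreline and
   blurred in the x-direction; the strips are composed side by side in
   temporal order. The default blur is the mean over the full strip width,
   which makes the `strip_width` columns contributed by one frame
   identical; a narrower box kernel is available (`blur_width`), and a
   *collapsed* mode keeps one column per frame. Because every trace-level
   statistic averages over the strip anyway, the collapsed and full-width
   kymographs are analytically equivalent; the full-width form exists for
   display. Canonical orientation is time on x, slot position on y.
2. **Trace.** One scalar per frame: the mean intensity of a
   `strip_width × height` px region (default 15 × 5) at a y-position near
   the droplet centre, inside the droplet span. Intensities are expressed
   in 8-bit arbitrary units (AU, 0–255). All timestamps are seconds from
   the completion of mixing; `t0_offset` records any delay between mixing
   and the first frame.
3. **Oscillations.** The trace is low-pass filtered, baseline-corrected
   with a running minimum, and decomposed into peaks (one per wavefront
   passing the trace region) and interleaved troughs. The frequency at a
   given time is the inverse of the peak-to-peak interval, assigned to the
   later peak.
4. **Lifecycle.** The record is segmented into induction → initial → main
   → late → exhausted periods from the frequency series alone.
5. **Features.** Per droplet: lifetime (mixing to the start of the
   exhausted state), median per-oscillation frequency, wave count (peak
   count), median baseline-corrected peak amplitude, and median
   trough-to-trough area (AU·s, reported as AU).
6. **Propagation.** On multi-droplet kymographs, oxidised bands are
   binarised with a per-time-column adaptive threshold, linked into
   wavefront tracks, and aggregated into per-interface propagated/blocked
   counts, per-droplet wave-origin labels and annihilation events.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `frame_rate` | 0.4 | frames/s | standard acquisition rate |
| `width_px` / `width_mm` | 108 / 2.5 | px, mm | template calibration (0.0231 mm/px) |
| `strip_width`, trace `height` | 15, 5 | px | the 15 × 5 px trace region |
| `lowpass()` width | ⌈period/8⌉, odd, ≥ 3 | samples | suppress photometric noise without displacing apexes |
| baseline `window_s` | one dominant period | s | a full period guarantees the window sees one true minimum |
| `prominence_frac` | 0.10 | — | fraction of the 90th-percentile corrected amplitude; see below |
| `distance_frac` | 0.35 | — | minimum peak separation as a fraction of the dominant period |
| `initial_drop_frac` | 0.6 | — | initial→main when frequency falls below 60% of the leading median |
| `late_step_frac` | 1.5 | — | main→late when a 3-wave rolling median exceeds 1.5× the trailing main median |
| `exhausted_after_periods` | 3 | periods | refractory margin after the final peak |
| `binarize_fronts()` `frac`, `min_contrast` | 0.5, 40 | —, AU | half-range threshold per column; columns without a front stay empty |
| tracking `max_dy_px`, `max_gap_frames` | 18, 2 | px, frames | bridge crossing delays without chaining successive waves |
| coupling `delay_window_s` | 25 | s | one oscillation period; longer gaps count as independent excitation |

The dominant period itself comes from the first prominent autocorrelation
maximum of the filtered trace (`estimate_period()`); a trace without
oscillatory structure reports "no period" and callers fall back to a
configured default (60 s for the baseline window).

### Why 10% prominence and 0.35 periods of separation

The original workflow found peaks with a manually tuned, per-trace
procedure. Reproducible defaults have to serve the initial and late periods
as well as the main period, and at 0.4 frames/s the fast initial
oscillations are barely oversampled: after the anti-noise smoother their
apparent amplitude is only ~15–25% of the main-period amplitude. A
prominence floor of 20% of the global amplitude scale would therefore
discard genuine initial-period waves wholesale, and a minimum separation of
half the dominant (main) period would discard *every* initial- and
late-period peak, whose spacing is 0.4–0.5 of the main period. The shipped
defaults — 10% prominence (still about four standard deviations above the
smoothed noise floor at the default 2% noise) and 0.35 periods of
separation — were calibrated against synthetic ground-truth schedules so
that no spurious peaks are admitted while initial/late trains are retained.
A JSON *curation sidecar* (`detect_peaks(curation = ...)`) records manual
add/remove edits reproducibly, replacing interactive verification.

### Segmentation boundary placement

Both oscillatory-stage boundaries are detected from the frequency series
and placed at the *earlier* peak of the first interval that crosses the
threshold. The straddling interval between two stages is unreliable: it can
be short (the first wave of the new stage starts half a period into it) or
long (a wave lost where pulses of different widths overlap), so its
midpoint is biased by up to a full period. The initial→main drop must also
be *sustained* (two consecutive sub-threshold intervals): a single long
interval — for example around a spurious peak at the droplet-appearance
edge — does not end the initial period.

## Numerical choices

* **Baseline windows are clamped, not truncated.** Near the record edges
  the one-period window keeps its full width and slides inside the record.
  A truncated half-window does not contain a full oscillation, so the
  running minimum would ride up the flank and the closed-form identity
  (baseline of `C + A·sin` ≡ `C − A`) would fail at the edges. Clamped
  windows always contain the sample they serve, so `corrected ≥ 0` holds
  everywhere.
* **Plateaus** (exactly equal consecutive samples, common in 8-bit data)
  count as a single candidate peak at their midpoint; series endpoints are
  never peaks.
* **Sub-sample peak times** come from a parabola through the three samples
  around the apex, clamped to ±half a sample. At 2.5 s per frame this is
  what makes 2% frequency recovery possible.
* **Medians** use the lower-of-two convention for even counts, so every
  reported median is an observed value and results are deterministic.
* **Ties** in peak selection are broken by height, then earlier time.
* **Degenerate inputs**: a constant trace has no period, no peaks, and
  segments as induction-then-exhausted with the boundary pinned to the
  record end (the transition is indeterminate without oscillations); the
  first/last peaks lack a flanking trough and are excluded from area
  statistics (kept as `NA`); a constant kymograph binarises to an empty
  mask via the `min_contrast` guard.
* **Even strip widths** bias one pixel toward lower coordinates; odd
  widths centre exactly (the defaults are odd).

## The synthetic generator

`simulate_traces()` is phenomenological by design: it emulates what the
camera sees, not the reaction kinetics (no Oregonator/FKN integration).
Each droplet follows a lifecycle schedule — induction delay, then initial,
main and late periods with per-stage wave frequency (the main period may
ramp linearly) and pulse amplitude, then an exhausted state in the reduced
or oxidised colour. Each scheduled wave contributes one asymmetric pulse
(half-cosine rise over 15% of the local period, half-cosine decay over
55%), overlapping pulses saturate via a pointwise maximum, and the trace
adds a slow sinusoidal baseline drift (default 5% amplitude, 30 min
period), Gaussian noise (default 2% of the main amplitude) and optional
static bright-spot artifacts emulating CO₂ bubbles. About 20% of droplets
are marked as starting with spiral waves, rendered as a modest contrast
reduction of the initial period.

Two generator choices deviate from the obvious first guess, both for
sampling-physics reasons at the 0.4 fps study frame rate:

* the default initial-period frequency is 0.1 s⁻¹, not 0.2 s⁻¹ — 0.2 s⁻¹
  *is* the Nyquist frequency of the acquisition and cannot be represented;
  0.1 s⁻¹ preserves the initial > main > (late between them) frequency
  ordering at four samples per cycle;
* pulse rise/decay widths are 15%/55% of the local period rather than
  10%/40% — a 10% rise on a 10 s initial-period pulse is shorter than one
  sample, which would make the generated initial period invisible to any
  analysis, unlike the real recordings the generator emulates.

With a layout and a coupling specification the generator becomes spatial:
waves spawn opposite-travelling fronts at the droplet centre (constant
speed, default 2.5 px/s ≈ 3.5 mm/min); a front reaching a droplet-droplet
interface crosses with the interface's probability after its delay (default
5 s) unless a wave crossed the *same interface* within the refractory time,
and otherwise terminates there; opposing fronts meeting inside a droplet
annihilate at their midpoint. The refractory clock is per interface rather
than per droplet so that fronts converging on one droplet from both sides —
the canonical annihilation geometry — are not spuriously blocked.
`render_kymograph()` draws the slot's blue channel directly (bands of
half-cosine profile, default 9 px wide, over red-resting droplets);
`render_frames()` materialises the same scene as RGB frames, and the two
are pixel-identical after `build_kymograph()` when noise is off.

**What the generator does not emulate** — and hence what passing tests do
not establish about laboratory data: reaction kinetics and their
composition dependence, 2-D wave geometry inside droplets (spiral/circular
fronts are not rendered; the classification of those patterns is out of
scope), droplet fusion and sliding, camera vignetting and focus drift, and
junction topologies beyond a linear slot. Ground-truth recovery results
certify the *quantification pipeline*, not the chemistry.

## Validation strategy and problem sizes

Every stage is tested against independent oracles: closed forms (running
minimum of a sinusoid, trapezoid areas, reciprocal peak spacings), an
exhaustive brute-force peak scan (1000 random traces of up to 200 samples),
generator ground truth (20 random lifecycle schedules, recovered median
frequency within 2% noise-free and 5% at default noise, wave counts within
±2, stage boundaries within one period), and full propagation bookkeeping
on 20-droplet arrays (all scheduled crossings and blocks recovered
noise-free; at least 95% at default noise; a single fully-coupled end
source traverses all 20 droplets). The packaged lifecycle fixture — droplet
appearing at 4.5 min, main period from 7.5 to 60 min, ten minutes of late
period — is recovered within one oscillation period. These sizes (single
slots, up to 42 slots per template, records up to 78 min at 0.4 fps) were
chosen to exercise every code path at the study's own calibration while
keeping the whole suite fast enough to run routinely.

## Known limitations

* **Sampling ceiling.** At 0.4 frames/s, pulse trains above ~0.1 s⁻¹ leave
  fewer than one empty sample between smoothed pulses and merge; wave
  counts for such trains are systematically undercounted. This is a
  resolution limit of the acquisition the package emulates, not a
  removable algorithm parameter.
* **Transition losses.** Where stages meet, a wave riding the previous
  stage's decay tail can fail to form a local maximum; segmentation
  placement is designed around this, but per-record wave counts can be
  low by one or two. The curation sidecar exists for exactly these cases.
* **Slot geometry.** Only axis-aligned linear slots are supported;
  networks are analysed slot by slot, and maze/junction topologies are out
  of scope.
* **Scalar traces.** Within-droplet wave geometry is not classified; a
  spiral and a planar wave with equal period are indistinguishable in a
  5 px trace.
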