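# Rendering synthetic recordings: ferroin-coloured droplets in a vertical
# slot. Reduced medium is red-dominant; each travelling oxidation wavefront
# is a blue band moving along the slot. Simulations without spatial fronts
# (no layout/coupling) are rendered as uniform whole-droplet blue flashes
# that reproduce the trace pulse shape.

REST_RGB <- c(0.70, 0.22, 0.25)   # reduced droplet
OIL_RGB <- c(0.16, 0.13, 0.10)    # background oil
BAND_BLUE <- 0.50                 # peak blue bump of an oxidation front

# pulse accumulation of one droplet on the frame grid, in 8-bit AU
pulse_accum <- function(sim, droplet_id, tgrid) {
  w <- sim$truth$waves[sim$truth$waves$droplet_id == droplet_id, ]
  row <- sim$schedule[sim$schedule$droplet_id == droplet_id, ]
  acc <- numeric(length(tgrid))
  if (nrow(w) == 0L) return(acc)
  amp_of <- c(initial = row$initial_amp, main = row$main_amp,
              late = row$late_amp, relay = sim$config$relay_amp)
  for (k in seq_len(nrow(w))) {
    acc <- add_pulse(acc, tgrid, w$time_s[k], amp_of[[w$stage[k]]],
                     w$period_s[k], sim$config$rise_frac,
                     sim$config$decay_frac)
  }
  acc
}

# blue-channel profile (0-1) along the slot for one frame
blue_profile <- function(sim, layout, frame_idx, tgrid, front_width_px,
                         acc_list) {
  slot <- resolve_slot(layout)
  ys <- slot$y_start
  H <- slot$y_end - ys
  prof <- rep(OIL_RGB[3L], H)
  d <- layout$droplets
  t <- tgrid[frame_idx]
  for (i in seq_len(nrow(d))) {
    rows <- (d$span_start[i] - ys + 1L):(d$span_end[i] - ys)
    prof[rows] <- REST_RGB[3L]
    if (!is.null(acc_list)) {
      prof[rows] <- prof[rows] + acc_list[[d$droplet_id[i]]][frame_idx] / 255
    }
  }
  fr <- sim$truth$fronts
  if (nrow(fr) > 0L) {
    sel <- which(abs(fr$time_s - t) < 1e-6)
    half <- front_width_px / 2
    for (k in sel) {
      y0 <- fr$position_px[k]
      yy <- max(1L, floor(y0 - half - ys + 1)):min(H, ceiling(y0 + half - ys + 1))
      if (length(yy) == 0L) next
      dist <- abs((yy - 1L + ys) - y0)
      bump <- BAND_BLUE * 0.5 * (1 + cos(pi * pmin(dist / half, 1)))
      prof[yy] <- pmax(prof[yy], REST_RGB[3L] + bump)
    }
  }
  pmin(prof, 1)
}

render_core <- function(sim, layout, front_width_px, seed) {
  stopifnot(inherits(sim, "bz_simulation"), inherits(layout, "bz_layout"))
  if (sim$config$t0_offset != 0) {
    stop_dropwave("rendering assumes recording starts at mixing (t0_offset = 0)",
                  "dropwave_config_error")
  }
  tgrid <- sort(unique(sim$traces$time_s))
  if (length(tgrid) == 0L) {
    stop_dropwave("simulation has no samples to render", "dropwave_validation_error")
  }
  spatial <- nrow(sim$truth$fronts) > 0L
  acc_list <- NULL
  if (!spatial) {
    acc_list <- setNames(
      lapply(sim$schedule$droplet_id, function(id) pulse_accum(sim, id, tgrid)),
      sim$schedule$droplet_id)
  }
  # aliasing check: a front should not jump a whole droplet between frames
  if (spatial && nrow(layout$droplets) > 0L) {
    step <- sim$config$front_speed_px_s / sim$config$frame_rate
    min_span <- min(layout$droplets$span_end - layout$droplets$span_start)
    if (step > min_span) {
      warning("front speed x frame interval exceeds the droplet span; fronts will alias",
              call. = FALSE)
    }
  }
  list(tgrid = tgrid, spatial = spatial, acc_list = acc_list)
}

#' Render a synthetic kymograph directly
#'
#' Produces the slot kymograph a [build_kymograph()] of the rendered frames
#' would yield (collapsed, blue channel), without materialising the frames:
#' the rendered intensity is constant across the strip width, so the x-blur
#' is the identity. Noise and drift are applied on the kymograph grid.
#'
#' @param sim A [simulate_traces()] result.
#' @param layout The [bz_layout()] the simulation used.
#' @param front_width_px Width of a rendered wavefront band (default 9).
#' @param noise A [noise_config()]; defaults to the simulation's.
#' @param seed Seed for the rendering noise (default: simulation seed + 1).
#' @return A `bz_kymograph` (collapsed: one column per frame).
#' @export
render_kymograph <- function(sim, layout, front_width_px = 9,
                             noise = sim$config$noise,
                             seed = sim$config$seed + 1L) {
  core <- render_core(sim, layout, front_width_px, seed)
  tgrid <- core$tgrid
  slot <- resolve_slot(layout)
  H <- slot$y_end - slot$y_start
  n <- length(tgrid)
  img <- matrix(0, nrow = H, ncol = n)
  for (j in seq_len(n)) {
    img[, j] <- blue_profile(sim, layout, j, tgrid, front_width_px,
                             core$acc_list)
  }
  with_local_seed(seed, {
    if (noise$drift_frac > 0) {
      phase <- runif(1, 0, 2 * pi)
      drift <- noise$drift_frac * BAND_BLUE *
        sin(2 * pi * tgrid / noise$drift_period_s + phase)
      img <- sweep(img, 2L, drift, `+`)
    }
    if (noise$sd_frac > 0) {
      img <- img + matrix(rnorm(length(img), 0, noise$sd_frac * BAND_BLUE),
                          nrow = H)
    }
    if (noise$bubbles > 0L) {
      yb <- sample.int(H, noise$bubbles)
      img[yb, ] <- img[yb, ] + noise$bubble_level
      if (any(yb > 1L)) img[yb[yb > 1L] - 1L, ] <- img[yb[yb > 1L] - 1L, ] +
          noise$bubble_level / 2
    }
  })
  img <- pmin(pmax(img, 0), 1)
  structure(img * 255,
            class = c("bz_kymograph", "matrix"),
            times = tgrid, frame_rate = sim$config$frame_rate,
            t0_offset = sim$config$t0_offset,
            strip_width = 15L, cols_per_frame = 1L,
            channel = "blue", slot_id = slot$slot_id,
            y_start = as.integer(slot$y_start))
}

#' Render a synthetic frame stack
#'
#' Materialises RGB video frames of the droplet slot: red-dominant droplets
#' at rest over darker oil, blue bands at the rendered wavefront positions
#' (or uniform whole-droplet flashes for non-spatial simulations). The frame
#' is just wide enough for the standard 15 px analysis strip plus an oil
#' margin; with the default calibration the slot width is 108 px / 2.5 mm
#' and the trace region 15 x 5 px.
#'
#' @inheritParams render_kymograph
#' @param margin_px Oil margin left and right of the slot (default 3).
#' @return A [frame_stack()] whose [build_kymograph()] equals
#'   [render_kymograph()] of the same simulation when noise is disabled.
#' @export
render_frames <- function(sim, layout, front_width_px = 9,
                          noise = sim$config$noise, margin_px = 3L,
                          seed = sim$config$seed + 1L) {
  core <- render_core(sim, layout, front_width_px, seed)
  tgrid <- core$tgrid
  slot <- resolve_slot(layout)
  H <- slot$y_end - slot$y_start
  W <- 2L * slot$centre_x + 1L
  inner <- (margin_px + 1L):(W - margin_px)   # slot interior columns
  droplet_rows <- rep(FALSE, H)
  d <- layout$droplets
  for (i in seq_len(nrow(d))) {
    droplet_rows[(d$span_start[i] - slot$y_start + 1L):
                   (d$span_end[i] - slot$y_start)] <- TRUE
  }
  frames <- vector("list", length(tgrid))
  with_local_seed(seed, {
    phase <- runif(1, 0, 2 * pi)
    bubbles <- NULL
    if (noise$bubbles > 0L) {
      bubbles <- cbind(sample.int(H, noise$bubbles),
                       sample(inner, noise$bubbles, replace = TRUE))
    }
    for (j in seq_along(tgrid)) {
      fr <- array(0, dim = c(H, W, 3L))
      for (ch in 1:3) fr[, , ch] <- OIL_RGB[ch]
      fr[droplet_rows, inner, 1L] <- REST_RGB[1L]
      fr[droplet_rows, inner, 2L] <- REST_RGB[2L]
      blue <- blue_profile(sim, layout, j, tgrid, front_width_px,
                           core$acc_list)
      fr[, inner, 3L] <- matrix(blue, nrow = H, ncol = length(inner))
      if (noise$drift_frac > 0) {
        fr <- fr + noise$drift_frac * BAND_BLUE *
          sin(2 * pi * tgrid[j] / noise$drift_period_s + phase)
      }
      if (noise$sd_frac > 0) {
        fr <- fr + array(rnorm(length(fr), 0, noise$sd_frac * BAND_BLUE),
                         dim = dim(fr))
      }
      if (!is.null(bubbles)) {
        for (b in seq_len(nrow(bubbles))) {
          fr[bubbles[b, 1L], bubbles[b, 2L], ] <-
            fr[bubbles[b, 1L], bubbles[b, 2L], ] + noise$bubble_level
        }
      }
      frames[[j]] <- pmin(pmax(fr, 0), 1)
    }
  })
  frame_stack(frames, frame_rate = sim$config$frame_rate, t0_offset = 0)
}
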