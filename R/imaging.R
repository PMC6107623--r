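#' Frame stacks
#'
#' A frame stack is the raw observational unit: an ordered set of
#' equally-sized video frames with a fixed frame rate. Frames are numeric
#' arrays in `[0, 1]`, either `H x W` (grayscale) or `H x W x 3` (RGB).
#' Timestamps are `t0_offset + index / frame_rate` seconds with a 0-based
#' frame index, i.e. all times are measured from the completion of mixing;
#' `t0_offset` is the delay between mixing and the first recorded frame.
#'
#' @param frames A list of numeric arrays sharing identical dimensions and
#'   channel count.
#' @param frame_rate Frames per second (default 0.4, the study acquisition
#'   rate).
#' @param t0_offset Seconds between completion of mixing and the first frame.
#' @return An object of class `bz_frames` with elements `frames`,
#'   `frame_rate`, `t0_offset` and `times`.
#' @export
frame_stack <- function(frames, frame_rate = 0.4, t0_offset = 0) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_dropwave("a frame stack needs at least one frame", "dropwave_validation_error")
  }
  if (!is_number(frame_rate) || frame_rate <= 0) {
    stop_dropwave("frame_rate must be a positive number", "dropwave_validation_error")
  }
  dims <- lapply(frames, dim)
  ref <- dims[[1L]]
  same <- vapply(dims, function(d) length(d) == length(ref) && all(d == ref), logical(1))
  if (!all(same)) {
    stop_dropwave(sprintf("frames have mismatched dimensions (frame %d differs from frame 1)",
                          which(!same)[1L]), "dropwave_validation_error")
  }
  if (!length(ref) %in% c(2L, 3L) || (length(ref) == 3L && ref[3L] != 3L)) {
    stop_dropwave("frames must be H x W or H x W x 3 arrays", "dropwave_validation_error")
  }
  structure(
    list(frames = frames, frame_rate = frame_rate, t0_offset = t0_offset,
         times = t0_offset + (seq_along(frames) - 1) / frame_rate),
    class = "bz_frames"
  )
}

#' @export
print.bz_frames <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<bz_frames: %d frame(s) of %d x %d%s at %g fps, t0_offset %g s>\n",
              length(x$frames), d[1L], d[2L],
              if (length(d) == 3L) " x 3 (RGB)" else " (gray)",
              x$frame_rate, x$t0_offset))
  invisible(x)
}

#' Read a directory of image frames
#'
#' Reads every PNG in `path` in lexicographic order (which must equal
#' temporal order, e.g. zero-padded frame numbers) into a [frame_stack()].
#'
#' @inheritParams frame_stack
#' @param path Directory containing the frames.
#' @param pattern Filename regexp, default `"\\.png$"`.
#' @return A `bz_frames` stack.
#' @export
read_frames <- function(path, frame_rate = 0.4, t0_offset = 0,
                        pattern = "\\.png$") {
  if (!dir.exists(path)) {
    stop_dropwave(sprintf("frame directory not found: %s", path), "dropwave_io_error")
  }
  files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) {
    stop_dropwave(sprintf("no frames matching '%s' in %s", pattern, path),
                  "dropwave_io_error")
  }
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L && dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
    img
  })
  frame_stack(frames, frame_rate = frame_rate, t0_offset = t0_offset)
}

#' Write a frame stack as numbered PNG files
#'
#' @param stack A `bz_frames` stack.
#' @param path Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "bz_frames"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  nd <- max(5L, nchar(length(stack$frames)))
  for (i in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[i]],
                  file.path(path, sprintf("frame_%0*d.png", nd, i)))
  }
  invisible(path)
}

channel_index <- function(channel) {
  switch(channel,
         red = 1L, green = 2L, blue = 3L, gray = 0L,
         stop_dropwave(sprintf("unknown channel '%s'", channel),
                       "dropwave_config_error"))
}

# x-pixel range of a strip of `width` centred on centre_x (0-based, inclusive).
# Odd widths centre exactly; even widths take one extra pixel on the low side.
strip_range <- function(centre_x, width) {
  lo <- centre_x - width %/% 2L
  if (width %% 2L == 0L) lo <- lo + 0L  # even width: [c - w/2, c + w/2 - 1]
  c(lo, lo + width - 1L)
}

#' Build a space-time plot (kymograph) from a frame stack
#'
#' Implements the strip-cropping construction: from every video frame a
#' `strip_width`-pixel-wide strip is cropped along the centre of the slot,
#' blurred in the x-direction (across the strip), and the strips are placed
#' side by side in temporal order. With the default full-width mean blur the
#' `strip_width` columns contributed by one frame are identical; setting
#' `collapse = TRUE` keeps a single column per frame, which is analytically
#' equivalent for every trace-level operation and more compact to plot.
#'
#' Orientation is canonical: time on x (columns), position along the slot on
#' y (rows). Intensities are rescaled from `[0, 1]` to 8-bit arbitrary units
#' (0-255).
#'
#' @param stack A [frame_stack()].
#' @param layout A [bz_layout()] (or a single-row slots data frame).
#' @param slot_id Which slot to crop; defaults to the first in the layout.
#' @param strip_width Strip width in pixels across the slot (default 15).
#' @param channel Colour channel carrying the redox signal: `"blue"`
#'   (default; ferroin's oxidised state is blue), `"red"`, `"green"`, or
#'   `"gray"` for single-channel frames.
#' @param blur_width Width of the mean box kernel used for the x-blur;
#'   defaults to the full strip width.
#' @param collapse If `TRUE`, emit one column per frame instead of
#'   `strip_width` identical columns.
#' @return A `bz_kymograph`: a numeric matrix (rows = slot position, columns
#'   = time) with attributes `times`, `frame_rate`, `t0_offset`,
#'   `strip_width`, `cols_per_frame`, `channel`, `slot_id`, `y_start`.
#' @export
build_kymograph <- function(stack, layout, slot_id = NULL, strip_width = 15L,
                            channel = "blue", blur_width = strip_width,
                            collapse = FALSE) {
  stopifnot(inherits(stack, "bz_frames"))
  slot <- resolve_slot(layout, slot_id)
  d <- dim(stack$frames[[1L]])
  ch <- channel_index(channel)
  if (ch > 0L && length(d) != 3L) {
    if (channel != "gray") channel <- "gray"
    ch <- 0L  # grayscale input: use the single channel
  }
  xr <- strip_range(slot$centre_x, as.integer(strip_width))
  ys <- slot$y_start; ye <- slot$y_end
  if (xr[1L] < 0L || xr[2L] >= d[2L] || ys < 0L || ye > d[1L]) {
    stop_dropwave(sprintf(
      "strip [x %d..%d, y %d..%d) exceeds the %d x %d frame bounds",
      xr[1L], xr[2L], ys, ye, d[1L], d[2L]), "dropwave_geometry_error")
  }
  rows <- (ys + 1L):ye          # 1-based row indices for 0-based [ys, ye)
  cols <- (xr[1L] + 1L):(xr[2L] + 1L)
  n_frames <- length(stack$frames)
  blur_width <- max(1L, min(as.integer(blur_width), as.integer(strip_width)))
  cols_per_frame <- if (collapse) 1L else as.integer(strip_width)
  out <- matrix(0, nrow = length(rows), ncol = n_frames * cols_per_frame)
  for (i in seq_len(n_frames)) {
    f <- stack$frames[[i]]
    strip <- if (ch == 0L) f[rows, cols, drop = FALSE] else f[rows, cols, ch]
    blurred <- blur_x(strip, blur_width)
    j0 <- (i - 1L) * cols_per_frame
    if (collapse) {
      out[, j0 + 1L] <- rowMeans(blurred)
    } else {
      out[, (j0 + 1L):(j0 + cols_per_frame)] <- blurred
    }
  }
  structure(out * 255,
            class = c("bz_kymograph", "matrix"),
            times = stack$times, frame_rate = stack$frame_rate,
            t0_offset = stack$t0_offset,
            strip_width = as.integer(strip_width),
            cols_per_frame = cols_per_frame,
            channel = channel, slot_id = slot$slot_id,
            y_start = as.integer(ys))
}

# mean box blur along x (columns) with truncated edges; width = ncol gives
# the full-width mean, making all columns identical
blur_x <- function(strip, width) {
  w <- ncol(strip)
  if (width >= w) {
    m <- rowMeans(strip)
    return(matrix(m, nrow = nrow(strip), ncol = w))
  }
  if (width <= 1L) return(strip)
  half <- (width - 1L) %/% 2L
  out <- strip
  for (j in seq_len(w)) {
    jj <- max(1L, j - half):min(w, j - half + width - 1L)
    out[, j] <- rowMeans(strip[, jj, drop = FALSE])
  }
  out
}

resolve_slot <- function(layout, slot_id = NULL) {
  s <- if (inherits(layout, "bz_layout")) layout$slots else as_tibble(layout)
  if (!is.null(slot_id)) s <- s[s$slot_id == slot_id, ]
  if (nrow(s) == 0L) {
    stop_dropwave("slot not found in layout", "dropwave_validation_error")
  }
  as.list(s[1L, ])
}

#' @export
print.bz_kymograph <- function(x, ...) {
  cat(sprintf("<bz_kymograph '%s': %d px x %d columns (%d frame(s), %s channel)>\n",
              attr(x, "slot_id"), nrow(x),
              ncol(x), length(attr(x, "times")), attr(x, "channel")))
  invisible(x)
}

kymo_frame_values <- function(kymo) {
  # one representative column per frame (columns within a frame are
  # identical under full-width blur; otherwise their mean)
  cpf <- attr(kymo, "cols_per_frame")
  n <- length(attr(kymo, "times"))
  if (cpf == 1L) return(unclass(kymo)[, seq_len(n), drop = FALSE])
  sapply(seq_len(n), function(i) {
    rowMeans(unclass(kymo)[, ((i - 1L) * cpf + 1L):(i * cpf), drop = FALSE])
  })
}

#' Extract a droplet's intensity trace from a kymograph
#'
#' For each frame the mean intensity over a `strip_width x height` pixel
#' region at a y-position near the droplet centre is taken (the default
#' 15 x 5 px region of the standard calibration), yielding one scalar per
#' frame.
#'
#' @param kymo A [build_kymograph()] result.
#' @param roi A single droplet row from a layout's `$droplets` (or a
#'   `bz_layout` plus `droplet_id`).
#' @param droplet_id Droplet to extract when `roi` is a layout.
#' @param height Height in pixels of the averaging region (default 5).
#' @return A tibble with columns `droplet_id`, `frame` (0-based), `time_s`
#'   and `intensity` (raw, 0-255 AU).
#' @export
extract_trace <- function(kymo, roi, droplet_id = NULL, height = 5L) {
  stopifnot(inherits(kymo, "bz_kymograph"))
  if (inherits(roi, "bz_layout")) {
    d <- roi$droplets
    if (!is.null(droplet_id)) d <- d[d$droplet_id == droplet_id, ]
    if (nrow(d) == 0L) stop_dropwave("droplet not found", "dropwave_validation_error")
    roi <- d[1L, ]
  }
  roi <- as.list(as_tibble(roi)[1L, ])
  height <- as.integer(height)
  yr <- strip_range(roi$centre_y, height)  # even heights bias one px low
  if (yr[1L] < roi$span_start || yr[2L] >= roi$span_end) {
    stop_dropwave(sprintf(
      paste0("the %d px trace region [%d..%d] crosses the boundary of droplet ",
             "'%s' [%d..%d); choose a centre_y further inside the droplet"),
      height, yr[1L], yr[2L], roi$droplet_id, roi$span_start, roi$span_end),
      "dropwave_geometry_error")
  }
  y0 <- attr(kymo, "y_start")
  rows <- (yr[1L] - y0 + 1L):(yr[2L] - y0 + 1L)
  if (rows[1L] < 1L || rows[length(rows)] > nrow(kymo)) {
    stop_dropwave("trace region lies outside the kymograph", "dropwave_geometry_error")
  }
  vals <- colMeans(kymo_frame_values(kymo)[rows, , drop = FALSE])
  tibble(
    droplet_id = roi$droplet_id,
    frame = seq_along(vals) - 1L,
    time_s = attr(kymo, "times"),
    intensity = as.numeric(vals)
  )
}

#' @rdname extract_trace
#' @param layout A `bz_layout`; traces are extracted for every droplet whose
#'   slot matches the kymograph.
#' @export
extract_traces <- function(kymo, layout, height = 5L) {
  stopifnot(inherits(layout, "bz_layout"))
  d <- layout$droplets[layout$droplets$slot_id == attr(kymo, "slot_id"), ]
  purrr::map_dfr(seq_len(nrow(d)), function(i) {
    extract_trace(kymo, d[i, ], height = height)
  })
}
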