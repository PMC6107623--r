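#' Slot-template layouts and droplet regions of interest
#'
#' A layout describes the acrylic slot template an experiment was recorded in:
#' where each slot lies in the image, its pixel/physical calibration, and the
#' final resting span of every droplet along the slot. Downstream operations
#' address droplets by identity (`droplet_id`) rather than raw pixels.
#'
#' Conventions: coordinates are 0-based pixels; droplet spans are half-open
#' `[span_start, span_end)` along the slot axis; time is seconds from the
#' start of the recording. Slots are axis-aligned with the image y-axis
#' (`axis = c(0, 1)`): the centreline is the vertical pixel path at
#' `centre_x` from `y_start` (inclusive) to `y_end` (exclusive). Droplets are
#' positioned by gravity at the lower end of the inclined slot; the layout
#' records their final spans explicitly. A droplet's neighbour on either side
#' is another `droplet_id`, the reserved marker `"wall"` (contact with the
#' acrylic slot wall), or `"none"` (open oil).
#'
#' @param slots A data frame with one row per slot and columns `slot_id`,
#'   `centre_x`, `y_start`, `y_end`, `width_px`, `width_mm`, `length_mm`,
#'   `incline_deg` (and optionally `axis_x`, `axis_y`, defaulting to 0, 1).
#' @param droplets A data frame with one row per droplet and columns
#'   `droplet_id`, `slot_id`, `span_start`, `span_end`, `centre_y`,
#'   `neighbour_prev`, `neighbour_next`.
#' @return An object of class `bz_layout`: a list with tibbles `$slots` and
#'   `$droplets`, droplet rows sorted along each slot axis.
#' @seealso [read_layout()], [write_layout()], [pixel_scale()], [linear_layout()]
#' @export
bz_layout <- function(slots, droplets = NULL) {
  slots <- as_tibble(slots)
  if (is.null(droplets)) {
    droplets <- tibble(
      droplet_id = character(), slot_id = character(),
      span_start = integer(), span_end = integer(), centre_y = integer(),
      neighbour_prev = character(), neighbour_next = character()
    )
  }
  droplets <- as_tibble(droplets)
  if (!"axis_x" %in% names(slots)) slots$axis_x <- 0
  if (!"axis_y" %in% names(slots)) slots$axis_y <- 1
  need_s <- c("slot_id", "centre_x", "y_start", "y_end", "width_px",
              "width_mm", "length_mm", "incline_deg")
  miss <- setdiff(need_s, names(slots))
  if (length(miss) > 0) {
    stop_dropwave(paste0("layout slots are missing field(s): ",
                         paste(miss, collapse = ", ")), "dropwave_parse_error")
  }
  need_d <- c("droplet_id", "slot_id", "span_start", "span_end", "centre_y",
              "neighbour_prev", "neighbour_next")
  miss <- setdiff(need_d, names(droplets))
  if (length(miss) > 0) {
    stop_dropwave(paste0("layout droplets are missing field(s): ",
                         paste(miss, collapse = ", ")), "dropwave_parse_error")
  }
  droplets <- dplyr::arrange(droplets, .data$slot_id, .data$span_start)
  out <- structure(list(slots = slots, droplets = droplets), class = "bz_layout")
  validate_layout(out)
  out
}

validate_layout <- function(layout) {
  s <- layout$slots
  d <- layout$droplets
  if (any(s$width_px <= 0)) {
    stop_dropwave("slot width_px must be > 0", "dropwave_validation_error")
  }
  if (any(s$width_mm <= 0)) {
    stop_dropwave("slot width_mm must be > 0", "dropwave_validation_error")
  }
  if (any(s$y_end <= s$y_start)) {
    stop_dropwave("slot centreline must have positive length (y_end > y_start)",
                  "dropwave_validation_error")
  }
  if (anyDuplicated(s$slot_id)) {
    stop_dropwave("duplicate slot_id in layout", "dropwave_validation_error")
  }
  if (nrow(d) == 0L) return(invisible(layout))
  if (anyDuplicated(d$droplet_id)) {
    stop_dropwave("duplicate droplet_id in layout", "dropwave_validation_error")
  }
  if (!all(d$slot_id %in% s$slot_id)) {
    stop_dropwave("droplet references an unknown slot_id", "dropwave_validation_error")
  }
  if (any(d$span_end <= d$span_start)) {
    stop_dropwave("droplet span must be non-empty (span_end > span_start)",
                  "dropwave_validation_error")
  }
  bad <- d$centre_y < d$span_start | d$centre_y >= d$span_end
  if (any(bad)) {
    stop_dropwave(sprintf("centre_y outside droplet span for: %s",
                          paste(d$droplet_id[bad], collapse = ", ")),
                  "dropwave_validation_error")
  }
  # spans inside the slot centreline, disjoint within each slot
  for (sid in unique(d$slot_id)) {
    di <- d[d$slot_id == sid, ]
    si <- s[s$slot_id == sid, ]
    if (any(di$span_start < si$y_start) || any(di$span_end > si$y_end)) {
      stop_dropwave(sprintf("droplet span outside slot '%s' centreline", sid),
                    "dropwave_validation_error")
    }
    di <- di[order(di$span_start), ]
    if (nrow(di) > 1L && any(di$span_start[-1] < di$span_end[-nrow(di)])) {
      stop_dropwave(sprintf("overlapping droplet spans in slot '%s'", sid),
                    "dropwave_validation_error")
    }
  }
  # neighbour symmetry: prev/next must be a droplet_id, "wall" or "none",
  # and if A lists B then B lists A on the facing side
  ids <- d$droplet_id
  ref_ok <- function(x) x %in% c(ids, "wall", "none")
  if (!all(ref_ok(d$neighbour_prev)) || !all(ref_ok(d$neighbour_next))) {
    stop_dropwave("neighbour reference is neither a droplet_id, 'wall' nor 'none'",
                  "dropwave_validation_error")
  }
  for (i in seq_len(nrow(d))) {
    nb <- d$neighbour_next[i]
    if (nb %in% ids && d$neighbour_prev[d$droplet_id == nb] != d$droplet_id[i]) {
      stop_dropwave(sprintf("asymmetric neighbour link %s -> %s",
                            d$droplet_id[i], nb), "dropwave_validation_error")
    }
    nb <- d$neighbour_prev[i]
    if (nb %in% ids && d$neighbour_next[d$droplet_id == nb] != d$droplet_id[i]) {
      stop_dropwave(sprintf("asymmetric neighbour link %s -> %s",
                            d$droplet_id[i], nb), "dropwave_validation_error")
    }
  }
  invisible(layout)
}

#' @export
print.bz_layout <- function(x, ...) {
  cat(sprintf("<bz_layout: %d slot(s), %d droplet(s)>\n",
              nrow(x$slots), nrow(x$droplets)))
  print(x$slots, ...)
  print(x$droplets, ...)
  invisible(x)
}

#' Read or write a layout file
#'
#' Layouts are stored as JSON with top-level arrays `slots` and `droplets`
#' whose element fields match the columns documented in [bz_layout()]. The
#' round trip `read_layout(write_layout(x, f))` reproduces the layout
#' field-by-field.
#'
#' @param path Path to a layout JSON file.
#' @return `read_layout()` returns a validated `bz_layout`; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) {
    stop_dropwave(sprintf("layout file not found: %s", path), "dropwave_io_error")
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    error = function(e) stop_dropwave(
      sprintf("malformed layout JSON (%s): %s", path, conditionMessage(e)),
      "dropwave_parse_error")
  )
  if (is.null(raw$slots)) {
    stop_dropwave("layout file has no 'slots' field", "dropwave_parse_error")
  }
  droplets <- raw$droplets
  if (is.null(droplets) || length(droplets) == 0L) droplets <- NULL
  bz_layout(as_tibble(raw$slots), droplets)
}

#' @param layout A `bz_layout`.
#' @rdname read_layout
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "bz_layout"))
  jsonlite::write_json(
    list(slots = layout$slots, droplets = layout$droplets),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Pixel/physical calibration of each slot
#'
#' The pixel scale of a slot is its physical width divided by its pixel
#' width. With the default template calibration a 2.5 mm slot spans 108
#' pixels, i.e. 0.0231 mm per pixel; scaling both widths by the same factor
#' leaves the result unchanged.
#'
#' @param slots A `bz_layout` or a slots data frame with `slot_id`,
#'   `width_mm` and `width_px` columns.
#' @return A tibble with columns `slot_id` and `mm_per_px`.
#' @export
#' @examples
#' pixel_scale(data.frame(slot_id = "s", width_mm = 2.5, width_px = 108))
pixel_scale <- function(slots) {
  if (inherits(slots, "bz_layout")) slots <- slots$slots
  slots <- as_tibble(slots)
  if (any(slots$width_px <= 0)) {
    stop_dropwave("width_px must be > 0 to define a pixel scale",
                  "dropwave_validation_error")
  }
  tibble(slot_id = slots$slot_id, mm_per_px = slots$width_mm / slots$width_px)
}

#' Build a linear slot layout of equally sized droplets
#'
#' Convenience constructor for the common experimental geometry: one straight
#' slot holding `n_droplets` droplets of equal span stacked end-to-end, the
#' first and last in contact with the slot wall. Defaults mirror the template
#' calibration (2.5 mm slot width imaged over 108 px, 0.5 degree incline).
#'
#' @param n_droplets Number of droplets in the slot.
#' @param droplet_px Span of each droplet along the slot, in pixels.
#' @param width_px,width_mm Slot width in pixels and millimetres.
#' @param incline_deg Dish tilt in degrees.
#' @param slot_id,id_prefix Labels for the slot and the droplets.
#' @param centre_x X pixel of the slot centreline (defaults to the strip
#'   centre of a frame just wide enough for a 15 px strip).
#' @param y_start First centreline pixel of the slot.
#' @return A `bz_layout` with one slot and `n_droplets` droplet ROIs whose
#'   neighbour links are symmetric, wall-terminated at both ends.
#' @export
linear_layout <- function(n_droplets, droplet_px = 108L, width_px = 108L,
                          width_mm = 2.5, incline_deg = 0.5,
                          slot_id = "slot1", id_prefix = "d",
                          centre_x = 15L, y_start = 0L) {
  n_droplets <- as.integer(n_droplets)
  stopifnot(n_droplets >= 0L, droplet_px > 0L)
  length_px <- n_droplets * droplet_px
  scale <- width_mm / width_px
  slots <- tibble(
    slot_id = slot_id, axis_x = 0, axis_y = 1,
    centre_x = as.integer(centre_x),
    y_start = as.integer(y_start),
    y_end = as.integer(y_start + max(length_px, droplet_px)),
    width_px = as.integer(width_px), width_mm = width_mm,
    length_mm = max(length_px, droplet_px) * scale,
    incline_deg = incline_deg
  )
  if (n_droplets == 0L) return(bz_layout(slots))
  ids <- paste0(id_prefix, seq_len(n_droplets))
  starts <- y_start + (seq_len(n_droplets) - 1L) * droplet_px
  droplets <- tibble(
    droplet_id = ids, slot_id = slot_id,
    span_start = as.integer(starts),
    span_end = as.integer(starts + droplet_px),
    centre_y = as.integer(starts + droplet_px %/% 2L),
    neighbour_prev = c("wall", ids[-n_droplets]),
    neighbour_next = c(ids[-1L], "wall")
  )
  bz_layout(slots, droplets)
}

#' Droplet-droplet interfaces of a layout
#'
#' Lists every boundary between two adjacent droplets in the same slot; these
#' are the candidate sites for interdroplet wave propagation.
#'
#' @param layout A `bz_layout`.
#' @return A tibble with columns `interface` (label `"a|b"`), `slot_id`,
#'   `droplet_a`, `droplet_b` and `boundary_px` (the shared span boundary).
#' @export
layout_interfaces <- function(layout) {
  stopifnot(inherits(layout, "bz_layout"))
  d <- layout$droplets
  out <- list()
  for (i in seq_len(nrow(d))) {
    nb <- d$neighbour_next[i]
    if (nb %in% d$droplet_id) {
      out[[length(out) + 1L]] <- tibble(
        interface = paste(d$droplet_id[i], nb, sep = "|"),
        slot_id = d$slot_id[i],
        droplet_a = d$droplet_id[i], droplet_b = nb,
        boundary_px = d$span_end[i]
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(interface = character(), slot_id = character(),
                  droplet_a = character(), droplet_b = character(),
                  boundary_px = numeric()))
  }
  dplyr::bind_rows(out)
}
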