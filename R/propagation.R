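#' Binarise oxidation wavefronts in a kymograph
#'
#' Marks the oxidised (high blue-channel intensity) bands of a space-time
#' plot. The threshold is adaptive per time column — the column minimum plus
#' a fraction of the column's intensity range — so slow baseline or
#' illumination drift does not flip the mask. Columns whose contrast falls
#' below `min_contrast` (no front present, or a degenerate constant
#' kymograph) stay entirely unmarked.
#'
#' @param kymo A `bz_kymograph`.
#' @param frac Threshold position within the column's intensity range
#'   (default 0.5).
#' @param min_contrast Minimum column intensity range (8-bit AU) for any
#'   pixel of the column to be marked (default 40).
#' @return A logical matrix of class `bz_front_mask` (rows = slot position,
#'   one column per frame) with the kymograph's time/geometry attributes.
#' @export
binarize_fronts <- function(kymo, frac = 0.5, min_contrast = 40) {
  stopifnot(inherits(kymo, "bz_kymograph"))
  v <- kymo_frame_values(kymo)
  lo <- apply(v, 2L, min)
  hi <- apply(v, 2L, max)
  contrast <- hi - lo
  thr <- lo + frac * contrast
  mask <- sweep(v, 2L, thr, `>=`)
  mask[, contrast < min_contrast] <- FALSE
  structure(mask,
            class = c("bz_front_mask", "matrix"),
            times = attr(kymo, "times"),
            frame_rate = attr(kymo, "frame_rate"),
            slot_id = attr(kymo, "slot_id"),
            y_start = attr(kymo, "y_start"))
}

# per-column detections: maximal TRUE runs with their centroid in absolute
# slot coordinates
column_detections <- function(col, y_start) {
  r <- rle(as.logical(col))
  if (!any(r$values)) return(numeric(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- (starts + ends) / 2
  (mid[r$values] - 1) + y_start
}

#' Track travelling wavefronts through a front mask
#'
#' Links the per-column mask components frame-to-frame into wavefront
#' tracks: each detection is matched to the nearest active track within
#' `max_dy_px` per frame of gap; unmatched detections open new tracks (so a
#' source emitting two opposite fronts yields two tracks sharing an origin);
#' a track unmatched for more than `max_gap_frames` frames is closed. Closed
#' tracks are labelled with exactly one termination: `"annihilation"` (a
#' partner track of opposite direction ended at the same place and time),
#' `"boundary"` (the slot end, or the end of the recording), or
#' `"dissipation"` (anything else — including a front blocked at a
#' droplet-droplet interface). Interface crossings are recorded where
#' consecutive track samples straddle a droplet boundary within
#' `crossing_max_gap` frames.
#'
#' @param mask A [binarize_fronts()] mask.
#' @param layout The slot [bz_layout()].
#' @param max_dy_px Maximum position jump per frame of gap when linking
#'   (default 18).
#' @param max_gap_frames Frames a track may go undetected before closing
#'   (default 2; covers interface crossing delays without chaining
#'   successive waves).
#' @param min_track_len Minimum samples for a track to be kept (default 2).
#' @param crossing_max_gap Maximum frame gap across an interface for a
#'   crossing (default 3).
#' @param edge_margin_px Distance from the slot ends within which a closed
#'   track terminates at the `"boundary"` (default 6).
#' @return A `bz_tracks` object: list with tibbles `$samples` (`track_id`,
#'   `time_s`, `position_px`, `droplet_id`), `$tracks` (per-track summary
#'   with `direction` and `termination`), and `$crossings` (`track_id`,
#'   `interface`, `time_s`, `delay_s`).
#' @export
track_wavefronts <- function(mask, layout, max_dy_px = 18,
                             max_gap_frames = 2L, min_track_len = 2L,
                             crossing_max_gap = 3L, edge_margin_px = 6) {
  stopifnot(inherits(mask, "bz_front_mask"), inherits(layout, "bz_layout"))
  times <- attr(mask, "times")
  y_start <- attr(mask, "y_start")
  n <- ncol(mask)
  slot <- resolve_slot(layout, attr(mask, "slot_id"))
  active <- list()   # id, last_y, last_frame, ys, frames
  closed <- list()
  next_id <- 1L
  close_track <- function(tr, end_frame) {
    tr$end_frame <- end_frame
    closed[[length(closed) + 1L]] <<- tr
  }
  for (j in seq_len(n)) {
    dets <- column_detections(mask[, j], y_start)
    # retire stale tracks
    if (length(active) > 0L) {
      stale <- vapply(active, function(a) j - a$last_frame > max_gap_frames,
                      logical(1))
      for (a in active[stale]) close_track(a, a$last_frame)
      active <- active[!stale]
    }
    if (length(dets) > 0L && length(active) > 0L) {
      # greedy nearest matching, one detection per track
      pairs <- expand.grid(ai = seq_along(active), di = seq_along(dets))
      pairs$dist <- abs(vapply(active, function(a) a$last_y, numeric(1))[pairs$ai] -
                          dets[pairs$di])
      gap <- vapply(active, function(a) j - a$last_frame, numeric(1))[pairs$ai]
      pairs <- pairs[pairs$dist <= max_dy_px * gap, , drop = FALSE]
      pairs <- pairs[order(pairs$dist), , drop = FALSE]
      used_a <- logical(length(active))
      used_d <- logical(length(dets))
      for (k in seq_len(nrow(pairs))) {
        ai <- pairs$ai[k]; di <- pairs$di[k]
        if (used_a[ai] || used_d[di]) next
        used_a[ai] <- TRUE; used_d[di] <- TRUE
        active[[ai]]$last_y <- dets[di]
        active[[ai]]$last_frame <- j
        active[[ai]]$ys <- c(active[[ai]]$ys, dets[di])
        active[[ai]]$frames <- c(active[[ai]]$frames, j)
      }
      dets <- dets[!used_d]
    }
    for (y in dets) {
      active[[length(active) + 1L]] <- list(
        id = next_id, last_y = y, last_frame = j, ys = y, frames = j)
      next_id <- next_id + 1L
    }
  }
  for (a in active) close_track(a, a$last_frame)
  closed <- closed[vapply(closed, function(tr) length(tr$ys) >= min_track_len,
                          logical(1))]
  if (length(closed) == 0L) {
    return(empty_tracks(layout))
  }
  d <- layout$droplets
  locate_droplet <- function(y) {
    i <- which(d$span_start <= y & y < d$span_end)
    if (length(i) == 0L) NA_character_ else d$droplet_id[i[1L]]
  }
  ifc <- layout_interfaces(layout)
  samples <- list()
  summaries <- list()
  crossings <- list()
  for (tr in closed) {
    ts <- times[tr$frames]
    dr <- vapply(tr$ys, locate_droplet, character(1))
    samples[[length(samples) + 1L]] <- tibble(
      track_id = tr$id, time_s = ts, position_px = tr$ys, droplet_id = dr)
    disp <- tr$ys[length(tr$ys)] - tr$ys[1L]
    direction <- if (abs(disp) < 2) "stationary" else if (disp > 0) "down" else "up"
    # interface crossings along this track
    if (nrow(ifc) > 0L && length(tr$ys) > 1L) {
      for (k in seq_len(length(tr$ys) - 1L)) {
        if (tr$frames[k + 1L] - tr$frames[k] > crossing_max_gap) next
        y1 <- tr$ys[k]; y2 <- tr$ys[k + 1L]
        hit <- which((pmin(y1, y2) < ifc$boundary_px) &
                       (ifc$boundary_px <= pmax(y1, y2)))
        for (h in hit) {
          tcross <- ts[k] + (ts[k + 1L] - ts[k]) *
            (ifc$boundary_px[h] - y1) / (y2 - y1)
          crossings[[length(crossings) + 1L]] <- tibble(
            track_id = tr$id, interface = ifc$interface[h],
            time_s = tcross, delay_s = ts[k + 1L] - ts[k])
        }
      }
    }
    summaries[[length(summaries) + 1L]] <- tibble(
      track_id = tr$id, n_samples = length(tr$ys),
      start_s = ts[1L], end_s = ts[length(ts)],
      start_px = tr$ys[1L], end_px = tr$ys[length(tr$ys)],
      direction = direction,
      droplets_visited = paste(unique(dr[!is.na(dr)]), collapse = ","),
      n_droplets = length(unique(dr[!is.na(dr)])),
      termination = NA_character_
    )
  }
  samples <- dplyr::bind_rows(samples)
  tracks <- dplyr::bind_rows(summaries)
  crossings <- if (length(crossings)) {
    # one crossing per (track, interface): keep the first
    dplyr::distinct(dplyr::arrange(dplyr::bind_rows(crossings),
                                   .data$time_s),
                    .data$track_id, .data$interface, .keep_all = TRUE)
  } else {
    tibble(track_id = integer(), interface = character(),
           time_s = numeric(), delay_s = numeric())
  }
  # terminations: boundary (slot end or record end), annihilation (opposing
  # partner closing at the same place/time), else dissipation
  slot_lo <- min(d$span_start); slot_hi <- max(d$span_end)
  dt <- if (length(times) > 1L) median(diff(times)) else 1
  for (i in seq_len(nrow(tracks))) {
    yend <- tracks$end_px[i]
    at_edge <- yend <= slot_lo + edge_margin_px || yend >= slot_hi - edge_margin_px
    at_record_end <- tracks$end_s[i] >= times[n] - dt / 2
    if (at_edge || at_record_end) {
      tracks$termination[i] <- "boundary"
      next
    }
    partner <- which(
      seq_len(nrow(tracks)) != i &
        abs(tracks$end_s - tracks$end_s[i]) <= (max_gap_frames + 1) * dt &
        abs(tracks$end_px - tracks$end_px[i]) <= 2 * max_dy_px &
        tracks$direction != tracks$direction[i] &
        tracks$direction != "stationary"
    )
    tracks$termination[i] <- if (length(partner) > 0L &&
                                 tracks$direction[i] != "stationary") {
      "annihilation"
    } else {
      "dissipation"
    }
  }
  structure(list(samples = samples, tracks = tracks, crossings = crossings,
                 layout = layout),
            class = "bz_tracks")
}

empty_tracks <- function(layout) {
  structure(list(
    samples = tibble(track_id = integer(), time_s = numeric(),
                     position_px = numeric(), droplet_id = character()),
    tracks = tibble(track_id = integer(), n_samples = integer(),
                    start_s = numeric(), end_s = numeric(),
                    start_px = numeric(), end_px = numeric(),
                    direction = character(), droplets_visited = character(),
                    n_droplets = integer(), termination = character()),
    crossings = tibble(track_id = integer(), interface = character(),
                       time_s = numeric(), delay_s = numeric()),
    layout = layout), class = "bz_tracks")
}

#' @export
print.bz_tracks <- function(x, ...) {
  cat(sprintf("<bz_tracks: %d track(s), %d crossing(s)>\n",
              nrow(x$tracks), nrow(x$crossings)))
  print(x$tracks, ...)
  invisible(x)
}

#' Classify interdroplet propagation, wave origins and annihilations
#'
#' Aggregates wavefront tracks into the propagation evidence: per interface,
#' how many arriving fronts crossed (propagated) versus terminated there
#' (blocked), and whether the interface counts as coupled (crossed fraction
#' at least `min_cross_frac` within the delay window); per droplet, where
#' each entering front originated (the droplet interior, the interface on
#' its upper or lower side, or a contact point with the slot wall); plus the
#' list of wave-annihilation events.
#'
#' @param tracks A [track_wavefronts()] result.
#' @param min_cross_frac Minimum propagated fraction for a coupled call
#'   (default 0.5).
#' @param delay_window_s Maximum crossing delay for a front to count as
#'   propagated rather than independently excited; default one oscillation
#'   period estimated as 25 s.
#' @param arrive_margin_px A dissipating track ending within this distance
#'   of an interface counts as a blocked arrival (default 10).
#' @param origin_margin_px A track sample this close to a droplet edge marks
#'   an interface/wall origin (default 8).
#' @return A `bz_propagation` object: list with tibbles `$interfaces`
#'   (`propagated`, `blocked`, `total`, `coupled`), `$origins` (`droplet_id`,
#'   `track_id`, `origin`, `time_s`) and `$annihilations` (`time_s`,
#'   `position_px`). `tidy()` returns the interface table, `glance()` the
#'   totals.
#' @export
classify_interfaces <- function(tracks, min_cross_frac = 0.5,
                                delay_window_s = 25,
                                arrive_margin_px = 10,
                                origin_margin_px = 8) {
  stopifnot(inherits(tracks, "bz_tracks"))
  layout <- tracks$layout
  ifc <- layout_interfaces(layout)
  d <- layout$droplets
  cr <- tracks$crossings
  cr <- cr[cr$delay_s <= delay_window_s, , drop = FALSE]
  propagated <- blocked <- integer(nrow(ifc))
  for (i in seq_len(nrow(ifc))) {
    propagated[i] <- sum(cr$interface == ifc$interface[i])
    ends <- tracks$tracks[tracks$tracks$termination == "dissipation", ]
    blocked[i] <- sum(abs(ends$end_px - ifc$boundary_px[i]) <= arrive_margin_px)
  }
  interfaces <- tibble(
    interface = ifc$interface, slot_id = ifc$slot_id,
    propagated = propagated, blocked = blocked,
    total = propagated + blocked,
    coupled = ifelse(propagated + blocked == 0L, NA,
                     propagated / pmax(propagated + blocked, 1L) >= min_cross_frac)
  )
  # wave origin per (track, droplet): where the track first appears in it
  origins <- list()
  s <- tracks$samples
  for (id in unique(s$track_id)) {
    si <- s[s$track_id == id & !is.na(s$droplet_id), ]
    if (nrow(si) == 0L) next
    for (dr in unique(si$droplet_id)) {
      first <- si[si$droplet_id == dr, ][1L, ]
      row <- d[d$droplet_id == dr, ]
      near_top <- first$position_px <= row$span_start + origin_margin_px
      near_bot <- first$position_px >= row$span_end - origin_margin_px
      origin <- if (near_top) {
        if (row$neighbour_prev %in% d$droplet_id) "interface-top" else "wall"
      } else if (near_bot) {
        if (row$neighbour_next %in% d$droplet_id) "interface-bottom" else "wall"
      } else {
        "interior"
      }
      origins[[length(origins) + 1L]] <- tibble(
        droplet_id = dr, track_id = id, origin = origin,
        time_s = first$time_s)
    }
  }
  origins <- if (length(origins)) dplyr::bind_rows(origins) else {
    tibble(droplet_id = character(), track_id = integer(),
           origin = character(), time_s = numeric())
  }
  # pair up annihilation terminations into events
  ann <- tracks$tracks[tracks$tracks$termination == "annihilation", ]
  annihilations <- if (nrow(ann) == 0L) {
    tibble(time_s = numeric(), position_px = numeric())
  } else {
    ann <- dplyr::arrange(ann, .data$end_s, .data$end_px)
    ann$event <- cumsum(c(1L, diff(round(ann$end_s)) > 15 |
                            abs(diff(ann$end_px)) > 40))
    dplyr::summarise(dplyr::group_by(ann, .data$event),
                     time_s = mean(.data$end_s),
                     position_px = mean(.data$end_px),
                     .groups = "drop")[, c("time_s", "position_px")]
  }
  structure(list(interfaces = interfaces, origins = origins,
                 annihilations = annihilations),
            class = "bz_propagation")
}

#' @export
print.bz_propagation <- function(x, ...) {
  cat(sprintf("<bz_propagation: %d interface(s), %d origin call(s), %d annihilation(s)>\n",
              nrow(x$interfaces), nrow(x$origins), nrow(x$annihilations)))
  print(x$interfaces, ...)
  invisible(x)
}

#' @rdname classify_interfaces
#' @param x A `bz_propagation`.
#' @param ... Unused.
#' @export
tidy.bz_propagation <- function(x, ...) x$interfaces

#' @rdname classify_interfaces
#' @export
glance.bz_propagation <- function(x, ...) {
  tibble(
    n_interfaces = nrow(x$interfaces),
    n_coupled = sum(x$interfaces$coupled %in% TRUE),
    propagated = sum(x$interfaces$propagated),
    blocked = sum(x$interfaces$blocked),
    n_annihilations = nrow(x$annihilations)
  )
}
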