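kymo_long <- function(kymo) {
  v <- kymo_frame_values(kymo)
  times <- attr(kymo, "times")
  y0 <- attr(kymo, "y_start")
  tibble(
    time_s = rep(times, each = nrow(v)),
    position_px = rep(y0 + seq_len(nrow(v)) - 1L, times = ncol(v)),
    intensity = as.numeric(v)
  )
}

#' Plot a kymograph
#'
#' Space-time plot with time on x and slot position on y (flip with
#' `transpose = TRUE` to match figures that draw space horizontally).
#'
#' @param object A `bz_kymograph`.
#' @param transpose Swap the axes.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bz_kymograph <- function(object, transpose = FALSE, ...) {
  df <- kymo_long(object)
  if (transpose) {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position_px,
                                          y = .data$time_s,
                                          fill = .data$intensity))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                          y = .data$position_px,
                                          fill = .data$intensity))
  }
  p + ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "grey10", high = "steelblue1",
                                 name = "blue AU") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = sprintf("Kymograph %s", attr(object, "slot_id")),
                  x = if (transpose) "position (px)" else "time (s)",
                  y = if (transpose) "time (s)" else "position (px)") +
    ggplot2::theme_minimal()
}

#' Plot a trace analysis
#'
#' Baseline-corrected intensity with detected peaks (points), troughs
#' (open points) and the lifecycle periods shaded.
#'
#' @param object A `bz_trace_analysis`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bz_trace_analysis <- function(object, ...) {
  tr <- object$trace
  segs <- as_tibble(object$segments)
  pk <- as_tibble(object$peaks)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_rect(data = segs, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$period), alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$corrected), linewidth = 0.3) +
    ggplot2::geom_point(data = pk[pk$kind == "peak", ],
                        ggplot2::aes(y = .data$value), colour = "red", size = 0.8) +
    ggplot2::geom_point(data = pk[pk$kind == "trough", ],
                        ggplot2::aes(y = .data$value), colour = "blue",
                        shape = 1, size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "corrected intensity (AU)",
                  fill = "period",
                  title = if (is.na(object$droplet_id)) NULL else object$droplet_id) +
    ggplot2::theme_minimal()
}

#' Plot wavefront tracks over the slot
#'
#' @param object A `bz_tracks` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bz_tracks <- function(object, ...) {
  ifc <- layout_interfaces(object$layout)
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$time_s, y = .data$position_px,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::geom_hline(data = ifc, ggplot2::aes(yintercept = .data$boundary_px),
                        linetype = "dotted", colour = "grey40") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "time (s)", y = "position (px)") +
    ggplot2::theme_minimal()
}

#' Plot per-interface propagation counts
#'
#' @param object A `bz_propagation` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bz_propagation <- function(object, ...) {
  df <- tidyr::pivot_longer(object$interfaces,
                            cols = c("propagated", "blocked"),
                            names_to = "outcome", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$interface, y = .data$n,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "interface", y = "wavefronts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a kymograph as a grayscale PNG
#'
#' @param kymo A `bz_kymograph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kymograph_png <- function(kymo, path) {
  png::writePNG(pmin(pmax(unclass(kymo) / 255, 0), 1), path)
  invisible(path)
}
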