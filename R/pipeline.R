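#' Run configuration
#'
#' Collects every input path, acquisition parameter, analysis threshold and
#' the seed of an end-to-end run; every threshold has a documented default
#' and the configuration round-trips losslessly through its JSON file format
#' ([write_run_config()] / [read_run_config()]), so the run manifest
#' suffices to reproduce a run.
#'
#' @param input_dir Directory of recorded frames: either one directory of
#'   PNGs, or one `slot_<id>` subdirectory per slot.
#' @param layout_path Path to the layout JSON.
#' @param out_dir Output directory.
#' @param frame_rate Frames per second (default 0.4).
#' @param t0_offset Seconds from mixing to the first frame (default 0).
#' @param channel Colour channel for intensities (default `"blue"`).
#' @param strip_width Kymograph strip width in px (default 15).
#' @param trace_height Trace region height in px (default 5).
#' @param collapse Collapse kymographs to one column per frame
#'   (default `TRUE`; analytically equivalent for all trace operations).
#' @param seed Integer seed governing all randomness.
#' @param analysis A [trace_config()].
#' @param propagation Named list of wavefront-analysis thresholds (see
#'   [binarize_fronts()], [track_wavefronts()], [classify_interfaces()]).
#' @param generator Named list used by [run_generate()]: `n_slots`,
#'   `n_droplets`, `droplet_px`, `width_px`, `width_mm`, `duration_s`,
#'   `coupling_probability` (`NULL` for uncoupled), `crossing_delay_s`,
#'   `refractory_s`, `noise` (a [noise_config()]), `render` (write frames).
#' @return A list of class `bz_run_config`.
#' @export
run_config <- function(input_dir = NULL, layout_path = NULL,
                       out_dir = "dropwave_out",
                       frame_rate = 0.4, t0_offset = 0, channel = "blue",
                       strip_width = 15L, trace_height = 5L, collapse = TRUE,
                       seed = 1L,
                       analysis = trace_config(),
                       propagation = list(frac = 0.5, min_contrast = 40,
                                          max_dy_px = 18, max_gap_frames = 2L,
                                          min_cross_frac = 0.5,
                                          delay_window_s = 25),
                       generator = list(n_slots = 1L, n_droplets = 3L,
                                        droplet_px = 108L, width_px = 108L,
                                        width_mm = 2.5, duration_s = NULL,
                                        coupling_probability = NULL,
                                        crossing_delay_s = 5,
                                        refractory_s = 10,
                                        noise = noise_config(),
                                        render = TRUE)) {
  structure(list(input_dir = input_dir, layout_path = layout_path,
                 out_dir = out_dir, frame_rate = frame_rate,
                 t0_offset = t0_offset, channel = channel,
                 strip_width = as.integer(strip_width),
                 trace_height = as.integer(trace_height),
                 collapse = collapse, seed = as.integer(seed),
                 analysis = analysis, propagation = propagation,
                 generator = generator),
            class = "bz_run_config")
}

#' @rdname run_config
#' @param config A `bz_run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$analysis$segmentation <- do.call(segment_config, raw$analysis$segmentation)
  raw$analysis <- do.call(trace_config, raw$analysis)
  raw$generator$noise <- do.call(noise_config, raw$generator$noise)
  do.call(run_config, raw)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attr(x, "class") <- NULL
  }
  x
}

write_tbl <- function(df, dir, name) {
  write.csv(as.data.frame(df), file.path(dir, name), row.names = FALSE)
}

ensure_out_dir <- function(path) {
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(path, 2L) != 0L) {
    stop_dropwave(sprintf("output path not writable: %s", path), "dropwave_io_error")
  }
  invisible(path)
}

with_stage <- function(stage, slot_id, droplet_id, expr) {
  tryCatch(expr, error = function(e) {
    stop_dropwave(sprintf("[stage %s | slot %s | droplet %s] %s",
                          stage, slot_id, droplet_id %||% "-",
                          conditionMessage(e)),
                  "dropwave_processing_error")
  })
}

manifest_list <- function(config) {
  list(package = "dropwave",
       version = as.character(utils::packageVersion("dropwave")),
       seed = config$seed,
       config = unclass_deep(config))
}

#' Run the full analysis pipeline
#'
#' frames -> kymographs -> traces -> peak/lifecycle features -> propagation
#' report. For every slot in the layout a kymograph PNG is written; per
#' droplet, a feature record; per slot, the propagation tables. All CSV
#' outputs and the JSON run manifest are deterministic for a given
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @param stacks Optional named list of [frame_stack()]s keyed by `slot_id`
#'   (bypasses `input_dir`; a single unnamed stack is used for all slots).
#' @param layout Optional [bz_layout()] (bypasses `layout_path`).
#' @return Invisibly, a list with `$features`, `$segments`, `$peaks`,
#'   `$traces`, `$interfaces`, `$origins`, `$annihilations` tibbles and the
#'   per-droplet `$analyses`.
#' @export
run_pipeline <- function(config, stacks = NULL, layout = NULL) {
  stopifnot(inherits(config, "bz_run_config"))
  if (is.null(layout)) {
    if (is.null(config$layout_path)) {
      stop_dropwave("no layout given (layout_path is NULL)", "dropwave_config_error")
    }
    layout <- read_layout(config$layout_path)
  }
  out <- ensure_out_dir(config$out_dir)
  kdir <- ensure_out_dir(file.path(out, "kymographs"))
  slot_stack <- function(sid) {
    if (!is.null(stacks)) {
      if (inherits(stacks, "bz_frames")) return(stacks)
      if (!is.null(stacks[[sid]])) return(stacks[[sid]])
      stop_dropwave(sprintf("no frame stack for slot '%s'", sid),
                    "dropwave_config_error")
    }
    sub <- file.path(config$input_dir, paste0("slot_", sid))
    dir <- if (dir.exists(sub)) sub else config$input_dir
    read_frames(dir, frame_rate = config$frame_rate,
                t0_offset = config$t0_offset)
  }
  analyses <- list()
  traces_all <- list()
  interfaces <- list(); origins <- list(); annihil <- list(); crossings <- list()
  pp <- config$propagation
  for (sid in layout$slots$slot_id) {
    stack <- with_stage("read_frames", sid, NULL, slot_stack(sid))
    kymo <- with_stage("build_kymograph", sid, NULL,
                       build_kymograph(stack, layout, slot_id = sid,
                                       strip_width = config$strip_width,
                                       channel = config$channel,
                                       collapse = config$collapse))
    write_kymograph_png(kymo, file.path(kdir, paste0("slot_", sid, ".png")))
    drops <- layout$droplets[layout$droplets$slot_id == sid, ]
    for (i in seq_len(nrow(drops))) {
      did <- drops$droplet_id[i]
      tr <- with_stage("extract_trace", sid, did,
                       extract_trace(kymo, drops[i, ],
                                     height = config$trace_height))
      traces_all[[length(traces_all) + 1L]] <- tr
      analyses[[did]] <- with_stage("analyze_trace", sid, did,
                                    analyze_trace(tr, config = config$analysis))
    }
    mask <- with_stage("binarize_fronts", sid, NULL,
                       binarize_fronts(kymo, frac = pp$frac,
                                       min_contrast = pp$min_contrast))
    tracks <- with_stage("track_wavefronts", sid, NULL,
                         track_wavefronts(mask, layout,
                                          max_dy_px = pp$max_dy_px,
                                          max_gap_frames = pp$max_gap_frames))
    report <- with_stage("classify_interfaces", sid, NULL,
                         classify_interfaces(tracks,
                                             min_cross_frac = pp$min_cross_frac,
                                             delay_window_s = pp$delay_window_s))
    interfaces[[sid]] <- report$interfaces
    origins[[sid]] <- report$origins
    annihil[[sid]] <- dplyr::mutate(report$annihilations, slot_id = sid)
    crossings[[sid]] <- dplyr::mutate(tracks$crossings, slot_id = sid)
  }
  bind_or_empty <- function(lst) if (length(lst)) dplyr::bind_rows(lst) else tibble()
  features <- purrr::map_dfr(analyses, glance)
  segments <- purrr::map_dfr(analyses, function(a) {
    dplyr::bind_cols(tibble(droplet_id = a$droplet_id), as_tibble(a$segments))
  })
  peaks <- purrr::map_dfr(analyses, tidy)
  res <- list(features = features, segments = segments, peaks = peaks,
              traces = bind_or_empty(traces_all),
              interfaces = bind_or_empty(interfaces),
              origins = bind_or_empty(origins),
              annihilations = bind_or_empty(annihil),
              crossings = bind_or_empty(crossings),
              analyses = analyses)
  write_tbl(res$features, out, "features.csv")
  write_tbl(res$segments, out, "segments.csv")
  write_tbl(res$peaks, out, "peaks.csv")
  write_tbl(res$traces, out, "traces.csv")
  write_tbl(res$interfaces, out, "interfaces.csv")
  write_tbl(res$origins, out, "origins.csv")
  write_tbl(res$annihilations, out, "annihilations.csv")
  write_tbl(res$crossings, out, "crossings.csv")
  jsonlite::write_json(manifest_list(config), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(res)
}

#' Generate a synthetic dataset on disk
#'
#' Builds the layout, schedules and (optionally coupled) simulations for
#' `generator$n_slots` slots of `generator$n_droplets` droplets each,
#' renders the frames, and writes everything a later [run_pipeline()] needs:
#' `frames/slot_<id>/` PNG directories, `layout.json`, `traces.csv`, the
#' ground-truth tables (`truth_waves.csv`, `truth_boundaries.csv`,
#' `truth_crossings.csv`) and a JSON manifest. Fully deterministic for a
#' given configuration and seed.
#'
#' @param config A [run_config()]; the `generator` entry drives everything.
#' @return Invisibly, a list with the combined `$layout` and the per-slot
#'   `$sims`.
#' @export
run_generate <- function(config) {
  stopifnot(inherits(config, "bz_run_config"))
  g <- config$generator
  out <- ensure_out_dir(config$out_dir)
  slots <- list(); droplets <- list(); sims <- list()
  traces <- list(); waves <- list(); bounds <- list(); crosses <- list()
  for (s in seq_len(g$n_slots)) {
    sid <- paste0("slot", s)
    lay <- linear_layout(g$n_droplets, droplet_px = g$droplet_px,
                         width_px = g$width_px, width_mm = g$width_mm,
                         slot_id = sid, id_prefix = sprintf("s%dd", s))
    sched <- g$schedule %||%
      lifecycle_schedule(g$n_droplets, droplet_id = lay$droplets$droplet_id)
    coupling <- NULL
    use_layout <- NULL
    if (!is.null(g$coupling_probability)) {
      coupling <- coupling_spec(lay, g$coupling_probability,
                                g$crossing_delay_s, g$refractory_s)
      use_layout <- lay
    }
    sim <- simulate_traces(sched, layout = use_layout, coupling = coupling,
                           noise = g$noise, seed = config$seed + 101L * s,
                           frame_rate = config$frame_rate,
                           duration_s = g$duration_s)
    sims[[sid]] <- sim
    if (isTRUE(g$render)) {
      stack <- render_frames(sim, lay, noise = g$noise,
                             seed = config$seed + 101L * s + 1L)
      write_frames(stack, file.path(out, "frames", paste0("slot_", sid)))
    }
    slots[[s]] <- lay$slots
    droplets[[s]] <- lay$droplets
    traces[[s]] <- sim$traces
    add_sid <- function(df) dplyr::mutate(df, slot_id = sid)
    waves[[s]] <- add_sid(sim$truth$waves)
    bounds[[s]] <- add_sid(sim$truth$boundaries)
    crosses[[s]] <- add_sid(sim$truth$crossings)
  }
  layout <- bz_layout(dplyr::bind_rows(slots), dplyr::bind_rows(droplets))
  write_layout(layout, file.path(out, "layout.json"))
  write_tbl(dplyr::bind_rows(traces), out, "traces.csv")
  write_tbl(dplyr::bind_rows(waves), out, "truth_waves.csv")
  write_tbl(dplyr::bind_rows(bounds), out, "truth_boundaries.csv")
  write_tbl(dplyr::bind_rows(crosses), out, "truth_crossings.csv")
  jsonlite::write_json(manifest_list(config), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(layout = layout, sims = sims))
}
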