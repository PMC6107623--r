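#' Noise model for the synthetic generator
#'
#' Emulates the photometric imperfections of the recordings: additive
#' Gaussian pixel noise, a slow sinusoidal illumination/baseline drift, and
#' optionally static bright spots standing in for CO2 bubbles.
#'
#' @param sd_frac Gaussian noise standard deviation as a fraction of the
#'   main-period pulse amplitude (default 0.02).
#' @param drift_frac Peak drift amplitude as a fraction of the main-period
#'   pulse amplitude (default 0.05).
#' @param drift_period_s Drift period in seconds (default 1800).
#' @param bubbles Number of static bright-spot artifacts rendered per slot
#'   (default 0).
#' @param bubble_level Added intensity of a bubble spot, on the 0-1 frame
#'   scale (default 0.3).
#' @return A list of class `bz_noise_config`.
#' @export
noise_config <- function(sd_frac = 0.02, drift_frac = 0.05,
                         drift_period_s = 1800, bubbles = 0L,
                         bubble_level = 0.3) {
  structure(list(sd_frac = sd_frac, drift_frac = drift_frac,
                 drift_period_s = drift_period_s,
                 bubbles = as.integer(bubbles), bubble_level = bubble_level),
            class = "bz_noise_config")
}

#' Lifecycle schedules for synthetic droplets
#'
#' One row per droplet, prescribing the oscillation lifecycle: an induction
#' delay, then initial, main and late periods each with a duration, a
#' frequency (the main period may ramp linearly from `main_freq_start` to
#' `main_freq_end`) and a pulse amplitude, then the exhausted state in either
#' the reduced or oxidised final state. Defaults follow the reference
#' acquisition: a 1 h main period at 0.04 waves/s preceded by 3 min of
#' faster (0.1 s^-1) low-amplitude initial oscillations and followed by
#' 10 min of 0.08 s^-1 late oscillations; about 20% of droplets start with
#' spiral waves (slightly lower initial contrast).
#'
#' @param n_droplets Number of droplets (rows).
#' @param droplet_id Labels; default `d1..dn`.
#' @param induction_s Quiescent delay after mixing, seconds.
#' @param initial_duration_s,initial_freq,initial_amp Initial period:
#'   duration (s), wave frequency (s^-1), pulse amplitude (8-bit AU).
#' @param main_duration_s,main_freq_start,main_freq_end,main_amp Main
#'   period; frequency ramps linearly between the two values.
#' @param late_duration_s,late_freq,late_amp Late period.
#' @param final_state `"reduced"` (red, default) or `"oxidised"` (blue).
#' @param spiral_start_probability Probability a droplet starts with spiral
#'   rather than planar waves (default 0.2).
#' @return A tibble of class `bz_schedule`.
#' @export
lifecycle_schedule <- function(n_droplets = 1L,
                               droplet_id = paste0("d", seq_len(n_droplets),
                                                   recycle0 = TRUE),
                               induction_s = 0,
                               initial_duration_s = 180, initial_freq = 0.1,
                               initial_amp = 30,
                               main_duration_s = 3600, main_freq_start = 0.04,
                               main_freq_end = 0.04, main_amp = 60,
                               late_duration_s = 600, late_freq = 0.08,
                               late_amp = 36,
                               final_state = "reduced",
                               spiral_start_probability = 0.2) {
  out <- tibble(
    droplet_id = droplet_id,
    induction_s = induction_s,
    initial_duration_s = initial_duration_s, initial_freq = initial_freq,
    initial_amp = initial_amp,
    main_duration_s = main_duration_s, main_freq_start = main_freq_start,
    main_freq_end = main_freq_end, main_amp = main_amp,
    late_duration_s = late_duration_s, late_freq = late_freq,
    late_amp = late_amp,
    final_state = final_state,
    spiral_start_probability = spiral_start_probability
  )
  validate_schedule(out)
  structure(out, class = c("bz_schedule", class(out)))
}

validate_schedule <- function(s) {
  s <- as_tibble(s)
  durs <- s[c("induction_s", "initial_duration_s", "main_duration_s",
              "late_duration_s")]
  if (any(as.matrix(durs) < 0)) {
    stop_dropwave("schedule durations must be >= 0", "dropwave_validation_error")
  }
  chk <- function(dur, f, what) {
    bad <- s[[dur]] > 0 & s[[f]] <= 0
    if (any(bad)) {
      stop_dropwave(sprintf("%s frequency must be > 0 where its duration is > 0", what),
                    "dropwave_validation_error")
    }
  }
  chk("initial_duration_s", "initial_freq", "initial")
  chk("main_duration_s", "main_freq_start", "main")
  chk("main_duration_s", "main_freq_end", "main")
  chk("late_duration_s", "late_freq", "late")
  both <- s$initial_duration_s > 0 & s$main_duration_s > 0
  if (any(both & s$initial_freq <= s$main_freq_start)) {
    stop_dropwave("initial frequency must exceed the main-period start frequency",
                  "dropwave_validation_error")
  }
  both <- s$late_duration_s > 0 & s$main_duration_s > 0
  if (any(both & s$late_freq <= s$main_freq_end)) {
    stop_dropwave("late frequency must exceed the main-period end frequency",
                  "dropwave_validation_error")
  }
  if (!all(s$final_state %in% c("reduced", "oxidised"))) {
    stop_dropwave("final_state must be 'reduced' or 'oxidised'",
                  "dropwave_validation_error")
  }
  invisible(s)
}

#' Interdroplet coupling specification
#'
#' Per-interface phenomenological coupling: the probability that a wavefront
#' arriving at the interface crosses into the neighbouring droplet, the
#' crossing delay, and the refractory time during which the receiving
#' droplet cannot accept another wave.
#'
#' @param layout A [bz_layout()]; one row is produced per droplet-droplet
#'   interface.
#' @param propagation_probability Crossing probability in `[0, 1]`.
#' @param crossing_delay_s Delay at the interface, seconds.
#' @param refractory_s Receiving-droplet refractory time, seconds.
#' @return A tibble of class `bz_coupling` keyed by `interface`.
#' @export
coupling_spec <- function(layout, propagation_probability = 1,
                          crossing_delay_s = 5, refractory_s = 10) {
  ifc <- layout_interfaces(layout)
  if (any(propagation_probability < 0 | propagation_probability > 1)) {
    stop_dropwave("propagation_probability must lie in [0, 1]",
                  "dropwave_validation_error")
  }
  if (any(crossing_delay_s < 0) || any(refractory_s < 0)) {
    stop_dropwave("crossing_delay_s and refractory_s must be >= 0",
                  "dropwave_validation_error")
  }
  out <- tibble(
    interface = ifc$interface,
    droplet_a = ifc$droplet_a, droplet_b = ifc$droplet_b,
    boundary_px = ifc$boundary_px,
    propagation_probability = propagation_probability,
    crossing_delay_s = crossing_delay_s,
    refractory_s = refractory_s
  )
  structure(out, class = c("bz_coupling", class(out)))
}

# run expr with a temporary RNG state seeded from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# autonomous wave (oxidation pulse) times of one schedule row, with the
# stage each wave belongs to and the local period at emission
schedule_wave_times <- function(row) {
  t_init <- row$induction_s
  t_main <- t_init + row$initial_duration_s
  t_late <- t_main + row$main_duration_s
  t_end <- t_late + row$late_duration_s
  waves <- list()
  emit_const <- function(t0, t1, f, stage) {
    if (t1 <= t0 || f <= 0) return(NULL)
    tt <- seq(t0 + 0.5 / f, t1, by = 1 / f)
    tt <- tt[tt < t1]
    if (length(tt) == 0L) return(NULL)
    tibble(time_s = tt, stage = stage, period_s = 1 / f)
  }
  waves[["initial"]] <- emit_const(t_init, t_main, row$initial_freq, "initial")
  if (row$main_duration_s > 0) {
    f0 <- row$main_freq_start
    f1 <- row$main_freq_end
    fr <- function(t) f0 + (f1 - f0) * (t - t_main) / row$main_duration_s
    t <- t_main + 0.5 / f0
    tt <- numeric(0)
    pp <- numeric(0)
    while (t < t_late) {
      tt <- c(tt, t)
      pp <- c(pp, 1 / fr(t))
      t <- t + 1 / fr(t)
    }
    if (length(tt) > 0L) {
      waves[["main"]] <- tibble(time_s = tt, stage = "main", period_s = pp)
    }
  }
  waves[["late"]] <- emit_const(t_late, t_end, row$late_freq, "late")
  out <- dplyr::bind_rows(waves)
  list(waves = out, boundaries = tibble(
    period = c("induction", "initial", "main", "late"),
    start_s = c(0, t_init, t_main, t_late),
    end_s = c(t_init, t_main, t_late, t_end)
  ))
}

# half-cosine asymmetric oxidation pulse (fast rise, slower decay), added to
# `acc` by pointwise maximum so overlapping pulses saturate
add_pulse <- function(acc, tgrid, tp, amp, period, rise_frac, decay_frac) {
  r <- max(rise_frac * period, 1e-6)
  d <- max(decay_frac * period, 1e-6)
  sel <- which(tgrid > tp - r & tgrid < tp + d)
  if (length(sel) == 0L) return(acc)
  tt <- tgrid[sel]
  v <- ifelse(tt < tp,
              0.5 * amp * (1 + cos(pi * (tp - tt) / r)),
              0.5 * amp * (1 + cos(pi * (tt - tp) / d)))
  acc[sel] <- pmax(acc[sel], v)
  acc
}

#' Simulate droplet intensity traces with ground truth
#'
#' Generates per-droplet blue-channel intensity traces following the
#' lifecycle schedules: a drifting baseline plus one asymmetric oxidation
#' pulse (fast rise, slower decay; widths proportional to the local period)
#' per scheduled wave, plus Gaussian noise. When a layout and a coupling
#' specification are given, waves are simulated spatially: each scheduled
#' wave spawns wavefronts at the droplet centre travelling both ways at
#' constant speed; a front reaching a droplet-droplet interface crosses with
#' the interface's propagation probability after its crossing delay (unless
#' the receiving droplet is refractory) and otherwise terminates there;
#' opposing fronts meeting inside a droplet annihilate. Relayed waves add
#' pulses to the receiving droplets' traces when the front passes their
#' centre. Everything is deterministic for a given seed.
#'
#' @param schedule A [lifecycle_schedule()] tibble.
#' @param layout Optional [bz_layout()]; required for coupling.
#' @param coupling Optional [coupling_spec()].
#' @param noise A [noise_config()]; set `sd_frac`, `drift_frac` to 0 for
#'   noise-free traces.
#' @param seed Integer seed; all randomness derives from it.
#' @param frame_rate Samples per second (default 0.4).
#' @param t0_offset Seconds between mixing and the first sample (default 0).
#' @param duration_s Record length in seconds; defaults to the longest
#'   schedule end plus 300 s of exhausted state.
#' @param base_level Resting (reduced-state) intensity, 8-bit AU
#'   (default 70).
#' @param front_speed_px_s Wavefront speed for the spatial simulation,
#'   px/s (default 2.5, about 3.5 mm/min at the 2.5 mm / 108 px
#'   calibration).
#' @param relay_amp,relay_period_s Pulse amplitude (AU) and shape period (s)
#'   for waves relayed into a droplet from a neighbour (defaults 60 and 25).
#' @param rise_frac,decay_frac Pulse rise/decay widths as fractions of the
#'   local period (defaults 0.15 and 0.55).
#' @param appearance_s Time the droplets are pipetted into the slot; before
#'   it the trace sits at `oil_level` (clear oil registers bright).
#'   Default 0.
#' @param oil_level Intensity before `appearance_s`, AU (default 180).
#' @return A `bz_simulation`: list with `$traces` (long tibble `droplet_id`,
#'   `frame`, `time_s`, `intensity`), `$truth` (lists of tibbles: `waves`,
#'   `boundaries`, `crossings`, `annihilations`, `fronts`, `spiral_start`)
#'   and `$config`.
#' @export
simulate_traces <- function(schedule, layout = NULL, coupling = NULL,
                            noise = noise_config(), seed = 1L,
                            frame_rate = 0.4, t0_offset = 0,
                            duration_s = NULL, base_level = 70,
                            front_speed_px_s = 2.5, relay_amp = 60,
                            relay_period_s = 25, rise_frac = 0.15,
                            decay_frac = 0.55, appearance_s = 0,
                            oil_level = 180) {
  schedule <- validate_schedule(schedule)
  n <- nrow(schedule)
  empty_truth <- list(
    waves = tibble(droplet_id = character(), time_s = numeric(),
                   stage = character(), period_s = numeric()),
    boundaries = tibble(droplet_id = character(), period = character(),
                        start_s = numeric(), end_s = numeric()),
    crossings = tibble(interface = character(), time_s = numeric(),
                       crossed = logical()),
    annihilations = tibble(time_s = numeric(), position_px = numeric()),
    fronts = tibble(front_id = integer(), time_s = numeric(),
                    position_px = numeric(), droplet_id = character(),
                    direction = integer()),
    spiral_start = tibble(droplet_id = character(), spiral = logical())
  )
  cfg <- list(seed = seed, frame_rate = frame_rate, t0_offset = t0_offset,
              base_level = base_level, front_speed_px_s = front_speed_px_s,
              relay_amp = relay_amp, relay_period_s = relay_period_s,
              rise_frac = rise_frac, decay_frac = decay_frac,
              appearance_s = appearance_s, oil_level = oil_level,
              noise = noise)
  if (n == 0L) {
    return(structure(list(
      traces = tibble(droplet_id = character(), frame = integer(),
                      time_s = numeric(), intensity = numeric()),
      truth = empty_truth, schedule = schedule, layout = layout,
      coupling = coupling, config = cfg), class = "bz_simulation"))
  }
  sched_ends <- schedule$induction_s + schedule$initial_duration_s +
    schedule$main_duration_s + schedule$late_duration_s
  if (is.null(duration_s)) duration_s <- max(sched_ends) + 300
  cfg$duration_s <- duration_s
  dt <- 1 / frame_rate
  tgrid <- seq(t0_offset, duration_s, by = dt)
  n_frames <- length(tgrid)

  with_local_seed(seed, {
    spiral <- runif(n) < schedule$spiral_start_probability
    # autonomous emissions and lifecycle boundaries
    auto <- lapply(seq_len(n), function(i) schedule_wave_times(schedule[i, ]))
    boundaries <- purrr::map_dfr(seq_len(n), function(i) {
      b <- auto[[i]]$boundaries
      b <- b[b$end_s > b$start_s, ]
      b <- dplyr::bind_rows(b, tibble(period = "exhausted",
                                      start_s = sched_ends[i],
                                      end_s = duration_s))
      dplyr::bind_cols(tibble(droplet_id = schedule$droplet_id[i]), b)
    })
    spatial <- !is.null(layout) && !is.null(coupling) && nrow(coupling) >= 0
    if (!is.null(layout) && is.null(coupling)) spatial <- FALSE
    if (spatial) {
      sim <- simulate_fronts(schedule, auto, layout, coupling, duration_s,
                             dt, front_speed_px_s)
      waves <- sim$waves
      crossings <- sim$crossings
      annihilations <- sim$annihilations
      fronts <- sim$fronts
    } else {
      waves <- purrr::map_dfr(seq_len(n), function(i) {
        w <- auto[[i]]$waves
        if (is.null(w) || nrow(w) == 0L) return(NULL)
        dplyr::bind_cols(tibble(droplet_id = schedule$droplet_id[i]), w)
      })
      if (nrow(waves) == 0L) waves <- empty_truth$waves
      crossings <- empty_truth$crossings
      annihilations <- empty_truth$annihilations
      fronts <- empty_truth$fronts
    }
    # synthesise the traces on the sample grid
    traces <- purrr::map_dfr(seq_len(n), function(i) {
      id <- schedule$droplet_id[i]
      row <- schedule[i, ]
      ref_amp <- max(row$initial_amp, row$main_amp, row$late_amp, relay_amp)
      w <- waves[waves$droplet_id == id, ]
      acc <- numeric(n_frames)
      amp_of <- c(initial = row$initial_amp, main = row$main_amp,
                  late = row$late_amp, relay = relay_amp)
      if (nrow(w) > 0L) {
        for (k in seq_len(nrow(w))) {
          a <- amp_of[[w$stage[k]]]
          if (w$stage[k] == "initial" && spiral[i]) a <- 0.8 * a
          acc <- add_pulse(acc, tgrid, w$time_s[k], a,
                           w$period_s[k], rise_frac, decay_frac)
        }
      }
      drift_phase <- runif(1, 0, 2 * pi)
      drift <- if (noise$drift_frac > 0) {
        noise$drift_frac * row$main_amp *
          sin(2 * pi * tgrid / noise$drift_period_s + drift_phase)
      } else 0
      y <- base_level + drift + acc
      if (row$final_state == "oxidised") {
        y[tgrid >= sched_ends[i]] <- pmax(y[tgrid >= sched_ends[i]],
                                          base_level + 0.5 * row$main_amp)
      }
      if (appearance_s > t0_offset) y[tgrid < appearance_s] <- oil_level
      if (noise$sd_frac > 0) y <- y + rnorm(n_frames, 0, noise$sd_frac * ref_amp)
      tibble(droplet_id = id, frame = seq_len(n_frames) - 1L,
             time_s = tgrid, intensity = y)
    })
    structure(list(
      traces = traces,
      truth = list(waves = waves, boundaries = boundaries,
                   crossings = crossings, annihilations = annihilations,
                   fronts = fronts,
                   spiral_start = tibble(droplet_id = schedule$droplet_id,
                                         spiral = spiral)),
      schedule = schedule, layout = layout, coupling = coupling,
      config = cfg), class = "bz_simulation")
  })
}

# discrete-time spatial wavefront simulation; dt is the frame interval.
# Fronts spawn in pairs at the droplet centre, travel at constant speed,
# cross interfaces per coupling draws, and annihilate on collision.
simulate_fronts <- function(schedule, auto, layout, coupling, duration_s,
                            dt, speed) {
  d <- layout$droplets
  ids <- d$droplet_id
  centre <- setNames(d$centre_y, ids)
  span_lo <- setNames(d$span_start, ids)
  span_hi <- setNames(d$span_end, ids)
  nb_next <- setNames(d$neighbour_next, ids)
  nb_prev <- setNames(d$neighbour_prev, ids)
  cpl_key <- function(a, b) {
    k1 <- paste(a, b, sep = "|")
    k2 <- paste(b, a, sep = "|")
    if (k1 %in% coupling$interface) k1 else k2
  }
  # spawn queue: all autonomous emissions
  spawns <- purrr::map_dfr(seq_len(nrow(schedule)), function(i) {
    w <- auto[[i]]$waves
    if (is.null(w) || nrow(w) == 0L) return(NULL)
    dplyr::bind_cols(tibble(droplet_id = schedule$droplet_id[i]), w)
  })
  if (nrow(spawns) > 0L) spawns <- spawns[order(spawns$time_s), ]
  fronts <- list()   # active fronts: id, droplet, pos, dir, hold_until, period
  next_id <- 1L
  waves <- list()
  crossings <- list()
  annihilations <- list()
  paths <- list()
  # refractory bookkeeping per interface: a crossing blocks further
  # crossings of the same interface for refractory_s
  last_entry <- setNames(rep(-Inf, nrow(coupling)), coupling$interface)
  record_wave <- function(id, t, stage, period) {
    waves[[length(waves) + 1L]] <<- tibble(
      droplet_id = id, time_s = t, stage = stage, period_s = period)
  }
  steps <- seq(0, duration_s, by = dt)
  spawn_ptr <- 1L
  for (t in steps) {
    # spawn autonomous fronts due by now
    while (spawn_ptr <= nrow(spawns) && spawns$time_s[spawn_ptr] <= t) {
      sp <- spawns[spawn_ptr, ]
      spawn_ptr <- spawn_ptr + 1L
      record_wave(sp$droplet_id, sp$time_s, sp$stage, sp$period_s)
      for (dir in c(-1L, 1L)) {
        fronts[[length(fronts) + 1L]] <- list(
          id = next_id, droplet = sp$droplet_id,
          pos = centre[[sp$droplet_id]], dir = dir,
          hold_until = sp$time_s, period = sp$period_s, alive = TRUE)
        paths[[length(paths) + 1L]] <- tibble(
          front_id = next_id, time_s = t,
          position_px = centre[[sp$droplet_id]],
          droplet_id = sp$droplet_id, direction = dir)
        next_id <- next_id + 1L
      }
    }
    if (length(fronts) == 0L) next
    # remember pre-step positions (collision test needs the ordering before
    # the step: only fronts that were approaching can annihilate)
    prev_pos_all <- vapply(fronts, function(f) f$pos, numeric(1))
    # advance fronts
    for (k in seq_along(fronts)) {
      fr <- fronts[[k]]
      if (!fr$alive || t < fr$hold_until) next
      step_px <- speed * dt
      new_pos <- fr$pos + fr$dir * step_px
      prev_pos <- fr$pos
      id <- fr$droplet
      # centre crossing -> a wave passes the trace region of this droplet
      cy <- centre[[id]]
      if ((prev_pos < cy && new_pos >= cy) || (prev_pos > cy && new_pos <= cy)) {
        if (abs(prev_pos - cy) > 1e-9) {  # spawned-at-centre already recorded
          record_wave(id, t, "relay", fr$period)
        }
      }
      # interface / wall handling
      lim <- if (fr$dir > 0L) span_hi[[id]] else span_lo[[id]]
      if ((fr$dir > 0L && new_pos >= lim) || (fr$dir < 0L && new_pos <= lim)) {
        nb <- if (fr$dir > 0L) nb_next[[id]] else nb_prev[[id]]
        if (!nb %in% ids) {
          fr$alive <- FALSE
          fr$termination <- "boundary"
          fr$pos <- lim
        } else {
          key <- cpl_key(id, nb)
          cp <- coupling[coupling$interface == key, ]
          ok <- runif(1) < cp$propagation_probability &&
            (t - last_entry[[key]]) >= cp$refractory_s
          crossings[[length(crossings) + 1L]] <- tibble(
            interface = key, time_s = t, crossed = isTRUE(ok))
          if (isTRUE(ok)) {
            fr$droplet <- nb
            fr$pos <- lim
            fr$hold_until <- t + cp$crossing_delay_s
            last_entry[[key]] <- t + cp$crossing_delay_s
          } else {
            fr$alive <- FALSE
            fr$termination <- "dissipation"
            fr$pos <- lim
          }
        }
      } else {
        fr$pos <- new_pos
      }
      fronts[[k]] <- fr
      if (fr$alive) {
        paths[[length(paths) + 1L]] <- tibble(
          front_id = fr$id, time_s = t, position_px = fr$pos,
          droplet_id = fr$droplet, direction = fr$dir)
      }
    }
    # collisions: opposing fronts in the same droplet that were approaching
    # before the step and whose order flipped (or met) after it
    alive_idx <- which(vapply(fronts, function(f) f$alive, logical(1)))
    if (length(alive_idx) > 1L) {
      for (a in alive_idx) {
        for (b in alive_idx) {
          if (a >= b) next
          fa <- fronts[[a]]; fb <- fronts[[b]]
          if (!fa$alive || !fb$alive) next
          if (fa$droplet != fb$droplet) next
          if (fa$dir == fb$dir) next
          up_i <- if (fa$dir > 0L) a else b  # moving toward larger y
          dn_i <- if (fa$dir > 0L) b else a  # moving toward smaller y
          approaching <- prev_pos_all[up_i] < prev_pos_all[dn_i]
          met <- fronts[[up_i]]$pos >= fronts[[dn_i]]$pos - 1e-9
          if (approaching && met) {
            mid <- (fronts[[up_i]]$pos + fronts[[dn_i]]$pos) / 2
            annihilations[[length(annihilations) + 1L]] <- tibble(
              time_s = t, position_px = mid)
            fronts[[a]]$alive <- FALSE
            fronts[[b]]$alive <- FALSE
          }
        }
      }
    }
    # prune dead fronts (keep list small)
    fronts <- fronts[vapply(fronts, function(f) f$alive, logical(1))]
  }
  bind_or <- function(lst, proto) if (length(lst)) dplyr::bind_rows(lst) else proto
  list(
    waves = bind_or(waves, tibble(droplet_id = character(), time_s = numeric(),
                                  stage = character(), period_s = numeric())),
    crossings = bind_or(crossings, tibble(interface = character(),
                                          time_s = numeric(), crossed = logical())),
    annihilations = bind_or(annihilations, tibble(time_s = numeric(),
                                                  position_px = numeric())),
    fronts = bind_or(paths, tibble(front_id = integer(), time_s = numeric(),
                                   position_px = numeric(),
                                   droplet_id = character(),
                                   direction = integer()))
  )
}

#' @export
print.bz_simulation <- function(x, ...) {
  cat(sprintf("<bz_simulation: %d droplet(s), %d samples/trace, %d scheduled wave(s)>\n",
              nrow(x$schedule),
              if (nrow(x$traces)) sum(x$traces$droplet_id == x$traces$droplet_id[1L]) else 0L,
              nrow(x$truth$waves)))
  invisible(x)
}

#' Packaged single-droplet lifecycle fixture
#'
#' A deterministic synthetic trace reproducing the canonical single-droplet
#' recording used to illustrate the lifecycle: the recording starts at
#' mixing with the empty slot registering bright clear oil; the droplet is
#' pipetted in at 4.5 min; fast low-amplitude initial oscillations run until
#' the main period starts at 7.5 min and lasts until 60 min; a late period
#' of about 10 min follows, after which the droplet is exhausted. Scheduled
#' boundaries are carried in `$truth$boundaries` for segmentation tests.
#'
#' @param noise If `TRUE`, add the default photometric noise; the default
#'   `FALSE` gives a bit-identical trace on every call.
#' @param seed Seed used when `noise = TRUE`.
#' @return A `bz_simulation` with a single trace (`droplet_id` `"fix1"`).
#' @export
demo_lifecycle_trace <- function(noise = FALSE, seed = 42L) {
  sched <- lifecycle_schedule(
    1L, droplet_id = "fix1",
    induction_s = 270,                       # droplet appears at 4.5 min
    initial_duration_s = 180, initial_freq = 0.1, initial_amp = 30,
    main_duration_s = 3150, main_freq_start = 0.04, main_freq_end = 0.036,
    main_amp = 60,                           # main period: 7.5 to 60 min
    late_duration_s = 600, late_freq = 0.08, late_amp = 36,
    spiral_start_probability = 0
  )
  nz <- if (noise) noise_config() else noise_config(sd_frac = 0, drift_frac = 0)
  simulate_traces(sched, noise = nz, seed = seed, duration_s = 4500,
                  appearance_s = 270, oil_level = 180)
}
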