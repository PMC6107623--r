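test_that("a resting droplet renders with a flat blue channel over its ROI", {
  sched <- lifecycle_schedule(1, induction_s = 0, initial_duration_s = 0,
                              main_duration_s = 0, late_duration_s = 0)
  lay <- linear_layout(1)
  sim <- simulate_traces(sched, noise = no_noise(), seed = 1, duration_s = 50)
  stack <- render_frames(sim, lay, noise = no_noise())
  kymo <- build_kymograph(stack, lay)
  tr <- extract_trace(kymo, lay$droplets[1, ])
  expect_equal(length(unique(round(tr$intensity, 6))), 1L)
  expect_false(any(binarize_fronts(kymo)))
})

test_that("rendered frames and the direct kymograph agree exactly without noise", {
  arr <- relay_array(2, 1, 30)
  cpl <- coupling_spec(arr$layout, 1, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 2, duration_s = 200)
  stack <- render_frames(sim, arr$layout, noise = no_noise())
  k_frames <- build_kymograph(stack, arr$layout, collapse = TRUE)
  k_direct <- render_kymograph(sim, arr$layout, noise = no_noise())
  expect_equal(unclass(k_frames), unclass(k_direct), tolerance = 1e-12,
               ignore_attr = TRUE)
  # and one rendered crossing front is recovered end to end
  tracks <- track_wavefronts(binarize_fronts(k_frames), arr$layout)
  expect_equal(nrow(tracks$crossings), 1L)
})

test_that("the default calibration gives the standard 15 x 5 px trace region", {
  sched <- lifecycle_schedule(1, initial_duration_s = 0, late_duration_s = 0,
                              main_duration_s = 150)
  lay <- linear_layout(1)  # 108 px droplet in a 2.5 mm slot
  sim <- simulate_traces(sched, noise = no_noise(), seed = 1, duration_s = 200)
  stack <- render_frames(sim, lay, noise = no_noise())
  kymo <- build_kymograph(stack, lay)   # 15 px strip
  expect_equal(attr(kymo, "strip_width"), 15L)
  tr <- extract_trace(kymo, lay$droplets[1, ], height = 5L)  # 5 px high
  a <- analyze_trace(tr)
  # the whole-droplet flashes reproduce the scheduled pulses
  expect_equal(a$features$wave_count, nrow(sim$truth$waves))
})

test_that("non-spatial renders flash whole droplets consistently with the trace", {
  sched <- lifecycle_schedule(1, initial_duration_s = 0, late_duration_s = 0,
                              main_duration_s = 300)
  lay <- linear_layout(1)
  sim <- simulate_traces(sched, noise = no_noise(), seed = 1, duration_s = 350)
  kymo <- render_kymograph(sim, lay, noise = no_noise())
  tr <- extract_trace(kymo, lay$droplets[1, ])
  sim_tr <- sim$traces
  # rendered blue trace = rest level + pulse (both in 8-bit AU)
  rendered_pulse <- tr$intensity - min(tr$intensity)
  sim_pulse <- sim_tr$intensity - min(sim_tr$intensity)
  expect_equal(rendered_pulse, sim_pulse, tolerance = 1e-9)
})

test_that("fronts faster than a droplet per frame trigger the aliasing warning", {
  arr <- relay_array(2, 1, 30, droplet_px = 20L)
  cpl <- coupling_spec(arr$layout, 1, 0, 0)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 1, duration_s = 60,
                         front_speed_px_s = 20)
  expect_warning(render_kymograph(sim, arr$layout, noise = no_noise()),
                 "alias")
})
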