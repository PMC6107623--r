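test_that("identical seed and configuration give bit-identical simulations", {
  s <- lifecycle_schedule(2, droplet_id = c("a", "b"))
  x <- simulate_traces(s, seed = 9)
  y <- simulate_traces(s, seed = 9)
  expect_identical(x$traces, y$traces)
  expect_identical(x$truth, y$truth)
  z <- simulate_traces(s, seed = 10)
  expect_false(identical(x$traces$intensity, z$traces$intensity))
})

test_that("schedule arithmetic: a 600 s main period at 0.04 per s gives 24 pulses", {
  sched <- lifecycle_schedule(1, initial_duration_s = 0, late_duration_s = 0,
                              main_duration_s = 600)
  sim <- simulate_traces(sched, noise = no_noise(), seed = 1)
  expect_equal(nrow(sim$truth$waves), 24L)
  a <- analyze_trace(sim$traces)
  expect_equal(a$features$wave_count, 24L)
})

test_that("zero droplets simulate to an empty result", {
  empty <- lifecycle_schedule(0)
  sim <- simulate_traces(empty, seed = 1)
  expect_equal(nrow(sim$traces), 0L)
  expect_equal(nrow(sim$truth$waves), 0L)
})

test_that("invalid schedules are rejected", {
  expect_error(lifecycle_schedule(1, main_duration_s = -5),
               class = "dropwave_validation_error")
  expect_error(lifecycle_schedule(1, main_freq_start = 0),
               class = "dropwave_validation_error")
  # lifecycle frequency ordering: initial faster than main, late faster
  # than the main end
  expect_error(lifecycle_schedule(1, initial_freq = 0.03),
               class = "dropwave_validation_error")
  expect_error(lifecycle_schedule(1, late_freq = 0.02),
               class = "dropwave_validation_error")
  expect_error(lifecycle_schedule(1, final_state = "blue"),
               class = "dropwave_validation_error")
})

test_that("coupled droplets pulse after the configured transit and delay", {
  arr <- relay_array(3, 1, 30)  # single wave from droplet 1
  cpl <- coupling_spec(arr$layout, 1, crossing_delay_s = 5, refractory_s = 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 2, duration_s = 400)
  w <- sim$truth$waves
  t1 <- w$time_s[w$droplet_id == "d1"][1]
  t2 <- w$time_s[w$droplet_id == "d2"][1]
  t3 <- w$time_s[w$droplet_id == "d3"][1]
  # centre-to-centre: half-span transit, delay, half-span transit
  expected_gap <- 54 / 2.5 + 5 + 54 / 2.5
  expect_equal(t2 - t1, expected_gap, tolerance = 2 * 2.5 / expected_gap)
  expect_equal(t3 - t2, expected_gap, tolerance = 2 * 2.5 / expected_gap)
  expect_equal(sum(sim$truth$crossings$crossed), 2L)
  # the relayed pulses appear in the receiving droplets' traces
  for (id in c("d2", "d3")) {
    tr <- sim$traces[sim$traces$droplet_id == id, ]
    expect_gt(max(tr$intensity) - min(tr$intensity), 30)
  }
})

test_that("realised propagated fractions stay within binomial bounds of the probability", {
  p <- 0.6
  crossed <- integer(0)
  for (seed in 1:5) {
    arr <- relay_array(2, 1, 500)  # 20 waves at the single interface
    cpl <- coupling_spec(arr$layout, p, 5, 10)
    sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                           noise = no_noise(), seed = seed, duration_s = 700)
    crossed <- c(crossed, sim$truth$crossings$crossed)
  }
  bt <- stats::binom.test(sum(crossed), length(crossed), p)
  expect_gt(bt$p.value, 0.05)
})

test_that("spiral starts are drawn at the scheduled probability", {
  sched <- lifecycle_schedule(200, spiral_start_probability = 0.2,
                              main_duration_s = 10, initial_duration_s = 0,
                              late_duration_s = 0, induction_s = 0)
  sim <- simulate_traces(sched, noise = no_noise(), seed = 6, duration_s = 30)
  frac <- mean(sim$truth$spiral_start$spiral)
  expect_gt(stats::binom.test(sum(sim$truth$spiral_start$spiral), 200, 0.2)$p.value,
            0.05)
  expect_true(frac > 0.1 && frac < 0.35)
})

test_that("an oxidised final state leaves the trace high after exhaustion", {
  red <- simulate_traces(lifecycle_schedule(1, main_duration_s = 300,
                                            initial_duration_s = 0,
                                            late_duration_s = 0),
                         noise = no_noise(), seed = 1, duration_s = 600)
  oxi <- simulate_traces(lifecycle_schedule(1, main_duration_s = 300,
                                            initial_duration_s = 0,
                                            late_duration_s = 0,
                                            final_state = "oxidised"),
                         noise = no_noise(), seed = 1, duration_s = 600)
  tail_red <- red$traces$intensity[red$traces$time_s > 500]
  tail_oxi <- oxi$traces$intensity[oxi$traces$time_s > 500]
  expect_equal(unique(tail_red), 70)
  expect_true(all(tail_oxi > 90))
})
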