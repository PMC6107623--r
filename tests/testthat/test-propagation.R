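test_that("a degenerate constant kymograph binarises to an empty mask", {
  lay <- linear_layout(2)
  flat <- structure(matrix(100, 216, 40), class = c("bz_kymograph", "matrix"),
                    times = (0:39) * 2.5, frame_rate = 0.4, t0_offset = 0,
                    strip_width = 15L, cols_per_frame = 1L, channel = "blue",
                    slot_id = "slot1", y_start = 0L)
  mask <- binarize_fronts(flat)
  expect_false(any(mask))
  expect_equal(nrow(track_wavefronts(mask, lay)$tracks), 0L)
})

test_that("a single rendered front binarises to one component hugging the band", {
  arr <- relay_array(2, 1, 30)  # one wave, two fronts; down-front crosses
  cpl <- coupling_spec(arr$layout, 1, 5, 10)
  # slow front so successive band positions overlap pixel-wise and each
  # front is one connected component
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 2, duration_s = 300,
                         front_speed_px_s = 1)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  mask <- binarize_fronts(kymo)
  fronts <- sim$truth$fronts
  half <- 9 / 2
  for (j in which(apply(mask, 2, any))) {
    t <- attr(mask, "times")[j]
    pos <- fronts$position_px[abs(fronts$time_s - t) < 1e-6]
    rows <- which(mask[, j]) - 1L
    # every marked pixel lies within the rendered band plus 1 px dilation
    expect_true(all(vapply(rows, function(r) any(abs(r - pos) <= half + 1),
                           logical(1))))
  }
  # components per column match the number of rendered fronts (oracle:
  # EBImage connected-component labelling on the mask)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  expect_equal(max(lab), 2L)  # up-front and down-front, disjoint in space-time
})

test_that("fully coupled arrays carry one track across every droplet", {
  arr <- relay_array(5, 1, 30)
  cpl <- coupling_spec(arr$layout, 1, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 5, duration_s = 350)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  tracks <- track_wavefronts(binarize_fronts(kymo), arr$layout)
  expect_equal(max(tracks$tracks$n_droplets), 5L)
  rep <- classify_interfaces(tracks)
  expect_true(all(rep$interfaces$coupled))
  expect_equal(sum(rep$interfaces$propagated), sum(sim$truth$crossings$crossed))
})

test_that("uncoupled arrays block every arriving front at the interfaces", {
  arr <- relay_array(3, 2, 250)
  cpl <- coupling_spec(arr$layout, 0, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 3, duration_s = 400)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  rep <- classify_interfaces(track_wavefronts(binarize_fronts(kymo), arr$layout))
  expect_true(all(rep$interfaces$coupled %in% FALSE))
  expect_equal(rep$interfaces$propagated, c(0L, 0L))
  expect_equal(rep$interfaces$blocked, c(10L, 10L))
  agree <- propagation_agreement(sim$truth$crossings, rep$interfaces)
  expect_equal(agree$accuracy, 1)
})

test_that("detected propagated fractions respect binomial bounds at p = 0.5", {
  arr <- relay_array(2, 1, 1000)  # 40 fronts arriving at the interface
  cpl <- coupling_spec(arr$layout, 0.5, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 8, duration_s = 1200)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  rep <- classify_interfaces(track_wavefronts(binarize_fronts(kymo), arr$layout))
  n <- rep$interfaces$total[1]
  k <- rep$interfaces$propagated[1]
  expect_equal(n, 40L)
  expect_gt(stats::binom.test(k, n, 0.5)$p.value, 0.05)
  # and the detected outcomes equal the scheduled draws exactly
  agree <- propagation_agreement(sim$truth$crossings, rep$interfaces)
  expect_equal(agree$accuracy, 1)
})

test_that("opposing equal-speed fronts annihilate at the midpoint", {
  arr <- relay_array(5, c(1, 5), 30)
  arr$schedule$main_duration_s <- c(30, 0, 0, 0, 30)
  cpl <- coupling_spec(arr$layout, 1, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 3, duration_s = 500)
  expect_equal(nrow(sim$truth$annihilations), 1L)
  expect_equal(sim$truth$annihilations$position_px, 270, tolerance = 0.05)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  tracks <- track_wavefronts(binarize_fronts(kymo), arr$layout)
  rep <- classify_interfaces(tracks)
  expect_equal(nrow(rep$annihilations), 1L)
  # midpoint recovered within one droplet span
  expect_lt(abs(rep$annihilations$position_px - 270), 108)
  expect_equal(sum(tracks$tracks$termination == "annihilation"), 2L)
})

test_that("every track terminates in exactly one of the three ways", {
  arr <- relay_array(4, 2, 200)
  cpl <- coupling_spec(arr$layout, 0.5, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         seed = 12, duration_s = 400)
  kymo <- render_kymograph(sim, arr$layout)
  tracks <- track_wavefronts(binarize_fronts(kymo), arr$layout)
  expect_true(all(tracks$tracks$termination %in%
                    c("boundary", "annihilation", "dissipation")))
  expect_false(any(is.na(tracks$tracks$termination)))
})

test_that("reversing the kymograph's time axis reverses track directions", {
  arr <- relay_array(3, 1, 60)
  cpl <- coupling_spec(arr$layout, 1, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 4, duration_s = 250)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  fwd <- track_wavefronts(binarize_fronts(kymo), arr$layout)
  rev_kymo <- kymo
  rev_kymo[] <- unclass(kymo)[, rev(seq_len(ncol(kymo)))]
  bwd <- track_wavefronts(binarize_fronts(rev_kymo), arr$layout)
  count <- function(tr, dir) sum(tr$tracks$direction == dir & tr$tracks$n_samples > 5)
  expect_equal(count(fwd, "down"), count(bwd, "up"))
  expect_equal(count(fwd, "up"), count(bwd, "down"))
})

test_that("wave origins are labelled interface, wall or interior", {
  arr <- relay_array(3, 2, 60)  # source in the middle droplet
  cpl <- coupling_spec(arr$layout, 1, 5, 10)
  sim <- simulate_traces(arr$schedule, layout = arr$layout, coupling = cpl,
                         noise = no_noise(), seed = 4, duration_s = 300)
  kymo <- render_kymograph(sim, arr$layout, noise = no_noise())
  rep <- classify_interfaces(track_wavefronts(binarize_fronts(kymo), arr$layout))
  org <- rep$origins
  # the source droplet's waves start in its interior
  expect_true("interior" %in% org$origin[org$droplet_id == "d2"])
  # the neighbours are entered through their shared interface with d2
  expect_true(all(org$origin[org$droplet_id == "d1"] == "interface-bottom"))
  expect_true(all(org$origin[org$droplet_id == "d3"] == "interface-top"))
})
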