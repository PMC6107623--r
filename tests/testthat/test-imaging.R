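gray_stack <- function(values, h = 40, w = 31, frame_rate = 0.4) {
  frame_stack(lapply(values, function(v) matrix(v, h, w)),
              frame_rate = frame_rate)
}

small_layout <- function(n = 1L, droplet_px = 40L) {
  linear_layout(n, droplet_px = droplet_px, width_px = 24L,
                width_mm = 2.5 * 24 / 108, centre_x = 15L)
}

test_that("frame stacks validate dimensions and carry mixing-based timestamps", {
  st <- gray_stack(rep(0.5, 24))
  expect_length(st$frames, 24L)
  expect_equal(st$times, (0:23) / 0.4)
  expect_equal(length(st$frames) / st$frame_rate, 60)  # 24 frames cover 60 s
  st1 <- gray_stack(0.2)
  expect_length(st1$frames, 1L)
  expect_error(frame_stack(list(matrix(0, 4, 4), matrix(0, 5, 4))),
               "mismatch", class = "dropwave_validation_error")
  expect_error(frame_stack(list()), class = "dropwave_validation_error")
  st2 <- gray_stack(0.3, frame_rate = 0.4)
  st2 <- frame_stack(st2$frames, frame_rate = 0.4, t0_offset = 270)
  expect_equal(st2$times[1], 270)
})

test_that("frames written as PNGs read back in temporal order", {
  st <- gray_stack(seq(0, 1, length.out = 12))
  dir <- withr::local_tempdir()
  write_frames(st, dir)
  back <- read_frames(dir, frame_rate = 0.4)
  expect_length(back$frames, 12L)
  for (i in c(1L, 7L, 12L)) {
    expect_equal(back$frames[[i]], st$frames[[i]], tolerance = 1 / 254)
  }
  expect_error(read_frames(withr::local_tempdir()), class = "dropwave_io_error")
})

test_that("kymograph composition conserves columns and blurs across the strip", {
  lay <- small_layout()
  st <- gray_stack(rep(0.5, 24))
  k <- build_kymograph(st, lay, strip_width = 15)
  expect_equal(ncol(k), 24 * 15)      # strip_width columns per frame
  expect_equal(nrow(k), 40)
  expect_true(all(k == k[1, 1]))      # constant frame -> constant kymograph
  kc <- build_kymograph(st, lay, collapse = TRUE)
  expect_equal(ncol(kc), 24)
  # a strip holding 0..14 across x blurs to its mean (7)
  f <- matrix(0, 40, 31)
  f[, 9:23] <- matrix(rep(0:14 / 255, each = 40), 40, 15)
  k2 <- build_kymograph(frame_stack(list(f), frame_rate = 0.4), lay)
  expect_equal(unique(as.numeric(k2)), 7)
  # strips that do not fit the frame are a geometry error
  tiny <- frame_stack(list(matrix(0, 40, 10)), frame_rate = 0.4)
  expect_error(build_kymograph(tiny, lay), class = "dropwave_geometry_error")
})

test_that("trace extraction averages the strip-by-height region per frame", {
  lay <- small_layout()
  roi <- lay$droplets[1, ]
  st <- gray_stack(rep(0, 10))
  k <- build_kymograph(st, lay)
  expect_equal(extract_trace(k, roi)$intensity, rep(0, 10))
  # frame i at constant value i -> trace[i] = i
  st2 <- gray_stack((1:10) / 255)
  tr <- extract_trace(build_kymograph(st2, lay), roi)
  expect_equal(tr$intensity, 1:10)
  expect_equal(tr$time_s, (0:9) / 0.4)
  # checkerboard 0/255 over the 15 x 5 region: 38 high of 75 px
  f <- matrix(0, 40, 31)
  cy <- roi$centre_y
  for (x in 9:23) for (y in (cy - 2):(cy + 2)) {
    f[y + 1, x] <- ((x + y) %% 2 == 1) * 1.0
  }
  stopifnot(sum(f[(cy - 1):(cy + 3), 9:23]) == 38)
  tr2 <- extract_trace(build_kymograph(frame_stack(list(f), frame_rate = 0.4), lay), roi)
  expect_equal(tr2$intensity, 255 * 38 / 75)
  # a region crossing the droplet boundary is refused with advice
  bad <- roi
  bad$centre_y <- 1L
  expect_error(extract_trace(k, bad), "centre_y",
               class = "dropwave_geometry_error")
})

test_that("trace extraction is linear in intensity and frame-permutation equivariant", {
  set.seed(11)
  vals <- runif(16, 0, 0.8)
  lay <- small_layout()
  roi <- lay$droplets[1, ]
  tr <- extract_trace(build_kymograph(gray_stack(vals), lay), roi)
  tr_scaled <- extract_trace(build_kymograph(gray_stack(vals * 0.5), lay), roi)
  expect_equal(tr_scaled$intensity, tr$intensity * 0.5)
  perm <- sample(16)
  tr_perm <- extract_trace(build_kymograph(gray_stack(vals[perm]), lay), roi)
  expect_equal(tr_perm$intensity, tr$intensity[perm])
  # collapsed and full-width kymographs are analytically equivalent
  trc <- extract_trace(build_kymograph(gray_stack(vals), lay, collapse = TRUE), roi)
  expect_equal(trc$intensity, tr$intensity)
})

test_that("colour channels select the intended plane of RGB frames", {
  lay <- small_layout()
  f <- array(0, dim = c(40, 31, 3))
  f[, , 1] <- 0.8  # red everywhere
  f[, , 3] <- 0.2  # blue low
  st <- frame_stack(list(f), frame_rate = 0.4)
  kb <- build_kymograph(st, lay, channel = "blue")
  kr <- build_kymograph(st, lay, channel = "red")
  expect_equal(unique(as.numeric(kb)), 0.2 * 255)
  expect_equal(unique(as.numeric(kr)), 0.8 * 255)
})
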