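# Registration, temporal averaging, MIP construction and FWHM estimation.

make_stack <- function(frames_ch1, frames_ch2 = frames_ch1, px = 1, dt = 4) {
  nf <- length(frames_ch1)
  d <- dim(frames_ch1[[1]])
  a <- array(0, c(d[1], d[2], 2, nf))
  for (f in seq_len(nf)) {
    a[, , 1, f] <- frames_ch1[[f]]
    a[, , 2, f] <- frames_ch2[[f]]
  }
  fov_stack(a, px, dt)
}

test_that("the reference is the pixel-wise mean of the vessel channel", {
  a <- matrix(1:9, 3, 3)
  b <- matrix(9:1, 3, 3)
  st <- make_stack(list(a, b))
  expect_equal(build_reference(st), (a + b) / 2)
  st1 <- make_stack(list(a, a, a))
  expect_equal(build_reference(st1), a)
})

test_that("translation estimation recovers known shifts to sub-pixel precision", {
  ref <- make_structured_image(96, seed = 5)
  expect_equal(estimate_shift(ref, ref)[c("dx", "dy")], list(dx = 0, dy = 0))
  fr <- shift_image(ref, 3, -2, fill = mean(ref))
  est <- estimate_shift(fr, ref)
  expect_equal(est$dx, 3, tolerance = 0.25)
  expect_equal(est$dy, -2, tolerance = 0.25)
  expect_gt(est$confidence, 0.8)
  # agrees with the exhaustive integer-search oracle
  oracle <- oracle_int_shift(fr - mean(fr), ref - mean(ref), max_shift = 6)
  expect_equal(round(est$dx), oracle[1])
  expect_equal(round(est$dy), oracle[2])
  # fractional shifts recovered within the stated tolerance
  fr2 <- shift_image(ref, 1.4, -2.6, fill = mean(ref))
  est2 <- estimate_shift(fr2, ref)
  expect_equal(est2$dx, 1.4, tolerance = 0.25)
  expect_equal(est2$dy, -2.6, tolerance = 0.25)
})

test_that("uninformative frames are flagged, never silently registered", {
  ref <- make_structured_image(96, seed = 6)
  expect_warning(out <- estimate_shift(matrix(5, 96, 96), ref), "constant")
  expect_equal(out$confidence, 0)
  set.seed(31)
  confs <- replicate(25, {
    estimate_shift(matrix(rnorm(96 * 96), 96, 96), ref)$confidence
  })
  expect_lt(max(confs), 0.2)
})

test_that("a motion-free noise-free series registers to itself exactly", {
  fr <- make_structured_image(64, seed = 7)
  st <- make_stack(list(fr, fr, fr))
  reg <- register_series(st)
  expect_equal(reg$stack$data, st$data, tolerance = 1e-12)
  expect_true(all(abs(reg$shifts$dx) < 1e-9))
})

test_that("registration recovers injected motion on both channels", {
  spec <- acquisition_spec(frame_shape = c(128, 128), duration = 120)
  nf <- 30
  set.seed(41)
  shifts <- matrix(runif(2 * nf, -4, 4), nf, 2)
  sim <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                             n_cells = 2, seed = 17, shifts = shifts)
  reg <- register_series(sim$stack)
  rx <- reg$shifts$dx - shifts[, 1]
  ry <- reg$shifts$dy - shifts[, 2]
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  expect_lt(sqrt(mean(rx^2 + ry^2)), 0.5)
  # registering an already-registered series is a near no-op
  reg2 <- register_series(reg$stack)
  expect_lt(sqrt(mean(reg2$shifts$dx^2 + reg2$shifts$dy^2)), 0.25)
})

test_that("temporal averaging reduces to block means", {
  cs <- lapply(c(0, 5, 10, 15, 20), function(v) matrix(v, 8, 8))
  st <- make_stack(cs)
  av <- temporal_average(st, 5)
  expect_equal(dim(av$data)[4], 1)
  expect_true(all(av$data == 10))
  expect_equal(av$frame_interval, 20)
  const <- make_stack(lapply(1:6, function(i) matrix(3, 8, 8)))
  expect_true(all(temporal_average(const, 3)$data == 3))
  expect_error(temporal_average(const, 9), "window")
})

test_that("temporal averaging reduces Poisson variance by the window size", {
  set.seed(10)
  frames <- lapply(1:5, function(i) matrix(rpois(120^2, 100), 120, 120))
  st <- make_stack(frames)
  av <- temporal_average(st, 5)
  expect_equal(var(as.vector(av$data[, , 1, 1])), 100 / 5, tolerance = 0.15)
})

test_that("max projection is the pixel-wise maximum", {
  f1 <- matrix(1, 4, 4); f2 <- matrix(7, 4, 4); f3 <- matrix(3, 4, 4)
  expect_true(all(max_project(list(f1, f2, f3)) == 7))
  expect_equal(max_project(list(f1)), f1)
  set.seed(2)
  fr <- lapply(1:4, function(i) matrix(rnorm(36), 6, 6))
  mp <- max_project(fr)
  for (f in fr) expect_true(all(mp >= f))
})

test_that("MIP series length is floor(frames / window) with rising timestamps", {
  zeros <- lapply(1:7, function(i) matrix(0, 8, 8))
  st <- make_stack(zeros)
  ms <- build_mip_series(st, 5)
  expect_equal(length(ms$images), 1)
  for (nf in c(5, 8, 12, 15)) {
    st2 <- make_stack(lapply(seq_len(nf), function(i) matrix(i, 4, 4)))
    ms2 <- build_mip_series(st2, 5)
    expect_equal(length(ms2$images), nf %/% 5)
    expect_true(all(diff(ms2$timestamps) > 0) || length(ms2$images) == 1)
  }
  expect_error(build_mip_series(make_stack(zeros[1:3]), 5), "fewer")
  # 150-frame session at window 5 gives the 30-point series
  big <- fov_stack(array(0, c(4, 4, 2, 150)), 1, 4)
  expect_equal(length(build_mip_series(big, 5)$images), 30)
})

test_that("averaging and projection commute with spatial cropping", {
  set.seed(3)
  frames <- lapply(1:6, function(i) matrix(rnorm(100), 10, 10))
  st <- make_stack(frames)
  crop <- function(m) m[3:8, 2:7]
  av_full <- temporal_average(st, 3)$data[, , 1, 1]
  st_crop <- make_stack(lapply(frames, crop))
  expect_equal(crop(av_full), temporal_average(st_crop, 3)$data[, , 1, 1])
  expect_equal(crop(max_project(frames)), max_project(lapply(frames, crop)))
})

test_that("the MIP contains every constituent frame's signal", {
  spec <- acquisition_spec(frame_shape = c(96, 96), duration = 20)
  sim <- generate_fov_series(spec, condition_preset("diabetic"), noise_model(),
                             n_cells = 1, seed = 5)
  ms <- build_mip_series(sim$stack, 5)
  for (f in 1:5)
    expect_true(all(ms$images[[1]] >= sim$stack$data[, , 2, f]))
})

test_that("FWHM matches the Gaussian closed form and is invariant to scale/offset", {
  for (sigma in c(0.5, 1, 5)) {
    x <- seq(-8 * sigma, 8 * sigma, length.out = 400)
    y <- exp(-x^2 / (2 * sigma^2))
    expect_equal(compute_fwhm(x, y), 2 * sqrt(2 * log(2)) * sigma,
                 tolerance = 0.01)
    expect_equal(compute_fwhm(x, 7 * y + 100),
                 compute_fwhm(x, y), tolerance = 1e-9)
  }
})

test_that("FWHM of a rectangular pulse is its width", {
  x <- seq(-5, 5, by = 0.25)
  y <- ifelse(abs(x) < 2, 1, ifelse(abs(x) == 2, 0.5, 0))
  expect_equal(compute_fwhm(x, y), 4)
})

test_that("FWHM errors on degenerate profiles", {
  x <- seq(0, 10, length.out = 50)
  expect_error(compute_fwhm(x, x), "crossing|monotone")
  expect_error(compute_fwhm(x[1:4], x[1:4]), "at least 5")
  expect_error(compute_fwhm(x, rep(1, 50)), "peak")
})

test_that("a noisy profile built at the lateral-resolution target is recovered", {
  target <- 1.38  # um, lateral line-spread width of the imaging system
  sigma <- target / (2 * sqrt(2 * log(2)))
  x <- seq(-4, 4, length.out = 800)
  set.seed(8)
  y <- exp(-x^2 / (2 * sigma^2)) + rnorm(800, 0, 0.05)
  y <- pmax(y, 0)
  est <- compute_fwhm(x, y)
  expect_equal(est, target, tolerance = 0.05 / target)
  est_g <- compute_fwhm(x, y, method = "gauss")
  expect_equal(est_g, target, tolerance = 0.05 / target)
})

test_that("line profiles across a rendered process recover its optical width", {
  sc <- render_cell_scene(soma_r = 8, tip_r = 38, angles = 0)
  # profile perpendicular to the process, ~20 um beyond the soma edge
  pr <- profile_line(sc$img, c(100, 70), c(100, 90), pixel_size = 1, n = 400)
  expect_equal(compute_fwhm(pr$position, pr$intensity),
               2 * sqrt(2 * log(2)) * 0.8, tolerance = 0.1)
})
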