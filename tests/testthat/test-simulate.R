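# Synthetic two-channel generator: acquisition arithmetic, determinism,
# rendering and noise contracts, tip dynamics, truth serialisation.

test_that("acquisition spec enforces its invariants and frame arithmetic", {
  spec <- acquisition_spec(duration = 600, frame_interval = 4)
  expect_equal(n_frames(spec), 150)
  expect_error(acquisition_spec(duration = 601, frame_interval = 4), "multiple")
  expect_error(acquisition_spec(pixel_size = 0), "pixel_size")
  expect_error(acquisition_spec(frame_interval = -1), "frame_interval")
  expect_error(acquisition_spec(n_channels = 3), "fixed at 2")
})

test_that("condition presets encode the diabetic-vs-control orderings", {
  ctl <- condition_preset("control")
  dm <- condition_preset("diabetic")
  lira <- condition_preset("liraglutide")
  lps <- condition_preset("lps")
  expect_gt(dm$soma_radius_mean, ctl$soma_radius_mean)
  expect_lt(dm$process_length_mean, ctl$process_length_mean)
  expect_lt(dm$territory_scale, ctl$territory_scale)
  expect_gt(dm$tip_step_sd, ctl$tip_step_sd)
  expect_gt(dm$retraction_speed_gain, ctl$retraction_speed_gain)
  expect_lte(lira$tip_step_sd, ctl$tip_step_sd)
  expect_gt(lps$tip_step_sd / dm$tip_step_sd, 0.8)
  expect_error(condition_preset("control", bogus = 1), "unknown")
  expect_error(condition_preset("control", extension_bias = 2), "extension_bias")
})

test_that("generator is deterministic and produces the requested geometry", {
  spec <- acquisition_spec(frame_shape = c(96, 96), duration = 20)
  s1 <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                            n_cells = 1, seed = 7)
  s2 <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                            n_cells = 1, seed = 7)
  expect_identical(s1$stack$data, s2$stack$data)
  expect_identical(s1$truth$tip_x, s2$truth$tip_x)
  expect_equal(dim(s1$stack$data), c(96, 96, 2, 5))
  expect_equal(nrow(s1$truth$shifts), 5)
  # truth time base equals frame time base; every cell has a truth record
  expect_equal(nrow(s1$truth$soma_area), 5)
  expect_equal(s1$truth$n_cells, nrow(s1$truth$cells))
  expect_true(all(s1$truth$soma_area >= 0))
})

test_that("an empty field is pure background at the configured offset", {
  spec <- acquisition_spec(frame_shape = c(64, 64), duration = 12)
  nm <- noise_model(background_offset = 140, read_noise_sd = 6,
                    motion_amplitude = 0)
  sim <- generate_fov_series(spec, condition_preset("control"), nm,
                             n_cells = 0, seed = 3)
  mg <- sim$stack$data[, , 2, ]
  expect_equal(mean(mg), 140, tolerance = 0.01)
})

test_that("render_frame honours the detector contract and determinism", {
  spec <- acquisition_spec(frame_shape = c(64, 64), duration = 4)
  nm <- noise_model(read_noise_sd = 0, background_offset = 77,
                    motion_amplitude = 0)
  fr <- render_frame(list(), spec, nm, seed = 1)
  expect_true(all(fr$microglia == 77))
  expect_true(all(fr$vessels == 77))
  f1 <- render_frame(list(), spec, noise_model(), seed = 9)
  f2 <- render_frame(list(), spec, noise_model(), seed = 9)
  expect_identical(f1$microglia, f2$microglia)
})

test_that("a rendered disk covers the analytic area", {
  spec <- acquisition_spec(frame_shape = c(64, 64), duration = 4)
  state <- list(somas = data.frame(x = 32, y = 32, radius = 10))
  img <- render_frame(state, spec, noise = NULL)$microglia
  count <- sum(img >= max(img) / 2)
  expect_equal(count, pi * 100, tolerance = 0.05)
})

test_that("both channels receive the identical injected shift", {
  spec <- acquisition_spec(frame_shape = c(64, 64), duration = 4)
  state0 <- list(somas = data.frame(x = 30, y = 30, radius = 6),
                 vessels = make_structured_image(64, seed = 2))
  state_sh <- c(state0, list(shift = c(3, -2)))
  a <- render_frame(state0, spec, noise = NULL)
  b <- render_frame(state_sh, spec, noise = NULL)
  expect_equal(b$vessels, shift_image(a$vessels, 3, -2), tolerance = 1e-12)
  expect_equal(b$microglia, shift_image(a$microglia, 3, -2), tolerance = 1e-12)
})

test_that("noise statistics follow the Poisson + read-noise prediction", {
  spec <- acquisition_spec(frame_shape = c(128, 128), duration = 4)
  nm <- noise_model(photon_gain = 1, read_noise_sd = 8, background_offset = 50,
                    motion_amplitude = 0)
  state <- list(vessels = matrix(200, 128, 128))
  fr <- render_frame(state, spec, nm, seed = 11)
  pred <- 1 * 200 + 8^2
  expect_equal(var(as.vector(fr$vessels)), pred, tolerance = 0.10)
  # signal-free channel: variance = read noise only
  expect_equal(var(as.vector(fr$microglia)), 64, tolerance = 0.10)
})

test_that("cell placement overflow raises an explicit error", {
  spec <- acquisition_spec(frame_shape = c(64, 64), duration = 4)
  expect_error(
    generate_fov_series(spec, condition_preset("control"), noise_model(),
                        n_cells = 100, seed = 1),
    "placement overflow")
})

test_that("tip steps are Rayleigh with the preset step size", {
  preset <- condition_preset("control", tip_step_sd = 0.5)
  n <- 10000
  pos <- cbind(runif(n, 90, 110), runif(n, 90, 110))
  anch <- matrix(0, n, 2)
  new <- step_tip_positions(pos, anch, preset, interval = 4, seed = 21,
                            territory_radius = Inf)
  steps <- sqrt(rowSums((new - pos)^2))
  expect_equal(mean(steps), 0.5 * sqrt(pi / 2), tolerance = 0.03)
  # zero step size leaves positions untouched
  frozen <- condition_preset("control", tip_step_sd = 0)
  expect_identical(step_tip_positions(pos, anch, frozen, seed = 1), pos)
})

test_that("retraction gain scales inward step magnitudes", {
  preset <- condition_preset("control", tip_step_sd = 1,
                             retraction_speed_gain = 2)
  n <- 10000
  pos <- cbind(rep(100, n), rep(0, n))
  anch <- matrix(0, n, 2)
  new <- step_tip_positions(pos, anch, preset, interval = 4, seed = 22,
                            territory_radius = Inf)
  d <- new - pos
  rhat <- pos / sqrt(rowSums(pos^2))
  inward <- rowSums(d * rhat) < 0
  ratio <- mean(sqrt(rowSums(d[inward, ]^2))) /
    mean(sqrt(rowSums(d[!inward, ]^2)))
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("preset orderings hold on generated truth at n >= 30 cells", {
  spec <- acquisition_spec(frame_shape = c(384, 384), duration = 8)
  ctl <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                             n_cells = 40, seed = 1)$truth
  dm <- generate_fov_series(spec, condition_preset("diabetic"), noise_model(),
                            n_cells = 40, seed = 2)$truth
  expect_gt(mean(pi * dm$cells$soma_radius^2), mean(pi * ctl$cells$soma_radius^2))
  tot_len <- function(tr) {
    pl <- truth_process_lengths(tr, 1)
    mean(tapply(pl$length, pl$cell, sum))
  }
  expect_lt(tot_len(dm), tot_len(ctl))
})

test_that("ground truth round-trips through its CSV + header serialisation", {
  spec <- acquisition_spec(frame_shape = c(128, 128), duration = 120)
  sim <- generate_fov_series(spec, condition_preset("diabetic"), noise_model(),
                             n_cells = 3, seed = 13)
  dir <- withr::local_tempdir()
  write_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$shifts, sim$truth$shifts, tolerance = 1e-9)
  expect_equal(back$soma_area, sim$truth$soma_area, tolerance = 1e-9)
  expect_equal(back$tip_x, sim$truth$tip_x, tolerance = 1e-9)
  expect_equal(back$tip_y, sim$truth$tip_y, tolerance = 1e-9)
  expect_equal(back$cells$x, sim$truth$cells$x, tolerance = 1e-9)
  expect_equal(unclass(back$preset), unclass(sim$truth$preset))
  expect_equal(back$seed, sim$truth$seed)
  # tip table row count = total tips x frames
  tips_csv <- read.csv(file.path(dir, "tips.csv"))
  expect_equal(nrow(tips_csv), nrow(sim$truth$tip_map) * 30)
})

test_that("an empty truth still writes valid files", {
  spec <- acquisition_spec(frame_shape = c(64, 64), duration = 8)
  sim <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                             n_cells = 0, seed = 1)
  dir <- withr::local_tempdir()
  write_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$n_cells, 0)
  expect_equal(nrow(back$tip_map), 0)
})
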