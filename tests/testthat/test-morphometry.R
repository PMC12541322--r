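# Static per-cell morphometry: soma detection/segmentation, skeleton lengths,
# territory polygons, density and the pixel-size invariance.

test_that("soma detection: blank image yields no seeds", {
  expect_equal(nrow(detect_somata(matrix(0, 64, 64), 1)), 0)
})

test_that("soma detection finds simulated somata near their true centres", {
  spec <- acquisition_spec(frame_shape = c(256, 256), duration = 20)
  sim <- generate_fov_series(spec, condition_preset("control"), noise_model(),
                             n_cells = 7, seed = 42)
  mip <- build_mip_series(sim$stack, 5)$images[[1]]
  seeds <- detect_somata(mip, 1)
  expect_equal(nrow(seeds), 7)
  d <- sapply(seq_len(7), function(i)
    min(sqrt((seeds$x - sim$truth$cells$x[i])^2 +
               (seeds$y - sim$truth$cells$y[i])^2)))
  expect_lt(max(d), 3)
})

test_that("nearby somata are flagged ambiguous, not merged", {
  spec <- acquisition_spec(frame_shape = c(96, 96), duration = 4)
  state <- list(somas = data.frame(x = c(40, 46), y = c(48, 48),
                                   radius = c(2.5, 2.5)))
  img <- render_frame(state, spec, noise = NULL)$microglia
  seeds <- detect_somata(img, 1, min_separation_um = 8)
  expect_equal(nrow(seeds), 2)
  expect_true(all(seeds$ambiguous))
})

test_that("wand segmentation recovers a rendered disk's area", {
  sc <- render_cell_scene(soma_r = 10, angles = numeric(0))
  soma <- segment_soma(sc$img, c(81, 81), 1)
  expect_equal(soma$area, pi * 100, tolerance = 0.05)
  expect_equal(unname(soma$centroid), c(80, 80), tolerance = 0.5)
})

test_that("tolerance 0 on a flat disk recovers the full disk", {
  img <- matrix(0, 64, 64)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, `+`))
  img[d <= 8] <- 50
  soma <- segment_soma(img, c(32, 32), 1, tolerance = 0)
  expect_equal(soma$area, sum(d <= 8))
})

test_that("a seed on background is rejected", {
  img <- matrix(0, 64, 64); img[30:34, 30:34] <- 100
  expect_error(segment_soma(img, c(5, 5), 1), "bad seed")
})

test_that("a single oblique process measures its constructed length", {
  sc <- render_cell_scene(soma_r = 8, tip_r = 38, angles = 37 * pi / 180)
  soma <- segment_soma(sc$img, c(81, 81), 1)
  sk <- extract_skeleton(sc$img, soma, 1)
  prim <- primary_process_lengths(sk)
  expect_length(prim, 1)
  expect_equal(prim, 30, tolerance = 1.5 / 30)
  expect_equal(nrow(sk$tips), 1)
  expect_equal(total_process_length(sk), 30, tolerance = 0.05)
})

test_that("a four-arm cross measures four tips and its total length", {
  sc <- render_cell_scene(soma_r = 6, tip_r = 31,
                          angles = c(0, pi / 2, pi, 3 * pi / 2))
  soma <- segment_soma(sc$img, c(81, 81), 1)
  sk <- extract_skeleton(sc$img, soma, 1)
  expect_equal(nrow(sk$tips), 4)
  expect_equal(total_process_length(sk), 100, tolerance = 0.05)
  expect_equal(primary_process_lengths(sk), rep(25, 4), tolerance = 0.06)
})

test_that("a soma without processes yields an empty skeleton", {
  sc <- render_cell_scene(soma_r = 9, angles = numeric(0))
  soma <- segment_soma(sc$img, c(81, 81), 1)
  sk <- extract_skeleton(sc$img, soma, 1)
  expect_equal(nrow(sk$tips), 0)
  expect_equal(total_process_length(sk), 0)
  expect_length(primary_process_lengths(sk), 0)
})

test_that("a branching process reports the trunk as the primary length", {
  # Y-shaped cell built from thin strokes so the skeleton junction sits at
  # the constructed branch point: trunk 15 um, two branches 10 um
  spec <- acquisition_spec(frame_shape = c(128, 128), duration = 4)
  ctr <- c(64, 64); rs <- 6
  img <- render_frame(list(somas = data.frame(x = 64, y = 64, radius = rs)),
                      spec, noise = NULL)$microglia
  bp <- ctr + c(rs + 15, 0)  # branch point 15 um from the soma edge
  ang <- c(-50, 50) * pi / 180
  segs <- rbind(
    c(ctr[1] + rs - 1, ctr[2], bp[1], bp[2], 200),
    c(bp[1], bp[2], bp[1] + 10 * cos(ang[1]), bp[2] + 10 * sin(ang[1]), 200),
    c(bp[1], bp[2], bp[1] + 10 * cos(ang[2]), bp[2] + 10 * sin(ang[2]), 200))
  img <- img + microsurv:::draw_strokes(matrix(0, 128, 128), segs, 0.6, 1)
  soma <- segment_soma(img, c(65, 65), 1)
  sk <- extract_skeleton(img, soma, 1)
  prim <- primary_process_lengths(sk)
  expect_length(prim, 1)
  expect_equal(prim, 15, tolerance = 1 / 15)
  expect_equal(nrow(sk$tips), 2)
  expect_gte(total_process_length(sk), max(prim))
})

test_that("territory area follows the shoelace formula on known polygons", {
  sq <- rbind(c(0, 0), c(40, 0), c(40, 40), c(0, 40))
  expect_equal(territory_area(sq, c(20, 20))$area, 1600)
  tri <- rbind(c(0, 0), c(4, 0), c(0, 3))
  expect_equal(territory_area(tri, c(1, 1))$area, 6)
})

test_that("territory area is invariant to tip ordering and flags degeneracy", {
  set.seed(12)
  tips <- cbind(rnorm(8, 0, 10), rnorm(8, 0, 10))
  a1 <- territory_area(tips, c(0, 0))$area
  for (i in 1:5) {
    a2 <- territory_area(tips[sample(8), ], c(0, 0))$area
    expect_equal(a2, a1, tolerance = 1e-12)
  }
  expect_true(territory_area(tips[1:2, ], c(0, 0))$degenerate)
  col <- cbind(1:5, 2 * (1:5))
  res <- territory_area(col, c(3, 6))
  expect_true(res$degenerate)
  expect_equal(res$area, 0)
})

test_that("shoelace areas agree with the rasterisation oracle", {
  set.seed(99)
  for (i in 1:12) {
    k <- sample(5:12, 1)
    ang <- 2 * pi * (0:(k - 1)) / k + runif(k, -0.25, 0.25)
    r <- runif(k, 8, 20)
    tips <- cbind(r * cos(ang), r * sin(ang))
    res <- territory_area(tips, c(0, 0))
    expect_equal(res$area, oracle_raster_area(res$polygon),
                 tolerance = 0.02)
  }
})

test_that("morphometry is invariant to pixel size at fixed physical geometry", {
  for (px in c(1.0, 0.5)) {
    side <- round(160 / px)
    spec <- acquisition_spec(frame_shape = c(side, side), pixel_size = px,
                             duration = 4)
    ctr <- c(80, 80)
    ang <- 2 * pi * (0:4) / 5 + 0.2
    state <- list(somas = data.frame(x = ctr[1], y = ctr[2], radius = 9),
                  tips = data.frame(cell = 1, x = ctr[1] + 35 * cos(ang),
                                    y = ctr[2] + 35 * sin(ang)))
    img <- render_frame(state, spec, noise = NULL)$microglia
    seeds <- detect_somata(img, px)
    soma <- segment_soma(img, c(seeds$row[1], seeds$col[1]), px)
    sk <- extract_skeleton(img, soma, px)
    if (px == 1.0) {
      base_area <- soma$area; base_len <- total_process_length(sk)
    } else {
      expect_equal(soma$area, base_area, tolerance = 0.05)
      expect_equal(total_process_length(sk), base_len, tolerance = 0.05)
    }
  }
})

test_that("total process length bounds every primary process length", {
  sc <- render_cell_scene(soma_r = 8, tip_r = c(30, 35, 40),
                          angles = c(0.3, 2.2, 4.4))
  soma <- segment_soma(sc$img, c(81, 81), 1)
  sk <- extract_skeleton(sc$img, soma, 1)
  prim <- primary_process_lengths(sk)
  expect_gte(total_process_length(sk) + 1e-9, max(prim))
  expect_equal(total_process_length(sk), sum(prim), tolerance = 0.02)
})

test_that("cell density counts interior cells and reports border exclusions", {
  expect_equal(nrow(detect_somata(matrix(0, 32, 32), 1)), 0)
  spec <- acquisition_spec(frame_shape = c(192, 192), duration = 4)
  xs <- c(50, 120, 60, 130, 96, 40, 150, 96, 3)
  ys <- c(50, 40, 120, 130, 85, 160, 90, 3, 96)
  state <- list(somas = data.frame(x = xs, y = ys, radius = 4))
  img <- render_frame(state, spec, noise = NULL)$microglia
  fov <- measure_mip(img, 1, morph_config(window_um = 20))
  expect_equal(cell_density(fov), 7)
  expect_equal(fov$excluded, 2)
  expect_equal(fov$n_detected, 9)
})
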