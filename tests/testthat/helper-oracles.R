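# Independent oracles and constructed-geometry fixtures used across tests.

# Even-odd point-in-polygon rasterisation: polygon area as the fraction of a
# dense grid inside the polygon, independent of the shoelace implementation.
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    denom <- yj - yi
    if (denom != 0) {
      crossed <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / denom + xi)
      inside <- xor(inside, crossed)
    }
    j <- i
  }
  inside
}

oracle_raster_area <- function(poly, n = 600) {
  bb <- apply(poly, 2, range)
  xs <- seq(bb[1, 1], bb[2, 1], length.out = n)
  ys <- seq(bb[1, 2], bb[2, 2], length.out = n)
  g <- expand.grid(x = xs, y = ys)
  mean(point_in_poly(g$x, g$y, poly)) * diff(bb[, 1]) * diff(bb[, 2])
}

# Monotone-chain convex hull + trapezoid area, independent of grDevices::chull.
oracle_hull_area <- function(pts) {
  pts <- unique(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  n <- nrow(pts)
  if (n < 3) return(0)
  cross2 <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross2(pts[h[length(h) - 1], ], pts[h[length(h)], ], pts[i, ]) <= 0)
        h <- h[-length(h)]
      h <- c(h, i)
    }
    h
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  hull <- pts[c(lower[-length(lower)], upper[-length(upper)]), , drop = FALSE]
  x <- hull[, 1]; y <- hull[, 2]
  j <- c(seq_len(nrow(hull))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Exhaustive integer-shift cross-correlation search (registration oracle).
oracle_int_shift <- function(frame, ref, max_shift = 8) {
  best <- c(0, 0); best_v <- -Inf
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    sh <- shift_image(ref, dx, dy, fill = mean(ref))
    v <- sum(frame * sh)
    if (v > best_v) { best_v <- v; best <- c(dx, dy) }
  }
  best
}

# A smooth structured random image (for registration tests).
make_structured_image <- function(n = 96, seed = 5) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n, n)
  k <- EBImage::makeBrush(9, "gaussian", sigma = 2.5)
  EBImage::filter2(img, k) * 100 + 200
}

# Render a single-cell scene: soma of radius r at centre plus straight
# processes to the given tip radii/angles; returns the clean image.
render_cell_scene <- function(side = 160, soma_r = 10, tip_r = 40,
                              angles = 2 * pi * (0:5) / 6 + 0.3,
                              noise = NULL, seed = NULL) {
  spec <- acquisition_spec(frame_shape = c(side, side), duration = 4,
                           frame_interval = 4)
  ctr <- c(side / 2, side / 2)
  tip_r <- rep_len(tip_r, length(angles))
  state <- list(
    somas = data.frame(x = ctr[1], y = ctr[2], radius = soma_r),
    tips = if (length(angles))
      data.frame(cell = 1, x = ctr[1] + tip_r * cos(angles),
                 y = ctr[2] + tip_r * sin(angles)))
  list(img = render_frame(state, spec, noise, seed)$microglia,
       ctr = ctr, spec = spec,
       tips = cbind(state$tips$x, state$tips$y))
}

# Memoised three-arm study shared by the end-to-end acceptance tests.
.study_env <- new.env(parent = emptyenv())
get_three_arm_study <- function() {
  if (is.null(.study_env$cells)) {
    .study_env$cells <- run_study(
      conditions = c("control", "diabetic", "liraglutide"),
      n_cells = 40, n_seeds = 5, base_seed = 101)
  }
  .study_env$cells
}

# Count replicates where group b exceeds (or is below) group a significantly.
count_significant <- function(cells, metric, groups, direction = c("greater", "less"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  cmp <- study_comparisons(cells, metrics = metric, groups = groups)
  ok <- cmp$p_value < alpha &
    (if (direction == "greater") cmp$mean_b > cmp$mean_a else cmp$mean_b < cmp$mean_a)
  sum(ok)
}
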