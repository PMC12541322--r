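# Synthetic two-channel time-lapse generator: ramified microglia with motile
# process tips over a static vessel background, rigid lateral motion artifact,
# Poisson-Gaussian noise, and full per-frame ground truth.

#' Place cell centres on a jittered grid with a minimum separation
#'
#' Deterministic given the RNG state. Errors when the field cannot hold
#' `n` cells at the requested separation (placement overflow), rather than
#' silently overlapping territories.
#' @noRd
place_cells <- function(n, fov_um, min_sep, margin) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  w <- fov_um[1] - 2 * margin
  h <- fov_um[2] - 2 * margin
  if (w <= 0 || h <= 0)
    stop("cell placement overflow: field too small for the requested margin")
  gx <- max(1L, ceiling(sqrt(n * w / h)))
  gy <- ceiling(n / gx)
  sx <- if (gx > 1) w / (gx - 1) else Inf
  sy <- if (gy > 1) h / (gy - 1) else Inf
  if (min(sx, sy) < min_sep)
    stop(sprintf(paste0("cell placement overflow: %d cells need separation ",
                        ">= %.1f um but the grid pitch is %.1f um"),
                 n, min_sep, min(sx, sy)))
  gpts <- as.matrix(expand.grid(
    x = margin + (seq_len(gx) - 1) * (if (gx > 1) sx else 0) + (if (gx == 1) w / 2 else 0),
    y = margin + (seq_len(gy) - 1) * (if (gy > 1) sy else 0) + (if (gy == 1) h / 2 else 0)))
  gpts <- gpts[sample.int(nrow(gpts)), , drop = FALSE][seq_len(n), , drop = FALSE]
  jit <- min((min(sx, sy) - min_sep) / 2 * 0.9, 3)
  gpts + matrix(stats::runif(2 * n, -jit, jit), n, 2)
}

#' Advance process-tip positions by one acquisition interval
#'
#' Tips take a biased persistent random-walk step: an isotropic Gaussian step
#' of per-axis sd `tip_step_sd` (scaled by `sqrt(interval / 4)` so preset
#' values refer to the 4-s acquisition interval), plus a radial drift of
#' `extension_bias * sd` along the soma-to-tip direction. Steps whose radial
#' component points towards the soma are scaled by `retraction_speed_gain`,
#' producing the extension/retraction speed asymmetry. Tips are reflected to
#' stay outside the soma and within `territory_radius` of their anchor.
#' Tips sharing an anchor are kept at least `min_tip_angle` radians apart
#' (processes of one cell are distinct structures and do not fuse): adjacent
#' tips closer in angle are rotated apart symmetrically.
#'
#' @param positions n x 2 matrix of tip positions (um; columns x, y).
#' @param anchors n x 2 matrix of soma-centre anchors (um), one row per tip.
#' @param preset a [condition_preset()].
#' @param interval time step in seconds.
#' @param seed optional integer seed for a self-contained draw.
#' @param soma_radius numeric, per-tip inner exclusion radius (um); default 0.
#' @param territory_radius numeric, per-tip outer bound (um); default Inf.
#' @param min_tip_angle minimum angular separation (radians) between tips of
#'   the same anchor; 0 disables the repulsion.
#' @return n x 2 matrix of updated positions.
#' @export
step_tip_positions <- function(positions, anchors, preset, interval = 4,
                               seed = NULL, soma_radius = 0,
                               territory_radius = Inf, min_tip_angle = 0) {
  stopifnot(ncol(positions) == 2, nrow(anchors) == nrow(positions))
  n <- nrow(positions)
  if (n == 0) return(positions)
  with_seed(seed, {
    sd0 <- preset$tip_step_sd * sqrt(interval / 4)
    if (sd0 == 0) return(positions)
    rel <- positions - anchors
    r <- pmax(sqrt(rowSums(rel^2)), 1e-9)
    rhat <- rel / r
    step <- matrix(stats::rnorm(2 * n, 0, sd0), n, 2) +
      preset$extension_bias * sd0 * rhat
    inward <- rowSums(step * rhat) < 0
    step[inward, ] <- step[inward, , drop = FALSE] * preset$retraction_speed_gain
    newp <- positions + step
    rel <- newp - anchors
    rn <- pmax(sqrt(rowSums(rel^2)), 1e-9)
    rmin <- pmax(soma_radius + 0.5, 0.5)
    rmax <- territory_radius
    rr <- rn
    below <- rr < rmin
    rr[below] <- pmin(rmin + (rmin - rr), rmax)[below]
    above <- rr > rmax
    rr[above] <- pmax(rmax - (rr - rmax), rmin)[above]
    out <- anchors + rel * (rr / rn)
    if (min_tip_angle > 0)
      out <- repel_tip_angles(out, anchors, min_tip_angle)
    out
  })
}

# Rotate same-anchor tips apart until adjacent angular gaps are >= amin
# (deterministic; radii preserved).
repel_tip_angles <- function(positions, anchors, amin) {
  key <- paste(round(anchors[, 1], 6), round(anchors[, 2], 6))
  for (k in unique(key)) {
    sel <- which(key == k)
    m <- length(sel)
    if (m < 2 || m * amin >= 2 * pi) next
    rel <- positions[sel, , drop = FALSE] - anchors[sel, , drop = FALSE]
    r <- sqrt(rowSums(rel^2))
    th <- atan2(rel[, 2], rel[, 1])
    for (it in 1:3) {
      ord <- order(th)
      gaps <- diff(c(th[ord], th[ord[1]] + 2 * pi))
      tight <- which(gaps < amin)
      if (!length(tight)) break
      for (gi in tight) {
        i <- ord[gi]; j <- ord[if (gi == m) 1 else gi + 1]
        push <- (amin - gaps[gi]) / 2
        th[i] <- th[i] - push
        th[j] <- th[j] + push
      }
    }
    positions[sel, 1] <- anchors[sel, 1] + r * cos(th)
    positions[sel, 2] <- anchors[sel, 2] + r * sin(th)
  }
  positions
}

#' Generate a two-channel time-lapse stack with ground truth
#'
#' Simulates `n_cells` ramified microglia (static somata with pulsating area,
#' straight processes ending in motile tips) over a static vessel map, under
#' the acquisition geometry of `spec` and the detector/motion model of
#' `noise`. Both channels receive the same injected per-frame translation.
#' Identical arguments (including `seed`) give bit-identical output.
#'
#' @param spec an [acquisition_spec()].
#' @param preset a [condition_preset()].
#' @param noise a [noise_model()].
#' @param n_cells number of cells to render (>= 0).
#' @param seed integer RNG seed.
#' @param shifts optional n_frames x 2 matrix of injected (dx, dy) pixel
#'   shifts; default draws each component from N(0, motion_amplitude^2).
#' @param min_separation minimum centre-to-centre cell distance (um);
#'   default `1.8 * territory_scale`.
#' @param margin border margin for cell centres (um); default
#'   `territory_scale + 4`.
#' @return list with `stack` (a `fov_stack`: array frame x channel layout
#'   stored as rows x cols x channel x frame, plus calibration) and `truth`
#'   (a `sim_truth`).
#' @examples
#' sim <- generate_fov_series(acquisition_spec(duration = 20),
#'                            condition_preset("control"), noise_model(),
#'                            n_cells = 2, seed = 1)
#' dim(sim$stack$data)  # 256 256 2 5
#' @export
generate_fov_series <- function(spec, preset, noise = noise_model(), n_cells,
                                seed, shifts = NULL, min_separation = NULL,
                                margin = NULL) {
  stopifnot(inherits(spec, "acquisition_spec"), inherits(preset, "condition_preset"),
            inherits(noise, "noise_model"), n_cells >= 0)
  nf <- n_frames(spec)
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  px <- spec$pixel_size
  fov_um <- c(nc * px, nr * px)  # (x extent, y extent)
  min_separation <- min_separation %||% (1.8 * preset$territory_scale)
  margin <- margin %||% (preset$territory_scale + 4)
  with_seed(seed, {
    vessels <- make_vessel_base(spec)
    centres <- place_cells(n_cells, fov_um, min_separation, margin)
    soma_r0 <- pmax(stats::rnorm(n_cells, preset$soma_radius_mean,
                                 preset$soma_radius_sd), 1.5)
    n_tips_cell <- if (n_cells > 0)
      sample(preset$n_primary_min:preset$n_primary_max, n_cells, replace = TRUE)
      else integer(0)
    tip_map <- data.frame(cell = rep(seq_len(n_cells), n_tips_cell))
    tip_map$tip <- unlist(lapply(n_tips_cell, seq_len), use.names = FALSE) %||% integer(0)
    ntt <- nrow(tip_map)
    # initial tips: evenly spread angles with jitter, length ~ preset mean
    ang <- unlist(lapply(n_tips_cell, function(k)
      2 * pi * (seq_len(k) - 1) / k + stats::runif(1, 0, 2 * pi) +
        stats::rnorm(k, 0, 0.15)), use.names = FALSE) %||% numeric(0)
    plen <- pmin(pmax(stats::rnorm(ntt, preset$process_length_mean,
                                   0.15 * preset$process_length_mean),
                      0.5 * preset$process_length_mean),
                 preset$territory_scale - soma_r0[tip_map$cell] - 1)
    rad0 <- soma_r0[tip_map$cell] + pmax(plen, 1)
    anchors <- centres[tip_map$cell, , drop = FALSE]
    pos <- anchors + rad0 * cbind(cos(ang), sin(ang))
    # soma area series: bounded random walk around the initial area
    A0 <- pi * soma_r0^2
    soma_area <- matrix(0, nf, max(n_cells, 1))[, seq_len(n_cells), drop = FALSE]
    if (n_cells > 0) {
      soma_area[1, ] <- A0
      for (f in seq_len(nf)[-1]) {
        a <- soma_area[f - 1, ] + stats::rnorm(n_cells, 0, preset$soma_pulsation_amp)
        soma_area[f, ] <- pmin(pmax(a, 0.6 * A0), 1.4 * A0)
      }
    }
    tip_x <- matrix(0, nf, ntt); tip_y <- matrix(0, nf, ntt)
    if (ntt > 0) {
      tip_x[1, ] <- pos[, 1]; tip_y[1, ] <- pos[, 2]
      for (f in seq_len(nf)[-1]) {
        srad <- sqrt(soma_area[f, tip_map$cell] / pi)
        pos <- step_tip_positions(pos, anchors, preset,
                                  interval = spec$frame_interval,
                                  soma_radius = srad,
                                  territory_radius = preset$territory_scale,
                                  min_tip_angle = 0.4)
        tip_x[f, ] <- pos[, 1]; tip_y[f, ] <- pos[, 2]
      }
    }
    if (is.null(shifts)) {
      shifts <- matrix(stats::rnorm(2 * nf, 0, noise$motion_amplitude), nf, 2)
    } else {
      shifts <- as.matrix(shifts)
      stopifnot(nrow(shifts) == nf, ncol(shifts) == 2)
    }
    data <- array(0, dim = c(nr, nc, 2L, nf))
    for (f in seq_len(nf)) {
      state <- list(
        somas = if (n_cells > 0)
          data.frame(x = centres[, 1], y = centres[, 2],
                     radius = sqrt(soma_area[f, ] / pi)) else NULL,
        tips = if (ntt > 0)
          data.frame(cell = tip_map$cell, x = tip_x[f, ], y = tip_y[f, ]) else NULL,
        vessels = vessels,
        shift = shifts[f, ])
      fr <- render_frame(state, spec, noise)
      data[, , 1L, f] <- fr$vessels
      data[, , 2L, f] <- fr$microglia
    }
    stack <- fov_stack(data, pixel_size = px, frame_interval = spec$frame_interval)
    truth <- structure(list(
      spec = spec, preset = preset, noise = noise, seed = seed,
      n_cells = n_cells,
      shifts = data.frame(frame = seq_len(nf), dx = shifts[, 1], dy = shifts[, 2]),
      cells = if (n_cells > 0)
        data.frame(cell = seq_len(n_cells), x = centres[, 1], y = centres[, 2],
                   soma_radius = soma_r0, n_tips = n_tips_cell)
        else data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                        soma_radius = numeric(0), n_tips = integer(0)),
      soma_area = soma_area, tip_map = tip_map,
      tip_x = tip_x, tip_y = tip_y), class = "sim_truth")
    list(stack = stack, truth = truth)
  })
}

#' Construct a calibrated two-channel image stack
#'
#' @param data numeric array, rows x cols x channel x frame (channel 1 =
#'   vessels, channel 2 = microglia).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @return An object of class `fov_stack`.
#' @export
fov_stack <- function(data, pixel_size, frame_interval) {
  stopifnot(length(dim(data)) == 4, dim(data)[3] == 2, pixel_size > 0,
            frame_interval > 0)
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 channels = c("vessels", "microglia")),
            class = "fov_stack")
}

#' @export
print.fov_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fov_stack: %d frames of %d x %d px, 2 channels, %.3g um/px, %g s/frame\n",
              d[4], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: preset '%s', %d cells, %d tips, %d frames, seed %d\n",
              x$preset$name, x$n_cells, nrow(x$tip_map), nrow(x$shifts), x$seed))
  invisible(x)
}

#' True tip positions at one frame
#' @param truth a `sim_truth`.
#' @param frame frame index.
#' @return data.frame cell, tip, x, y (um).
#' @export
truth_tips <- function(truth, frame) {
  data.frame(cell = truth$tip_map$cell, tip = truth$tip_map$tip,
             x = truth$tip_x[frame, ], y = truth$tip_y[frame, ])
}

#' True per-process lengths at one frame (soma edge to tip, um)
#' @inheritParams truth_tips
#' @return data.frame cell, tip, length.
#' @export
truth_process_lengths <- function(truth, frame) {
  tp <- truth_tips(truth, frame)
  ctr <- truth$cells[tp$cell, ]
  srad <- sqrt(truth$soma_area[frame, tp$cell] / pi)
  tp$length <- sqrt((tp$x - ctr$x)^2 + (tp$y - ctr$y)^2) - srad
  tp[, c("cell", "tip", "length")]
}

#' True territory polygon areas at one frame (um^2)
#' @inheritParams truth_tips
#' @return data.frame cell, territory_area.
#' @export
truth_territory <- function(truth, frame) {
  tp <- truth_tips(truth, frame)
  out <- lapply(split(tp, tp$cell), function(d) {
    ctr <- truth$cells[d$cell[1], ]
    ta <- territory_area(cbind(d$x, d$y), c(ctr$x, ctr$y))
    data.frame(cell = d$cell[1], territory_area = ta$area)
  })
  do.call(rbind, out)
}
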