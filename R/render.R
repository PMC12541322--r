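# Rendering primitives for the synthetic generator: curvilinear strokes with a
# Gaussian cross-section (processes, vessels), soft-edged disks (somata), and
# the Poisson + Gaussian detector model.

# Rendering amplitudes (intensity units) and physical widths (um). Somata are
# rendered brighter than process ridges so tolerance-based soma segmentation
# does not leak into processes.
.render_const <- list(
  soma_amp = 600, process_amp = 250, vessel_amp = 600,
  stroke_sigma_um = 0.8, vessel_sigma_um = 1.6, soma_edge_um = 0.3
)

#' Add Gaussian-profile strokes to a canvas
#'
#' Each segment is sampled at sub-pixel spacing and each sample stamps a small
#' Gaussian kernel; stamp amplitudes are normalised so the ridge peak of a
#' straight stroke equals `amp`.
#'
#' @param canvas numeric matrix (modified copy returned).
#' @param seg matrix/data.frame with columns x0, y0, x1, y1 (um) and amp.
#' @param sigma_um stroke cross-section sd in um.
#' @param pixel_size um per pixel.
#' @noRd
draw_strokes <- function(canvas, seg, sigma_um, pixel_size, spacing_px = 0.5) {
  if (NROW(seg) == 0) return(canvas)
  nr <- nrow(canvas); nc <- ncol(canvas)
  sigma <- sigma_um / pixel_size
  pr <- pc <- wts <- vector("list", NROW(seg))
  for (i in seq_len(NROW(seg))) {
    x0 <- seg[i, 1]; y0 <- seg[i, 2]; x1 <- seg[i, 3]; y1 <- seg[i, 4]
    len_px <- sqrt((x1 - x0)^2 + (y1 - y0)^2) / pixel_size
    ns <- max(2L, ceiling(len_px / spacing_px) + 1L)
    tt <- seq(0, 1, length.out = ns)
    pc[[i]] <- (x0 + tt * (x1 - x0)) / pixel_size + 1
    pr[[i]] <- (y0 + tt * (y1 - y0)) / pixel_size + 1
    # line-integral normalisation: sum of stamps along the ridge ~ sigma*sqrt(2*pi)/spacing
    step <- len_px / (ns - 1L)
    wts[[i]] <- rep(seg[i, 5] * step / (sigma * sqrt(2 * pi)), ns)
  }
  pr <- unlist(pr); pc <- unlist(pc); wts <- unlist(wts)
  ir <- round(pr); ic <- round(pc)
  half <- max(2L, ceiling(3 * sigma))
  off <- as.matrix(expand.grid(dr = -half:half, dc = -half:half))
  npt <- length(pr); noff <- nrow(off)
  R <- rep(ir, noff) + rep(off[, 1], each = npt)
  C <- rep(ic, noff) + rep(off[, 2], each = npt)
  D2 <- (R - rep(pr, noff))^2 + (C - rep(pc, noff))^2
  W <- rep(wts, noff) * exp(-D2 / (2 * sigma^2))
  keep <- R >= 1 & R <= nr & C >= 1 & C <= nc
  idx <- R[keep] + (C[keep] - 1) * nr
  acc <- rowsum(W[keep], idx)
  canvas[as.integer(rownames(acc))] <- canvas[as.integer(rownames(acc))] + acc[, 1]
  canvas
}

#' Add soft-edged filled disks (somata) to a canvas
#' @param disks matrix/data.frame with columns x (um), y (um), radius (um), amp.
#' @noRd
draw_disks <- function(canvas, disks, pixel_size, edge_um = .render_const$soma_edge_um) {
  if (NROW(disks) == 0) return(canvas)
  nr <- nrow(canvas); nc <- ncol(canvas)
  edge <- max(edge_um / pixel_size, 1e-3)
  for (i in seq_len(NROW(disks))) {
    cx <- disks[i, 1] / pixel_size + 1
    cy <- disks[i, 2] / pixel_size + 1
    r0 <- disks[i, 3] / pixel_size
    amp <- disks[i, 4]
    half <- ceiling(r0 + 4 * edge + 1)
    rs <- max(1L, floor(cy - half)):min(nr, ceiling(cy + half))
    cs <- max(1L, floor(cx - half)):min(nc, ceiling(cx + half))
    if (!length(rs) || !length(cs)) next
    d <- sqrt(outer((rs - cy)^2, (cs - cx)^2, `+`))
    canvas[rs, cs] <- canvas[rs, cs] + amp * stats::plogis((r0 - d) / edge)
  }
  canvas
}

#' Apply the detector model to a clean signal image
#'
#' `counts = rpois(photon_gain * signal) + background_offset + N(0, read_sd)`,
#' rounded and clamped to the 16-bit range. Draws from the current RNG stream.
#' @noRd
apply_noise <- function(clean, noise) {
  lam <- pmax(noise$photon_gain * clean, 0)
  out <- stats::rpois(length(lam), lam) + noise$background_offset
  if (noise$read_noise_sd > 0)
    out <- out + stats::rnorm(length(lam), 0, noise$read_noise_sd)
  out <- round(pmin(pmax(out, 0), 65535))
  matrix(out, nrow(clean), ncol(clean))
}

#' Render one two-channel frame from a scene state
#'
#' The scene state holds the static vessel map and the per-cell microglia
#' geometry at one time point; the frame is produced by drawing somata as
#' soft-edged disks and processes as Gaussian-profile strokes, translating
#' both channels by the injected shift (identically, as a rigid lateral
#' motion artifact), and applying the Poisson/read-noise detector model.
#'
#' @param state list with elements `somas` (data.frame: x, y, radius in um),
#'   `tips` (data.frame: cell, x, y in um; one stroke is drawn from each
#'   cell's soma towards each of its tips), optional `vessels` (numeric
#'   matrix, clean vessel intensity), and optional `shift` (c(dx, dy) pixels).
#' @param spec an [acquisition_spec()].
#' @param noise a [noise_model()], or `NULL` to return the clean (noise-free,
#'   offset-free) signal.
#' @param seed optional integer; when given, the frame is rendered under its
#'   own RNG stream so identical (state, spec, noise, seed) give identical
#'   images.
#' @return list with numeric matrices `vessels` and `microglia`.
#' @export
render_frame <- function(state, spec, noise = NULL, seed = NULL) {
  with_seed(seed, {
    nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
    px <- spec$pixel_size
    mg <- matrix(0, nr, nc)
    somas <- state$somas
    tips <- state$tips
    if (!is.null(tips) && NROW(tips) > 0) {
      if (is.null(somas)) stop("tips require somas (stroke anchors)")
      anc <- as.matrix(somas[tips$cell, c("x", "y")])
      rad <- somas$radius[tips$cell]
      dx <- tips$x - anc[, 1]; dy <- tips$y - anc[, 2]
      dd <- pmax(sqrt(dx^2 + dy^2), 1e-9)
      r0 <- pmax(rad - 1, 0.3)  # start strokes just inside the soma edge
      seg <- cbind(anc[, 1] + r0 * dx / dd, anc[, 2] + r0 * dy / dd,
                   tips$x, tips$y, rep(.render_const$process_amp, NROW(tips)))
      seg <- seg[dd > r0 + 0.5, , drop = FALSE]
      mg <- draw_strokes(mg, seg, .render_const$stroke_sigma_um, px)
    }
    if (!is.null(somas) && NROW(somas) > 0) {
      mg <- draw_disks(mg, cbind(somas$x, somas$y, somas$radius,
                                 rep(.render_const$soma_amp, NROW(somas))), px)
    }
    vs <- state$vessels %||% matrix(0, nr, nc)
    sh <- state$shift %||% c(0, 0)
    if (any(sh != 0)) {
      vs <- shift_image(vs, sh[1], sh[2], fill = 0)
      mg <- shift_image(mg, sh[1], sh[2], fill = 0)
    }
    if (is.null(noise)) return(list(vessels = vs, microglia = mg))
    list(vessels = apply_noise(vs, noise), microglia = apply_noise(mg, noise))
  })
}

#' Draw a static vessel map (clean intensity) for a field of view
#' @noRd
make_vessel_base <- function(spec) {
  nr <- spec$frame_shape[1]; nc <- spec$frame_shape[2]
  px <- spec$pixel_size
  w <- nc * px; h <- nr * px
  canvas <- matrix(0, nr, nc)
  n_ves <- max(3L, round(min(w, h) / 100))
  segs <- list()
  for (v in seq_len(n_ves)) {
    horiz <- stats::runif(1) < 0.5
    if (horiz) {
      x <- 0; y <- stats::runif(1, 0.12, 0.88) * h; ang <- 0
    } else {
      x <- stats::runif(1, 0.12, 0.88) * w; y <- 0; ang <- pi / 2
    }
    step <- 6
    pts <- list(c(x, y))
    repeat {
      ang <- ang + stats::rnorm(1, 0, 0.18)
      nxt <- pts[[length(pts)]] + step * c(cos(ang), sin(ang))
      pts[[length(pts) + 1L]] <- nxt
      if (nxt[1] < -step || nxt[1] > w + step || nxt[2] < -step || nxt[2] > h + step) break
      if (length(pts) > 400) break
    }
    p <- do.call(rbind, pts)
    segs[[v]] <- cbind(p[-nrow(p), 1], p[-nrow(p), 2], p[-1, 1], p[-1, 2],
                       .render_const$vessel_amp)
  }
  draw_strokes(canvas, do.call(rbind, segs), .render_const$vessel_sigma_um, px)
}
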