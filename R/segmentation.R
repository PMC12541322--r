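# Soma detection and tolerance-based ("wand") soma segmentation on MIP images.

#' Detect soma seed points on a MIP image
#'
#' Automates manual seed selection: the image is thresholded (Otsu), thin
#' process ridges are removed by a binary opening whose radius is matched to
#' `min_diameter_um`, and the remaining blobs become seeds (their centroids)
#' when they pass the minimum-area criterion and an intensity criterion:
#' somata are the brightest structures in the channel, so blobs whose peak
#' falls below `min_peak_frac` of the brightest blob's peak-to-background
#' range (e.g. thick swept process segments) are rejected. Deterministic
#' given the configuration. Seed pairs closer than `min_separation_um` are
#' flagged as ambiguous rather than silently merged.
#'
#' @param mip numeric matrix (microglia-channel MIP).
#' @param pixel_size um per pixel.
#' @param min_diameter_um minimum soma diameter (um).
#' @param min_separation_um seed pairs closer than this are flagged.
#' @param border_px number of border pixels to ignore (registration fill).
#' @param min_peak_frac blob peak intensity floor, as a fraction of the
#'   brightest blob's peak-to-background range.
#' @return data.frame with columns `row`, `col` (pixels), `x`, `y` (um),
#'   `area_px` and `ambiguous`; zero rows for a blank image.
#' @export
detect_somata <- function(mip, pixel_size, min_diameter_um = 4,
                          min_separation_um = 8, border_px = 0,
                          min_peak_frac = 0.5) {
  stopifnot(is.matrix(mip), pixel_size > 0)
  empty <- data.frame(row = numeric(0), col = numeric(0), x = numeric(0),
                      y = numeric(0), area_px = numeric(0), ambiguous = logical(0))
  if (stats::sd(mip) == 0) return(empty)
  th <- otsu_threshold(mip)
  fg <- mip >= th
  if (border_px > 0) {
    nr <- nrow(fg); nc <- ncol(fg)
    b <- min(border_px, floor(min(nr, nc) / 4))
    fg[c(seq_len(b), nr - seq_len(b) + 1L), ] <- FALSE
    fg[, c(seq_len(b), nc - seq_len(b) + 1L)] <- FALSE
  }
  r_px <- max(2L, round(min_diameter_um / pixel_size / 2))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  op <- EBImage::opening(fg * 1, brush)
  lab <- EBImage::bwlabel(op > 0)
  n <- max(lab)
  if (n == 0) return(empty)
  min_area <- 0.5 * pi * (min_diameter_um / pixel_size / 2)^2
  idx <- which(lab > 0)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  lv <- lab[idx]
  area <- tabulate(lv, nbins = n)
  cr <- vapply(seq_len(n), function(k) mean(rows[lv == k]), numeric(1))
  cc <- vapply(seq_len(n), function(k) mean(cols[lv == k]), numeric(1))
  pk <- vapply(seq_len(n), function(k) max(mip[idx[lv == k]]), numeric(1))
  bg <- stats::median(mip)
  keep <- area >= min_area & pk >= bg + min_peak_frac * (max(pk) - bg)
  seeds <- data.frame(row = cr[keep], col = cc[keep],
                      x = (cc[keep] - 1) * pixel_size,
                      y = (cr[keep] - 1) * pixel_size,
                      area_px = area[keep], ambiguous = FALSE)
  if (nrow(seeds) > 1) {
    dd <- as.matrix(stats::dist(seeds[, c("x", "y")]))
    diag(dd) <- Inf
    seeds$ambiguous <- apply(dd < min_separation_um, 1, any)
  }
  seeds[order(seeds$row, seeds$col), , drop = FALSE]
}

#' Segment one soma by tolerance-based region growing (wand tool)
#'
#' Grows the connected region around the seed whose intensity stays within
#' `tolerance` of the local soma level: the cutoff is
#' `peak - tolerance * (peak - background)` with `peak` the maximum in a
#' small window around the seed and `background` the image median. The
#' default `tolerance = 0.5` is the half-maximum level set, which recovers
#' the true boundary of a symmetric-edged soma without bias. The region is
#' morphologically closed and hole-filled; its area is reported in um^2.
#'
#' @param mip numeric matrix.
#' @param seed length-2 (row, col) seed position, or a row of
#'   [detect_somata()] output.
#' @param pixel_size um per pixel.
#' @param tolerance fraction of the peak-to-background range (0..1).
#' @param window_um half-width of the local analysis window (um); the soma
#'   must fit inside it.
#' @return An object of class `soma_region`: list with `mask_idx` (pixel
#'   linear indices), `dim`, `centroid` (x, y um), `area` (um^2), `seed`,
#'   `touches_border` (logical).
#' @export
segment_soma <- function(mip, seed, pixel_size, tolerance = 0.5,
                         window_um = 14) {
  stopifnot(is.matrix(mip), tolerance >= 0, tolerance <= 1)
  if (is.data.frame(seed)) seed <- c(seed$row[1], seed$col[1])
  sr <- round(seed[1]); sc <- round(seed[2])
  nr <- nrow(mip); nc <- ncol(mip)
  stopifnot(sr >= 1, sr <= nr, sc >= 1, sc <= nc)
  window_px <- max(16L, ceiling(window_um / pixel_size))
  rs <- max(1L, sr - window_px):min(nr, sr + window_px)
  cs <- max(1L, sc - window_px):min(nc, sc + window_px)
  crop <- mip[rs, cs]
  bg <- stats::median(crop)
  lr <- sr - rs[1] + 1L; lc <- sc - cs[1] + 1L
  wr <- max(1L, lr - 3L):min(nrow(crop), lr + 3L)
  wc <- max(1L, lc - 3L):min(ncol(crop), lc + 3L)
  peak <- max(crop[wr, wc])
  if (peak <= bg + 1e-9)
    stop("bad seed: seed neighbourhood is not above background")
  cutoff <- peak - tolerance * (peak - bg) - 1e-9
  mask <- crop >= cutoff
  lab <- EBImage::bwlabel(mask)
  k <- lab[lr, lc]
  if (k == 0) {
    # seed pixel itself below cutoff (can happen for off-centre seeds):
    # snap to the brightest pixel in the window
    wpk <- which(crop[wr, wc] == peak, arr.ind = TRUE)[1, ]
    k <- lab[wr[wpk[1]], wc[wpk[2]]]
  }
  if (k == 0) stop("bad seed: no region at the cutoff contains the seed")
  reg <- lab == k
  reg <- EBImage::fillHull(EBImage::closing(reg * 1, EBImage::makeBrush(3, "box"))) > 0
  idx_l <- which(reg)
  lrow <- (idx_l - 1L) %% nrow(reg) + 1L
  lcol <- (idx_l - 1L) %/% nrow(reg) + 1L
  rows <- rs[1] - 1L + lrow
  cols <- cs[1] - 1L + lcol
  idx <- rows + (cols - 1L) * nr
  structure(list(mask_idx = idx, dim = c(nr, nc),
                 centroid = c(x = (mean(cols) - 1) * pixel_size,
                              y = (mean(rows) - 1) * pixel_size),
                 area = length(idx) * pixel_size^2,
                 seed = c(sr, sc),
                 touches_border = any(rows == 1L | rows == nr |
                                        cols == 1L | cols == nc)),
            class = "soma_region")
}

#' @export
print.soma_region <- function(x, ...) {
  cat(sprintf("soma_region: area %.1f um^2, centroid (%.1f, %.1f) um%s\n",
              x$area, x$centroid[1], x$centroid[2],
              if (x$touches_border) " [touches border]" else ""))
  invisible(x)
}
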