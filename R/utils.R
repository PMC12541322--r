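# Internal utilities shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring the caller's stream
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Integer-offset matrix shift with constant fill
#' @noRd
m_shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (dr >= nr || dr <= -nr || dc >= nc || dc <= -nc) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Translate an image by a (possibly fractional) pixel offset
#'
#' Translation convention: content moves by `dx` columns (x, rightwards) and
#' `dy` rows (y, downwards); `out[r, c] = img[r - dy, c - dx]` with bilinear
#' interpolation for fractional offsets and constant fill outside the frame.
#'
#' @param img numeric matrix.
#' @param dx,dy translation in pixels (x = columns, y = rows).
#' @param fill value for pixels translated in from outside the frame.
#' @return numeric matrix of the same dimension.
#' @export
shift_image <- function(img, dx, dy, fill = 0) {
  stopifnot(is.matrix(img), is.finite(dx), is.finite(dy))
  dx0 <- floor(dx); dy0 <- floor(dy)
  fx <- dx - dx0; fy <- dy - dy0
  if (fx == 0 && fy == 0) return(m_shift(img, dy0, dx0, fill))
  (1 - fy) * (1 - fx) * m_shift(img, dy0,      dx0,      fill) +
  (1 - fy) * fx       * m_shift(img, dy0,      dx0 + 1L, fill) +
  fy       * (1 - fx) * m_shift(img, dy0 + 1L, dx0,      fill) +
  fy       * fx       * m_shift(img, dy0 + 1L, dx0 + 1L, fill)
}

#' Otsu threshold of a numeric matrix (histogram with `levels` bins)
#' @noRd
otsu_threshold <- function(x, levels = 256L) {
  v <- as.numeric(x)
  rng <- range(v, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  h <- tabulate(pmin(levels, 1L + floor((v - rng[1]) / diff(rng) * levels)), nbins = levels)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- 0
  mids[which.max(sb2)]
}

#' Shoelace (signed trapezoid) area of a closed polygon
#' @noRd
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Standard error of the mean
#'
#' @param x numeric vector (NAs dropped).
#' @return sd(x)/sqrt(n).
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  stats::sd(x) / sqrt(length(x))
}

#' Bilinear sample of an image at fractional (row, col) positions
#' @noRd
bilinear_at <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r0 <- pmin(pmax(r0, 1), nr - 1); c0 <- pmin(pmax(c0, 1), nc - 1)
  i00 <- cbind(r0, c0); i01 <- cbind(r0, c0 + 1)
  i10 <- cbind(r0 + 1, c0); i11 <- cbind(r0 + 1, c0 + 1)
  (1 - fr) * (1 - fc) * img[i00] + (1 - fr) * fc * img[i01] +
    fr * (1 - fc) * img[i10] + fr * fc * img[i11]
}

#' Intensity profile along a line segment in an image
#'
#' Samples the image by bilinear interpolation along the segment from `from`
#' to `to` (x, y in physical units), returning positions (um along the line)
#' and intensities, suitable for [compute_fwhm()].
#'
#' @param img numeric matrix.
#' @param from,to numeric length-2, (x, y) endpoints in physical units (um).
#' @param pixel_size um per pixel.
#' @param n number of samples.
#' @return data.frame with columns `position` (um) and `intensity`.
#' @export
profile_line <- function(img, from, to, pixel_size = 1, n = 200L) {
  tt <- seq(0, 1, length.out = n)
  x <- from[1] + tt * (to[1] - from[1])
  y <- from[2] + tt * (to[2] - from[2])
  # physical (x, y), origin at pixel (1,1) centre: col = x/px + 1, row = y/px + 1
  vals <- bilinear_at(img, y / pixel_size + 1, x / pixel_size + 1)
  data.frame(position = tt * sqrt(sum((to - from)^2)), intensity = vals)
}
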