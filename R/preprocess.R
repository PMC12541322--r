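# Preprocessing: vessel-referenced translation registration, temporal
# averaging, maximum-intensity projection, and FWHM resolution estimation.

#' Average-intensity vessel reference image
#'
#' Returns the pixel-wise mean of the vessel channel across all frames; each
#' frame is subsequently aligned to this reference.
#'
#' @param stack a `fov_stack`.
#' @return numeric matrix.
#' @export
build_reference <- function(stack) {
  stopifnot(inherits(stack, "fov_stack"))
  d <- dim(stack$data)
  if (d[4] < 1) stop("empty stack")
  rowMeans(stack$data[, , 1L, , drop = FALSE], dims = 2)
}

#' Estimate the translation between a frame and a reference image
#'
#' FFT cross-correlation over integer displacements up to `max_shift`,
#' refined to sub-pixel precision by a quadratic fit of the correlation peak
#' in each axis. Confidence is the Pearson correlation between the frame and
#' the reference translated by the estimate (clamped to [0, 1]); a constant
#' frame or reference yields shift (0, 0) with confidence 0 and a warning,
#' never a silent result.
#'
#' @param frame,reference numeric matrices of equal size.
#' @param max_shift search radius in pixels.
#' @return list with `dx`, `dy` (pixels; the frame content is displaced by
#'   this amount relative to the reference), and `confidence` in [0, 1].
#' @export
estimate_shift <- function(frame, reference, max_shift = 20) {
  stopifnot(is.matrix(frame), all(dim(frame) == dim(reference)))
  if (stats::sd(frame) == 0 || stats::sd(reference) == 0) {
    warning("constant image: shift undefined, returning (0, 0) with confidence 0")
    return(list(dx = 0, dy = 0, confidence = 0))
  }
  est_shift_fft(frame, reference,
                Conj(stats::fft(reference - mean(reference))), max_shift)
}

# Workhorse: cross-correlation peak with a precomputed conjugate reference
# FFT (register_series reuses it across frames).
est_shift_fft <- function(frame, reference, ref_fft_conj, max_shift) {
  nr <- nrow(frame); nc <- ncol(frame)
  f1 <- frame - mean(frame)
  cc <- Re(stats::fft(stats::fft(f1) * ref_fft_conj, inverse = TRUE)) / (nr * nc)
  # displacement u (rows), v (cols): cc index (1 + u mod nr, 1 + v mod nc)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  us <- wrap(0:(nr - 1), nr); vs <- wrap(0:(nc - 1), nc)
  ok <- outer(abs(us) <= max_shift, abs(vs) <= max_shift, `&`)
  cc_ok <- ifelse(ok, cc, -Inf)
  pk <- arrayInd(which.max(cc_ok), dim(cc))
  dy0 <- us[pk[1]]; dx0 <- vs[pk[2]]
  # quadratic sub-pixel refinement on circular neighbours
  at <- function(u, v) cc[1 + ((u %% nr)), 1 + ((v %% nc))]
  refine <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  ddy <- refine(at(dy0 - 1, dx0), at(dy0, dx0), at(dy0 + 1, dx0))
  ddx <- refine(at(dy0, dx0 - 1), at(dy0, dx0), at(dy0, dx0 + 1))
  dy <- dy0 + ddy; dx <- dx0 + ddx
  shifted_ref <- shift_image(reference, dx, dy, fill = mean(reference))
  conf <- suppressWarnings(stats::cor(as.vector(frame), as.vector(shifted_ref)))
  if (!is.finite(conf)) conf <- 0
  list(dx = dx, dy = dy, confidence = max(0, min(1, conf)))
}

#' Register a two-channel series to its average vessel image
#'
#' Estimates a per-frame translation on the vessel channel against the
#' [build_reference()] image and applies its negation to both channels with a
#' single bilinear interpolation; the identical transform on both channels
#' preserves vessel-microglia correspondence. Out-of-frame pixels are filled
#' with the frame's median background; the maximal translated-in border is
#' recorded in the `border_px` attribute of the result so downstream
#' morphometry can ignore border artifacts.
#'
#' @param stack a `fov_stack`.
#' @param max_shift registration search radius in pixels.
#' @return list with `stack` (registered `fov_stack`) and `shifts`
#'   (data.frame frame, dx, dy, confidence).
#' @export
register_series <- function(stack, max_shift = 20) {
  stopifnot(inherits(stack, "fov_stack"))
  ref <- build_reference(stack)
  nf <- dim(stack$data)[4]
  out <- stack$data
  sh <- data.frame(frame = seq_len(nf), dx = 0, dy = 0, confidence = 0)
  const_ref <- stats::sd(ref) == 0
  ref_fft_conj <- if (!const_ref) Conj(stats::fft(ref - mean(ref)))
  for (f in seq_len(nf)) {
    fr_v <- stack$data[, , 1L, f]
    est <- if (const_ref || stats::sd(fr_v) == 0)
      estimate_shift(fr_v, ref, max_shift = max_shift)
    else est_shift_fft(fr_v, ref, ref_fft_conj, max_shift)
    sh$dx[f] <- est$dx; sh$dy[f] <- est$dy; sh$confidence[f] <- est$confidence
    if (est$dx != 0 || est$dy != 0) {
      for (ch in 1:2) {
        fr <- stack$data[, , ch, f]
        out[, , ch, f] <- shift_image(fr, -est$dx, -est$dy,
                                      fill = stats::median(fr))
      }
    }
  }
  reg <- fov_stack(out, stack$pixel_size, stack$frame_interval)
  attr(reg, "border_px") <- ceiling(max(abs(c(sh$dx, sh$dy))))
  list(stack = reg, shifts = sh)
}

#' Temporal block averaging
#'
#' Averages consecutive non-overlapping windows of `window` frames (aligned
#' with the MIP windows); each output frame is the pixel-wise mean of its
#' block. A trailing partial window is dropped.
#'
#' @param stack a `fov_stack`.
#' @param window frames per block (>= 1, <= number of frames).
#' @return a `fov_stack` with `floor(n_frames / window)` frames and a frame
#'   interval of `window * frame_interval`.
#' @export
temporal_average <- function(stack, window = 5L) {
  stopifnot(inherits(stack, "fov_stack"), window >= 1)
  d <- dim(stack$data)
  if (window > d[4]) stop("window larger than the series")
  nb <- d[4] %/% window
  out <- array(0, dim = c(d[1], d[2], d[3], nb))
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * window + 1L):(b * window)
    out[, , , b] <- rowMeans(stack$data[, , , idx, drop = FALSE], dims = 3)
  }
  fov_stack(out, stack$pixel_size, stack$frame_interval * window)
}

#' Pixel-wise maximum-intensity projection of a set of frames
#'
#' @param frames numeric array rows x cols x n, or a list of matrices.
#' @return numeric matrix.
#' @export
max_project <- function(frames) {
  if (is.list(frames)) frames <- simplify2array(frames)
  if (is.matrix(frames)) return(frames)
  stopifnot(length(dim(frames)) == 3)
  if (dim(frames)[3] < 1) stop("empty input")
  apply(frames, c(1, 2), max)
}

#' Build the maximum-intensity-projection series of the microglia channel
#'
#' Consecutive non-overlapping windows of `window` registered frames each
#' yield one MIP; timestamps are window start times. A trailing partial
#' window is dropped, so the series length is `floor(n_frames / window)`
#' (30 for a 600-s session at 4 s/frame and window 5).
#'
#' @param stack a registered `fov_stack`.
#' @param window frames per MIP (default 5, i.e. 20 s of scanning at 4 s).
#' @param channel channel to project (default 2, microglia).
#' @return An object of class `mip_series`: list with `images` (list of
#'   matrices), `timestamps` (s), `window`, `pixel_size`.
#' @export
build_mip_series <- function(stack, window = 5L, channel = 2L) {
  stopifnot(inherits(stack, "fov_stack"), window >= 1)
  d <- dim(stack$data)
  if (d[4] < window) stop("fewer frames than one window")
  nb <- d[4] %/% window
  imgs <- vector("list", nb)
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * window + 1L):(b * window)
    m <- stack$data[, , channel, idx[1]]
    for (i in idx[-1]) m <- pmax(m, stack$data[, , channel, i])
    imgs[[b]] <- m
  }
  structure(list(images = imgs,
                 timestamps = (seq_len(nb) - 1L) * window * stack$frame_interval,
                 window = as.integer(window), pixel_size = stack$pixel_size),
            class = "mip_series")
}

#' @export
print.mip_series <- function(x, ...) {
  cat(sprintf("mip_series: %d MIPs (window %d), %.3g um/px, t = %g..%g s\n",
              length(x$images), x$window, x$pixel_size,
              min(x$timestamps), max(x$timestamps)))
  invisible(x)
}

#' Full width at half maximum of an intensity profile
#'
#' Background is the profile minimum; the half-maximum level is
#' `background + (max - background) / 2`; the FWHM is the distance between
#' the half-maximum crossings on either side of the peak, located by linear
#' interpolation (`method = "interp"`, the default, assumption-free) or by a
#' least-squares Gaussian fit (`method = "gauss"`). The estimate is invariant
#' to intensity scaling and constant background offsets.
#'
#' @param position ordered sample positions (um).
#' @param intensity intensities at `position`.
#' @param method `"interp"` or `"gauss"`.
#' @return FWHM in um.
#' @export
compute_fwhm <- function(position, intensity, method = c("interp", "gauss")) {
  method <- match.arg(method)
  stopifnot(length(position) == length(intensity))
  if (length(position) < 5) stop("need at least 5 profile samples")
  if (is.unsorted(position, strictly = TRUE)) stop("positions must be strictly increasing")
  bg <- min(intensity)
  pk <- which.max(intensity)
  if (intensity[pk] <= bg) stop("profile has no peak above background")
  # peak height from a local quadratic fit (guarded by the raw maximum):
  # unbiased under sampling noise, and exact on plateaus where the fit is
  # rejected in favour of the raw maximum
  wpk <- max(2L, round(length(position) / 40))
  win <- max(1, pk - wpk):min(length(position), pk + wpk)
  peak_val <- intensity[pk]
  if (length(win) >= 3) {
    fit <- stats::lm.fit(cbind(1, position[win], position[win]^2),
                         intensity[win])
    cf <- fit$coefficients
    if (is.finite(cf[3]) && cf[3] < 0) {
      vtx <- cf[1] - cf[2]^2 / (4 * cf[3])
      if (is.finite(vtx) && vtx > bg) peak_val <- min(peak_val, vtx)
    }
  }
  half <- bg + (peak_val - bg) / 2
  if (method == "gauss") {
    amp0 <- intensity[pk] - bg
    mu0 <- position[pk]
    sig0 <- sum((intensity - bg) / sum(intensity - bg) * abs(position - mu0))
    obj <- function(p) sum((bg + p[1] * exp(-(position - p[2])^2 / (2 * p[3]^2)) -
                              intensity)^2)
    fit <- stats::optim(c(amp0, mu0, max(sig0, diff(range(position)) / 50)), obj)
    return(2 * sqrt(2 * log(2)) * abs(fit$par[3]))
  }
  cross <- function(vals, idx_range, rising) {
    v <- vals[idx_range]
    above <- v >= half
    ii <- if (rising) which(!above[-length(v)] & above[-1])
          else which(above[-length(v)] & !above[-1])
    if (!length(ii)) return(list(x = NA_real_, n = 0L))
    i <- idx_range[if (rising) max(ii) else min(ii)]
    # linear interpolation between samples i and i+1
    x0 <- position[i]; x1 <- position[i + 1]
    y0 <- vals[i]; y1 <- vals[i + 1]
    x <- if (y1 == y0) (x0 + x1) / 2 else x0 + (half - y0) / (y1 - y0) * (x1 - x0)
    list(x = x, n = length(ii))
  }
  both <- function(vals) {
    n <- length(position)
    list(left = if (pk > 1) cross(vals, 1:pk, TRUE) else list(x = NA_real_, n = 0L),
         right = if (pk < n) cross(vals, pk:n, FALSE) else list(x = NA_real_, n = 0L))
  }
  cr <- both(intensity)
  if (cr$left$n > 1 || cr$right$n > 1) {
    # noise produces multiple half-level crossings: take the crossings of a
    # lightly smoothed profile (anchored moving average; a clean profile has
    # one crossing per side and never reaches this branch)
    k <- length(intensity)
    wmax <- max(2L, round(k / 50))
    sm <- intensity
    for (i in seq_len(k)) {
      w <- min(i - 1L, k - i, wmax)
      sm[i] <- mean(intensity[(i - w):(i + w)])
    }
    cr2 <- both(sm)
    if (cr2$left$n >= 1 && cr2$right$n >= 1) cr <- cr2
  }
  if (is.na(cr$left$x) || is.na(cr$right$x))
    stop("no half-maximum crossing on both sides of the peak (monotone profile?)")
  cr$right$x - cr$left$x
}
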