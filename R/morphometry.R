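# Per-cell static morphometry on a single MIP image: cell density, soma area,
# territory area, primary process length, total process length.

#' Territory polygon and area from distal tip positions
#'
#' Tips are ordered by polar angle about the soma centroid (ties broken by
#' radius) to form a simple polygon whose area is computed by the shoelace
#' formula. Fewer than 3 tips, or collinear tips, give area 0 with a
#' degeneracy flag. The result is invariant to the input ordering of tips.
#'
#' @param tips matrix/data.frame of tip positions, columns x, y (um).
#' @param centroid length-2 soma centroid (x, y um).
#' @return list with `polygon` (ordered n x 2 matrix), `area` (um^2) and
#'   `degenerate` (logical).
#' @export
territory_area <- function(tips, centroid) {
  tips <- as.matrix(tips)[, 1:2, drop = FALSE]
  n <- nrow(tips)
  if (n < 3)
    return(list(polygon = tips, area = 0, degenerate = TRUE))
  ang <- atan2(tips[, 2] - centroid[2], tips[, 1] - centroid[1])
  rad <- sqrt((tips[, 1] - centroid[1])^2 + (tips[, 2] - centroid[2])^2)
  poly <- tips[order(ang, rad), , drop = FALSE]
  a <- shoelace_area(poly)
  span <- max(abs(c(diff(range(tips[, 1])), diff(range(tips[, 2])))), 1)
  if (a < 1e-9 * span^2)
    return(list(polygon = poly, area = 0, degenerate = TRUE))
  list(polygon = poly, area = a, degenerate = FALSE)
}

#' Morphometry configuration
#'
#' @param tolerance wand region-growing tolerance (fraction of
#'   peak-to-background range; 0.5 = half-maximum level set).
#' @param prune_um skeleton spur prune length (um).
#' @param min_soma_diameter_um minimum soma diameter for detection (um).
#' @param min_separation_um soma seeds closer than this are flagged ambiguous.
#' @param window_um half-width of the per-cell skeleton window (um).
#' @param process_threshold skeleton foreground cut as a fraction of the
#'   soma peak-to-background range.
#' @param tip_snap correct tip endpoint erosion (logical).
#' @return list of class `morph_config`.
#' @export
morph_config <- function(tolerance = 0.5, prune_um = 2,
                         min_soma_diameter_um = 4, min_separation_um = 8,
                         window_um = 40, process_threshold = 0.2,
                         tip_snap = TRUE) {
  structure(list(tolerance = tolerance, prune_um = prune_um,
                 min_soma_diameter_um = min_soma_diameter_um,
                 min_separation_um = min_separation_um,
                 window_um = window_um, process_threshold = process_threshold,
                 tip_snap = tip_snap),
            class = "morph_config")
}

#' Measure all cells on one MIP image
#'
#' Runs the static morphometry chain: soma detection, wand soma
#' segmentation, per-cell skeleton extraction, territory polygon. Cells
#' whose soma or arbor mask touches the field border are excluded from the
#' per-cell table but counted in `excluded`.
#'
#' @param mip numeric matrix.
#' @param pixel_size um per pixel.
#' @param config a [morph_config()].
#' @param border_px border width treated as invalid (registration fill).
#' @return An object of class `fov_morphometry`: list with `cells`
#'   (data.frame: cell, x, y, soma_area_um2, territory_area_um2,
#'   territory_degenerate, n_primary, primary_mean_um, total_length_um,
#'   n_tips), `tips` (data.frame: cell, tip, x, y), `skeletons` (list),
#'   `somas` (list), `n_detected`, `excluded`.
#' @export
measure_mip <- function(mip, pixel_size, config = morph_config(),
                        border_px = 0) {
  seeds <- detect_somata(mip, pixel_size,
                         min_diameter_um = config$min_soma_diameter_um,
                         min_separation_um = config$min_separation_um,
                         border_px = border_px)
  cells <- list(); tipsl <- list(); skels <- list(); somas <- list()
  excluded <- 0L
  if (nrow(seeds) > 0) {
    cents <- as.matrix(seeds[, c("x", "y")])
    for (i in seq_len(nrow(seeds))) {
      soma <- tryCatch(
        segment_soma(mip, c(seeds$row[i], seeds$col[i]), pixel_size,
                     tolerance = config$tolerance),
        error = function(e) NULL)
      if (is.null(soma)) next
      if (soma$touches_border) { excluded <- excluded + 1L; next }
      skel <- tryCatch(
        extract_skeleton(mip, soma, pixel_size,
                         window_um = config$window_um,
                         prune_um = config$prune_um,
                         other_centroids = cents[-i, , drop = FALSE],
                         process_threshold = config$process_threshold,
                         tip_snap = config$tip_snap),
        error = function(e) NULL)
      if (is.null(skel)) { excluded <- excluded + 1L; next }
      prim <- primary_process_lengths(skel)
      terr <- territory_area(skel$tips[, c("x", "y")], soma$centroid)
      k <- length(cells) + 1L
      cells[[k]] <- data.frame(
        cell = k, x = unname(soma$centroid["x"]), y = unname(soma$centroid["y"]),
        soma_area_um2 = soma$area,
        territory_area_um2 = terr$area,
        territory_degenerate = terr$degenerate,
        n_primary = length(prim),
        primary_mean_um = if (length(prim)) mean(prim) else NA_real_,
        total_length_um = total_process_length(skel),
        n_tips = nrow(skel$tips),
        ambiguous_seed = seeds$ambiguous[i])
      if (nrow(skel$tips) > 0)
        tipsl[[k]] <- data.frame(cell = k, tip = seq_len(nrow(skel$tips)),
                                 x = skel$tips$x, y = skel$tips$y)
      skels[[k]] <- skel
      somas[[k]] <- soma
    }
  }
  structure(list(
    cells = if (length(cells)) do.call(rbind, cells) else
      data.frame(cell = integer(0), x = numeric(0), y = numeric(0),
                 soma_area_um2 = numeric(0), territory_area_um2 = numeric(0),
                 territory_degenerate = logical(0), n_primary = integer(0),
                 primary_mean_um = numeric(0), total_length_um = numeric(0),
                 n_tips = integer(0), ambiguous_seed = logical(0)),
    tips = if (length(tipsl)) do.call(rbind, tipsl) else
      data.frame(cell = integer(0), tip = integer(0), x = numeric(0),
                 y = numeric(0)),
    skeletons = skels, somas = somas,
    n_detected = nrow(seeds), excluded = excluded),
    class = "fov_morphometry")
}

#' @export
print.fov_morphometry <- function(x, ...) {
  cat(sprintf("fov_morphometry: %d cells measured (%d detected, %d excluded)\n",
              nrow(x$cells), x$n_detected, x$excluded))
  invisible(x)
}

#' Cell density of a field of view
#'
#' Number of included (non-border) cells in the FOV.
#'
#' @param fov a `fov_morphometry` from [measure_mip()].
#' @return integer count.
#' @export
cell_density <- function(fov) {
  stopifnot(inherits(fov, "fov_morphometry"))
  nrow(fov$cells)
}

#' Measure a whole MIP series, linking cells across time points
#'
#' Each MIP is measured with [measure_mip()]; cells are linked across time to
#' the reference identities established at the first time point by nearest
#' soma centroid within `link_um` (somata are effectively static over 10
#' min). Unmatched detections found later start new identities.
#'
#' @param mips a `mip_series` from [build_mip_series()].
#' @param config a [morph_config()].
#' @param link_um cell-identity linking radius (um).
#' @param border_px border width excluded from detection.
#' @return list with `cells` (long data.frame: t, time_s, cell plus the
#'   per-cell columns of [measure_mip()]), `tips` (long data.frame: t,
#'   time_s, cell, tip, x, y), `timestamps`, `pixel_size`.
#' @export
measure_series <- function(mips, config = morph_config(), link_um = 6,
                           border_px = 0) {
  stopifnot(inherits(mips, "mip_series"))
  nt <- length(mips$images)
  ref <- NULL  # reference centroids: data.frame cell, x, y
  cells <- list(); tips <- list()
  for (t in seq_len(nt)) {
    m <- measure_mip(mips$images[[t]], mips$pixel_size, config, border_px)
    ct <- m$cells
    if (nrow(ct) == 0) next
    if (is.null(ref)) {
      ct$id <- seq_len(nrow(ct))
      ref <- data.frame(cell = ct$id, x = ct$x, y = ct$y)
    } else {
      ct$id <- NA_integer_
      if (nrow(ref) > 0) {
        d <- outer(seq_len(nrow(ct)), seq_len(nrow(ref)),
                   function(i, j) sqrt((ct$x[i] - ref$x[j])^2 +
                                         (ct$y[i] - ref$y[j])^2))
        # greedy nearest assignment under the gate (somata are static)
        repeat {
          k <- which.min(d)
          if (!length(k) || d[k] > link_um) break
          ij <- arrayInd(k, dim(d))
          ct$id[ij[1]] <- ref$cell[ij[2]]
          d[ij[1], ] <- Inf; d[, ij[2]] <- Inf
        }
      }
      new <- which(is.na(ct$id))
      if (length(new)) {
        nxt <- max(ref$cell, 0L) + seq_along(new)
        ct$id[new] <- nxt
        ref <- rbind(ref, data.frame(cell = nxt, x = ct$x[new], y = ct$y[new]))
      }
    }
    local_to_id <- ct$id[match(seq_len(nrow(ct)), ct$cell)]
    ctt <- ct
    ctt$cell <- ctt$id; ctt$id <- NULL
    ctt <- cbind(data.frame(t = t, time_s = mips$timestamps[t]), ctt)
    cells[[t]] <- ctt
    if (nrow(m$tips) > 0) {
      tp <- m$tips
      tp$cell <- local_to_id[tp$cell]
      tips[[t]] <- cbind(data.frame(t = t, time_s = mips$timestamps[t]), tp)
    }
  }
  list(cells = if (length(cells)) do.call(rbind, cells) else NULL,
       tips = if (length(tips)) do.call(rbind, tips) else NULL,
       timestamps = mips$timestamps, pixel_size = mips$pixel_size)
}
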