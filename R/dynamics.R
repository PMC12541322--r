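# Dynamic surveillance metrics: tip tracking across the MIP series, cumulative
# change sums, tip movement distance, surveillance territory area, and
# extension/retraction speeds, averaged per cell.

#' Link process tips across MIP time points (one cell)
#'
#' Tips at consecutive time points are matched by mutual nearest neighbour
#' under the gate; unmatched old tips terminate their tracks and unmatched
#' new tips start tracks. A track that misses detections may be bridged
#' across up to `max_gap` time points when the bridging displacement is
#' within `gate * gap`; otherwise it is split. Deterministic given the input
#' order.
#'
#' @param tip_sets list over time points of n x 2 matrices of tip positions
#'   (um); entries may have zero rows.
#' @param gate_um maximum per-interval displacement for a link (um).
#' @param max_gap maximum number of bridged missing time points.
#' @return data.frame with columns `track`, `t` (time index), `x`, `y`.
#' @export
link_tips <- function(tip_sets, gate_um = 10, max_gap = 2L) {
  nt <- length(tip_sets)
  tracks <- list()   # each: list(t = int vector, xy = matrix)
  open <- integer(0) # indices into tracks that may still be extended
  for (t in seq_len(nt)) {
    pts <- tip_sets[[t]]
    pts <- if (is.null(pts)) matrix(numeric(0), 0, 2) else
      as.matrix(pts)[, 1:2, drop = FALSE]
    # drop tracks whose last observation is too old
    if (length(open)) {
      last_t <- vapply(tracks[open], function(tr) tr$t[length(tr$t)], numeric(1))
      open <- open[t - last_t <= max_gap]
    }
    np <- nrow(pts)
    if (np == 0) next
    assigned <- rep(FALSE, np)
    if (length(open)) {
      heads <- t(vapply(tracks[open], function(tr) tr$xy[nrow(tr$xy), ],
                        numeric(2)))
      gaps <- t - vapply(tracks[open], function(tr) tr$t[length(tr$t)], numeric(1))
      d <- outer(seq_len(np), seq_along(open),
                 function(i, j) sqrt((pts[i, 1] - heads[j, 1])^2 +
                                       (pts[i, 2] - heads[j, 2])^2))
      gmat <- matrix(rep(gate_um * gaps, each = np), np)
      dok <- ifelse(d <= gmat, d, Inf)
      # mutual nearest neighbour links
      if (any(is.finite(dok))) {
        row_min <- apply(dok, 1, which.min)
        col_min <- apply(dok, 2, which.min)
        for (i in seq_len(np)) {
          j <- row_min[i]
          if (is.finite(dok[i, j]) && col_min[j] == i) {
            k <- open[j]
            tracks[[k]]$t <- c(tracks[[k]]$t, t)
            tracks[[k]]$xy <- rbind(tracks[[k]]$xy, pts[i, ])
            assigned[i] <- TRUE
          }
        }
        # matched tracks keep their open slot; unmatched stay open until gap
      }
    }
    for (i in which(!assigned)) {
      tracks[[length(tracks) + 1L]] <- list(t = t, xy = pts[i, , drop = FALSE])
      open <- c(open, length(tracks))
    }
    # refresh open set: any track extended this round remains open
    open <- unique(c(open, which(vapply(tracks, function(tr)
      tr$t[length(tr$t)] == t, logical(1)))))
  }
  if (!length(tracks))
    return(data.frame(track = integer(0), t = integer(0),
                      x = numeric(0), y = numeric(0)))
  do.call(rbind, lapply(seq_along(tracks), function(k)
    data.frame(track = k, t = tracks[[k]]$t,
               x = tracks[[k]]$xy[, 1], y = tracks[[k]]$xy[, 2])))
}

#' Cumulative absolute change of a scalar series
#'
#' `sum(|x[t+1] - x[t]|)` over consecutive valid (non-NA) time points — the
#' summation-of-changes statistic used for cell body size and territory area
#' over the observation period.
#'
#' @param x numeric series (NAs are skipped; change is measured between
#'   consecutive valid points).
#' @return the cumulative absolute change, or `NA` (with a warning) when
#'   fewer than 2 valid points exist.
#' @export
cumulative_abs_change <- function(x) {
  v <- x[!is.na(x)]
  if (length(v) < 2) {
    warning("fewer than 2 valid time points: cumulative change undefined")
    return(NA_real_)
  }
  sum(abs(diff(v)))
}

#' Cumulative movement distance of a tip track
#'
#' Sum of Euclidean displacements between consecutive valid positions.
#'
#' @param xy n x 2 matrix of track positions (um), in time order.
#' @return distance in um; `NA` with a warning for single-point tracks.
#' @export
tip_movement_distance <- function(xy) {
  xy <- as.matrix(xy)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 2) {
    warning("single-point track: movement distance undefined")
    return(NA_real_)
  }
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Surveillance territory area of a tip track
#'
#' Area of the convex hull of the track's positions — the region enclosed by
#' the trajectory of one process tip over the observation period. Invariant
#' to the temporal order of positions. Fewer than 3 distinct positions, or
#' collinear positions, give 0 with a degeneracy flag.
#'
#' @param xy n x 2 matrix of positions (um).
#' @return list with `area` (um^2), `hull` (vertex matrix) and `degenerate`.
#' @export
surveillance_area <- function(xy) {
  xy <- as.matrix(xy)
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 3)
    return(list(area = 0, hull = xy, degenerate = TRUE))
  h <- grDevices::chull(xy[, 1], xy[, 2])
  hull <- xy[h, , drop = FALSE]
  a <- shoelace_area(hull)
  span <- max(abs(c(diff(range(xy[, 1])), diff(range(xy[, 2])))), 1e-6)
  if (nrow(hull) < 3 || a < 1e-9 * span^2)
    return(list(area = 0, hull = hull, degenerate = TRUE))
  list(area = a, hull = hull, degenerate = FALSE)
}

#' Extension and retraction speeds of a tip track
#'
#' Per interval, the change in the tip's Euclidean distance to the (fixed)
#' soma centroid classifies the move: `dr > epsilon` is extension,
#' `dr < -epsilon` retraction, in between is stationary. Speeds are the mean
#' `|dr| / dt` within each class, in um/min; a class with no intervals is
#' `NA`.
#'
#' @param xy n x 2 matrix of valid track positions (um), in time order.
#' @param times_s observation times (s) of the rows of `xy`.
#' @param centroid length-2 soma centroid (x, y um).
#' @param epsilon_um stationary band half-width per interval (um).
#' @return list with `extension`, `retraction` (um/min), and interval counts
#'   `n_extension`, `n_retraction`.
#' @export
extension_retraction_speeds <- function(xy, times_s, centroid,
                                        epsilon_um = 0.2) {
  xy <- as.matrix(xy)
  ok <- stats::complete.cases(xy)
  xy <- xy[ok, , drop = FALSE]
  times_s <- times_s[ok]
  if (nrow(xy) < 2)
    return(list(extension = NA_real_, retraction = NA_real_,
                n_extension = 0L, n_retraction = 0L))
  r <- sqrt((xy[, 1] - centroid[1])^2 + (xy[, 2] - centroid[2])^2)
  dr <- diff(r)
  dt <- diff(times_s)
  ext <- dr > epsilon_um
  ret <- dr < -epsilon_um
  list(extension = if (any(ext)) mean(dr[ext] / dt[ext]) * 60 else NA_real_,
       retraction = if (any(ret)) mean(-dr[ret] / dt[ret]) * 60 else NA_real_,
       n_extension = sum(ext), n_retraction = sum(ret))
}

#' Summarise the dynamics of one cell
#'
#' Per-tip metrics (movement distance, surveillance area, speeds) are
#' averaged over the cell's accepted tracks into one representative value per
#' cell; scalar-series metrics (soma area, territory area) are reduced to
#' their cumulative absolute change. Tracks spanning less than
#' `min_track_fraction` of the time points are excluded from the averages
#' (but counted).
#'
#' @param tracks data.frame from [link_tips()] (columns track, t, x, y).
#' @param soma_series numeric soma-area series (um^2) on the MIP time base.
#' @param territory_series numeric territory-area series (um^2).
#' @param times_s MIP timestamps (s).
#' @param centroid soma centroid (x, y um) for radial speeds.
#' @param epsilon_um stationary band for speed classification.
#' @param min_track_fraction minimum fraction of time points a track must
#'   span to enter the averages.
#' @return one-row data.frame of class `cell_dynamics`.
#' @export
summarize_cell <- function(tracks, soma_series, territory_series, times_s,
                           centroid, epsilon_um = 0.2,
                           min_track_fraction = 0.5) {
  nt <- length(times_s)
  n_tracks <- if (nrow(tracks)) length(unique(tracks$track)) else 0L
  per_tip <- NULL
  if (n_tracks > 0) {
    per_tip <- do.call(rbind, lapply(split(tracks, tracks$track), function(tr) {
      span <- nrow(tr)
      xy <- cbind(tr$x, tr$y)
      sp <- extension_retraction_speeds(xy, times_s[tr$t], centroid, epsilon_um)
      data.frame(span = span,
                 distance = if (span >= 2)
                   suppressWarnings(tip_movement_distance(xy)) else NA_real_,
                 area = surveillance_area(xy)$area,
                 extension = sp$extension, retraction = sp$retraction)
    }))
    per_tip <- per_tip[per_tip$span >= min_track_fraction * nt, , drop = FALSE]
  }
  nacc <- if (is.null(per_tip)) 0L else nrow(per_tip)
  mean_ <- function(v) if (nacc > 0 && any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_
  out <- data.frame(
    soma_change_um2 = suppressWarnings(cumulative_abs_change(soma_series)),
    territory_change_um2 = suppressWarnings(cumulative_abs_change(territory_series)),
    tip_distance_um = mean_(per_tip$distance),
    surveillance_um2 = mean_(per_tip$area),
    extension_um_min = mean_(per_tip$extension),
    retraction_um_min = mean_(per_tip$retraction),
    n_tracks = n_tracks, n_tracks_used = nacc,
    span_s = if (nt >= 2) diff(range(times_s)) else 0,
    incomplete = nacc == 0L)
  class(out) <- c("cell_dynamics", class(out))
  out
}

#' Per-cell dynamics table for a measured MIP series
#'
#' Applies [link_tips()] and [summarize_cell()] to every cell of a
#' [measure_series()] result. Cells must appear in at least
#' `min_cell_fraction` of the time points to be summarised.
#'
#' @param meas result of [measure_series()].
#' @param gate_um tip linking gate per MIP interval (um).
#' @param epsilon_um stationary band for radial speeds (um).
#' @param min_track_fraction minimum track span fraction.
#' @param min_cell_fraction minimum fraction of time points a cell must be
#'   detected in.
#' @param max_gap maximum bridged detection gap (time points).
#' @return data.frame, one row per cell: static references plus the
#'   [summarize_cell()] columns.
#' @export
cell_dynamics_table <- function(meas, gate_um = 10, epsilon_um = 0.2,
                                min_track_fraction = 0.5,
                                min_cell_fraction = 0.5, max_gap = 2L) {
  if (is.null(meas$cells) || nrow(meas$cells) == 0) return(NULL)
  nt <- length(meas$timestamps)
  out <- list()
  for (id in sort(unique(meas$cells$cell))) {
    rows <- meas$cells[meas$cells$cell == id, ]
    if (nrow(rows) < min_cell_fraction * nt) next
    centroid <- c(stats::median(rows$x), stats::median(rows$y))
    soma_series <- territory_series <- rep(NA_real_, nt)
    soma_series[rows$t] <- rows$soma_area_um2
    territory_series[rows$t] <- rows$territory_area_um2
    tip_sets <- vector("list", nt)
    if (!is.null(meas$tips)) {
      tp <- meas$tips[meas$tips$cell == id, ]
      for (t in unique(tp$t))
        tip_sets[[t]] <- as.matrix(tp[tp$t == t, c("x", "y")])
    }
    tracks <- link_tips(tip_sets, gate_um = gate_um, max_gap = max_gap)
    dyn <- summarize_cell(tracks, soma_series, territory_series,
                          meas$timestamps, centroid,
                          epsilon_um = epsilon_um,
                          min_track_fraction = min_track_fraction)
    out[[length(out) + 1L]] <- cbind(
      data.frame(cell = id, x = centroid[1], y = centroid[2],
                 n_observed = nrow(rows)), dyn)
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
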