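# Serialisation of simulation ground truth: tabular CSV series plus a
# structured YAML header (seed, preset, acquisition spec, noise model).

#' Write simulation ground truth to a directory
#'
#' Writes `header.yaml` (seed, preset, spec, noise), `shifts.csv`,
#' `cells.csv`, `soma_area.csv` (long: frame, cell, area_um2) and `tips.csv`
#' (long: frame, cell, tip, x_um, y_um). The representation round-trips
#' through [read_truth()] to numerical identity (within text precision).
#'
#' @param truth a `sim_truth` from [generate_fov_series()].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create truth directory: ", path)
  hdr <- list(
    seed = truth$seed, n_cells = truth$n_cells,
    preset = unclass(truth$preset),
    spec = unclass(truth$spec),
    noise = unclass(truth$noise))
  yaml::write_yaml(hdr, file.path(path, "header.yaml"), precision = 15)
  fwrite_ <- function(d, f) data.table::fwrite(d, file.path(path, f))
  fwrite_(truth$shifts, "shifts.csv")
  fwrite_(truth$cells, "cells.csv")
  nf <- nrow(truth$shifts)
  sa <- if (truth$n_cells > 0)
    data.frame(frame = rep(seq_len(nf), truth$n_cells),
               cell = rep(seq_len(truth$n_cells), each = nf),
               area_um2 = as.vector(truth$soma_area))
    else data.frame(frame = integer(0), cell = integer(0), area_um2 = numeric(0))
  fwrite_(sa, "soma_area.csv")
  ntt <- nrow(truth$tip_map)
  tp <- if (ntt > 0)
    data.frame(frame = rep(seq_len(nf), ntt),
               cell = rep(truth$tip_map$cell, each = nf),
               tip = rep(truth$tip_map$tip, each = nf),
               x_um = as.vector(truth$tip_x), y_um = as.vector(truth$tip_y))
    else data.frame(frame = integer(0), cell = integer(0), tip = integer(0),
                    x_um = numeric(0), y_um = numeric(0))
  fwrite_(tp, "tips.csv")
  invisible(path)
}

#' Read simulation ground truth written by [write_truth()]
#'
#' @param path directory containing the truth files.
#' @return a `sim_truth`.
#' @export
read_truth <- function(path) {
  hdr <- yaml::read_yaml(file.path(path, "header.yaml"))
  spec <- do.call(acquisition_spec, hdr$spec[c("frame_shape", "pixel_size",
                                               "frame_interval", "duration",
                                               "n_channels")])
  preset <- do.call(condition_preset,
                    c(list(name = hdr$preset$name),
                      hdr$preset[setdiff(names(hdr$preset), "name")]))
  noise <- do.call(noise_model, hdr$noise)
  fread_ <- function(f) as.data.frame(data.table::fread(file.path(path, f)))
  shifts <- fread_("shifts.csv")
  cells <- fread_("cells.csv")
  sa <- fread_("soma_area.csv")
  tp <- fread_("tips.csv")
  nf <- nrow(shifts)
  n_cells <- hdr$n_cells
  soma_area <- matrix(0, nf, n_cells)
  if (n_cells > 0) soma_area[cbind(sa$frame, sa$cell)] <- sa$area_um2
  if (nrow(tp) > 0) {
    tm <- unique(tp[, c("cell", "tip")])
    tm <- tm[order(tm$cell, tm$tip), ]
    rownames(tm) <- NULL
    key <- paste(tp$cell, tp$tip)
    col <- match(key, paste(tm$cell, tm$tip))
    tip_x <- matrix(0, nf, nrow(tm)); tip_y <- matrix(0, nf, nrow(tm))
    tip_x[cbind(tp$frame, col)] <- tp$x_um
    tip_y[cbind(tp$frame, col)] <- tp$y_um
  } else {
    tm <- data.frame(cell = integer(0), tip = integer(0))
    tip_x <- matrix(0, nf, 0); tip_y <- matrix(0, nf, 0)
  }
  structure(list(spec = spec, preset = preset, noise = noise, seed = hdr$seed,
                 n_cells = n_cells, shifts = shifts, cells = cells,
                 soma_area = soma_area, tip_map = tm,
                 tip_x = tip_x, tip_y = tip_y),
            class = "sim_truth")
}
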