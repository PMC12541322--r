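# Formats, configuration and orchestration: TIFF stack IO with explicit
# calibration, the register -> MIP -> morphometry -> dynamics chain, and
# multi-arm simulation studies with group statistics.

#' Write a two-channel stack as a multi-page 16-bit TIFF with a calibration sidecar
#'
#' Pages are time-major and channel-interleaved (page = 2 (t - 1) + channel).
#' Calibration (pixel size, frame interval, page order) is written to a YAML
#' sidecar `<path>.yaml` so the file round-trips through [read_stack()]
#' without guessing physical units.
#'
#' @param stack a `fov_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fov_stack"))
  d <- dim(stack$data)
  pages <- vector("list", d[3] * d[4])
  for (f in seq_len(d[4])) for (ch in seq_len(d[3]))
    pages[[(f - 1L) * d[3] + ch]] <-
      pmin(pmax(stack$data[, , ch, f], 0), 65535) / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(pixel_size = stack$pixel_size,
                        frame_interval = stack$frame_interval,
                        n_channels = d[3], n_frames = d[4],
                        page_order = "time_major"),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a two-channel time-lapse stack from a multi-page TIFF
#'
#' Calibration is taken from the `<path>.yaml` sidecar written by
#' [write_stack()]; without a sidecar, `pixel_size` and `frame_interval`
#' must be supplied (physical units are never guessed). `page_order`
#' declares how pages map to (frame, channel): `"time_major"`
#' (channel-interleaved, the default) or `"channel_major"` (all frames of
#' channel 1, then channel 2).
#'
#' @param path TIFF path.
#' @param pixel_size,frame_interval calibration overrides (um/px, s).
#' @param page_order `NULL` (sidecar or default), "time_major" or
#'   "channel_major".
#' @return a `fov_stack` with integer-valued data in counts.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       page_order = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot parse TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  np <- length(pages)
  if (np %% 2L != 0L)
    stop("expected an even number of pages (2 channels); got page count ", np)
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
  pixel_size <- pixel_size %||% meta$pixel_size
  frame_interval <- frame_interval %||% meta$frame_interval
  page_order <- page_order %||% meta$page_order %||% "time_major"
  if (is.null(pixel_size) || is.null(frame_interval))
    stop("missing calibration: supply pixel_size and frame_interval ",
         "or provide the '", basename(side), "' sidecar")
  page_order <- match.arg(page_order, c("time_major", "channel_major"))
  nf <- np %/% 2L
  d1 <- dim(pages[[1]])
  data <- array(0, dim = c(d1[1], d1[2], 2L, nf))
  for (f in seq_len(nf)) for (ch in 1:2) {
    pg <- if (page_order == "time_major") (f - 1L) * 2L + ch
          else (ch - 1L) * nf + f
    m <- pages[[pg]]
    if (!all(dim(m) == d1))
      stop("page ", pg, " has dimensions ", paste(dim(m), collapse = "x"),
           ", expected ", paste(d1, collapse = "x"))
    data[, , ch, f] <- m
  }
  fov_stack(data, pixel_size = pixel_size, frame_interval = frame_interval)
}

#' Pipeline configuration
#'
#' Collects every tunable of the chain in one serialisable object; unknown
#' keys are rejected. Defaults reproduce the standard protocol: 5-frame MIP
#' windows, 10-um linking gate per 20-s interval, 0.2-um stationary band.
#'
#' @param simulate list: preset, n_cells, seed (omit to read `input` instead).
#' @param input list: path (TIFF with sidecar) — used when `simulate` is NULL.
#' @param spec an [acquisition_spec()].
#' @param noise a [noise_model()].
#' @param window MIP/averaging window (frames).
#' @param max_shift registration search radius (px).
#' @param morphometry a [morph_config()].
#' @param gate_um,epsilon_um,min_track_fraction,min_cell_fraction,max_gap
#'   dynamics parameters (see [cell_dynamics_table()]).
#' @param alpha significance level for reports.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL,
                            spec = acquisition_spec(), noise = noise_model(),
                            window = 5L, max_shift = 20,
                            morphometry = morph_config(),
                            gate_um = 10, epsilon_um = 0.2,
                            min_track_fraction = 0.5,
                            min_cell_fraction = 0.5, max_gap = 2L,
                            alpha = 0.05) {
  if (!is.null(simulate)) {
    bad <- setdiff(names(simulate), c("preset", "n_cells", "seed"))
    if (length(bad)) stop("unknown simulate keys: ", paste(bad, collapse = ", "))
  }
  if (!is.null(input)) {
    bad <- setdiff(names(input), c("path", "pixel_size", "frame_interval",
                                   "page_order"))
    if (length(bad)) stop("unknown input keys: ", paste(bad, collapse = ", "))
  }
  structure(list(simulate = simulate, input = input, spec = spec,
                 noise = noise, window = as.integer(window),
                 max_shift = max_shift, morphometry = morphometry,
                 gate_um = gate_um, epsilon_um = epsilon_um,
                 min_track_fraction = min_track_fraction,
                 min_cell_fraction = min_cell_fraction,
                 max_gap = as.integer(max_gap), alpha = alpha),
            class = "pipeline_config")
}

#' Run the analysis chain on one registered-or-raw stack
#'
#' register -> MIP series -> per-MIP morphometry -> per-cell dynamics.
#' Static morphology (soma area, territory, process lengths) is taken at the
#' first MIP time point, matching single-time-point morphometry; dynamics
#' summarise the whole series.
#'
#' @param stack a `fov_stack`.
#' @param config a [pipeline_config()] (its `simulate`/`input` are ignored).
#' @return list with `shifts`, `mips`, `measurements`, `dynamics` and
#'   `cells` (the merged per-cell table).
#' @export
analyze_stack <- function(stack, config = pipeline_config()) {
  reg <- register_series(stack, max_shift = config$max_shift)
  border <- attr(reg$stack, "border_px") %||% 0
  mips <- build_mip_series(reg$stack, window = config$window)
  meas <- measure_series(mips, config$morphometry, border_px = border + 1L)
  dyn <- cell_dynamics_table(meas, gate_um = config$gate_um,
                             epsilon_um = config$epsilon_um,
                             min_track_fraction = config$min_track_fraction,
                             min_cell_fraction = config$min_cell_fraction,
                             max_gap = config$max_gap)
  cells <- NULL
  if (!is.null(meas$cells) && !is.null(dyn)) {
    static <- meas$cells[meas$cells$t == 1L,
                         c("cell", "soma_area_um2", "territory_area_um2",
                           "primary_mean_um", "total_length_um", "n_tips")]
    cells <- merge(static, dyn[, setdiff(names(dyn), c("x", "y"))], by = "cell")
  }
  list(shifts = reg$shifts, mips = mips, measurements = meas,
       dynamics = dyn, cells = cells)
}

#' Run the full pipeline and write stage outputs
#'
#' Simulates (or reads) the stack, runs [analyze_stack()], and writes plain
#' inspectable intermediates to `out`: resolved `config.yaml`, `shifts.csv`,
#' per-time-point `morphometry.csv`, `cells.csv`, and a `manifest.yaml` with
#' row counts, warning counts and the config hash. Reruns with an identical
#' config produce identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out output directory.
#' @return `out`, invisibly.
#' @export
run_pipeline <- function(config, out) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- generate_fov_series(config$spec,
                               condition_preset(config$simulate$preset),
                               config$noise, config$simulate$n_cells,
                               config$simulate$seed)
    stack <- sim$stack; truth <- sim$truth
  } else if (!is.null(config$input)) {
    stack <- do.call(read_stack, config$input)
  } else stop("config must specify either simulate or input")
  res <- analyze_stack(stack, config)
  fw <- function(d, f) data.table::fwrite(d, file.path(out, f))
  fw(res$shifts, "shifts.csv")
  if (!is.null(res$measurements$cells)) fw(res$measurements$cells, "morphometry.csv")
  if (!is.null(res$measurements$tips)) fw(res$measurements$tips, "tips.csv")
  if (!is.null(res$cells)) fw(res$cells, "cells.csv")
  if (!is.null(truth)) write_truth(truth, file.path(out, "truth"))
  cfg_path <- file.path(out, "config.yaml")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), cfg_path)
  manifest <- list(
    tool = paste0("microsurv ", as.character(utils::packageVersion("microsurv"))),
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_frames = dim(stack$data)[4],
    n_mips = length(res$mips$images),
    n_cell_rows = if (is.null(res$measurements$cells)) 0L else nrow(res$measurements$cells),
    n_cells = if (is.null(res$cells)) 0L else nrow(res$cells),
    n_degenerate_territories = if (is.null(res$measurements$cells)) 0L else
      sum(res$measurements$cells$territory_degenerate),
    max_registration_shift_px = max(abs(c(res$shifts$dx, res$shifts$dy))))
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(out)
}

#' Simulate and analyse one study arm
#'
#' @param preset preset name or [condition_preset()].
#' @param n_cells cells per field.
#' @param seed integer seed.
#' @param spec,noise acquisition and noise models.
#' @param config a [pipeline_config()] for the analysis stages.
#' @return list with `cells` (per-cell metric table with `condition` and
#'   `seed` columns), `truth`, and the [analyze_stack()] result.
#' @export
run_arm <- function(preset, n_cells, seed, spec = study_spec(),
                    noise = noise_model(), config = pipeline_config()) {
  if (is.character(preset)) preset <- condition_preset(preset)
  sim <- generate_fov_series(spec, preset, noise, n_cells, seed)
  res <- analyze_stack(sim$stack, config)
  cells <- res$cells
  if (!is.null(cells)) {
    cells <- cbind(data.frame(condition = preset$name, seed = seed), cells)
  }
  list(cells = cells, truth = sim$truth, result = res)
}

#' Acquisition spec used for simulation studies
#'
#' A 384 x 384 um field at 1 um/pixel holds 40 non-overlapping cells per arm;
#' cadence matches the in vivo protocol (4 s/frame, 10 min).
#'
#' @param side field side in pixels.
#' @param duration session length (s).
#' @return an [acquisition_spec()].
#' @export
study_spec <- function(side = 384L, duration = 600) {
  acquisition_spec(frame_shape = c(side, side), pixel_size = 1.0,
                   frame_interval = 4, duration = duration)
}

#' Run a multi-arm, multi-seed simulation study
#'
#' For every condition and seed, simulates an independent field of `n_cells`
#' cells and runs the full chain, returning the pooled per-cell metric
#' table. Arm seeds are `base_seed + 1000 * (arm - 1) + replicate`.
#'
#' @param conditions character vector of preset names.
#' @param n_cells cells per arm.
#' @param n_seeds replicates per condition.
#' @param base_seed integer.
#' @param spec,noise,config shared models and analysis configuration.
#' @param progress print per-arm progress.
#' @return data.frame of per-cell metrics across all arms and seeds.
#' @export
run_study <- function(conditions = c("control", "diabetic"), n_cells = 40,
                      n_seeds = 5, base_seed = 1, spec = study_spec(),
                      noise = noise_model(), config = pipeline_config(),
                      progress = FALSE) {
  out <- list()
  for (ai in seq_along(conditions)) for (si in seq_len(n_seeds)) {
    seed <- base_seed + 1000L * (ai - 1L) + si
    if (progress)
      message(sprintf("arm %s replicate %d (seed %d)", conditions[ai], si, seed))
    arm <- run_arm(conditions[ai], n_cells, seed, spec, noise, config)
    arm$cells$replicate <- si
    out[[length(out) + 1L]] <- arm$cells
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-replicate two-group comparisons of a study metric table
#'
#' For each metric and replicate, compares the two conditions with Welch's
#' t test (the protocol's two-group parametric test) and records the
#' direction of the difference.
#'
#' @param cells data.frame from [run_study()].
#' @param metrics metric column names to compare.
#' @param groups length-2 character: conditions to compare (b vs a).
#' @return data.frame: metric, replicate, mean_a, mean_b, p_value, higher.
#' @export
study_comparisons <- function(cells,
                              metrics = c("soma_area_um2", "territory_area_um2",
                                          "total_length_um",
                                          "territory_change_um2",
                                          "tip_distance_um", "surveillance_um2",
                                          "retraction_um_min"),
                              groups = c("control", "diabetic")) {
  out <- list()
  for (m in metrics) for (r in sort(unique(cells$replicate))) {
    a <- cells[cells$condition == groups[1] & cells$replicate == r, m]
    b <- cells[cells$condition == groups[2] & cells$replicate == r, m]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3 || length(b) < 3) next
    cmp <- compare_two_groups(a, b, route = "parametric", labels = groups)
    out[[length(out) + 1L]] <- data.frame(
      metric = m, replicate = r,
      mean_a = mean(a), mean_b = mean(b), p_value = cmp$p_value,
      higher = groups[if (mean(b) > mean(a)) 2 else 1])
  }
  do.call(rbind, out)
}
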