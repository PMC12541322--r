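# Acquisition geometry, condition presets and the noise model for the
# synthetic two-channel time-lapse generator.

#' Acquisition specification for a two-channel time-lapse recording
#'
#' Describes the imaging geometry and cadence the simulator emulates: square
#' frames scanned at a fixed interval over a fixed session length, with two
#' channels (channel 1 = blood vessels, channel 2 = microglia). The in vivo
#' target is a 1,024 x 1,024-pixel field scanned once every 4 s (0.25 Hz) for
#' 10 min; the default here is a desk-scale 256 x 256 field at 1 um/pixel with
#' the same cadence.
#'
#' @param frame_shape integer length-2, frame size in pixels (rows, cols).
#' @param pixel_size um per pixel (> 0).
#' @param frame_interval seconds between frames (> 0).
#' @param duration session length in seconds; must be an integer multiple of
#'   `frame_interval`.
#' @param n_channels number of channels; fixed at 2.
#' @return An object of class `acquisition_spec`.
#' @examples
#' spec <- acquisition_spec(duration = 600, frame_interval = 4)
#' n_frames(spec)  # 150
#' @export
acquisition_spec <- function(frame_shape = c(256L, 256L), pixel_size = 1.0,
                             frame_interval = 4, duration = 600, n_channels = 2L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 16))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (n_channels != 2L) stop("n_channels is fixed at 2 (1 = vessels, 2 = microglia)")
  k <- duration / frame_interval
  if (abs(k - round(k)) > 1e-9)
    stop("duration must be an integer multiple of frame_interval")
  structure(list(frame_shape = as.integer(frame_shape), pixel_size = pixel_size,
                 frame_interval = frame_interval, duration = duration,
                 n_channels = 2L),
            class = "acquisition_spec")
}

#' Number of frames implied by an acquisition spec
#' @param spec an `acquisition_spec`.
#' @return integer frame count (duration / frame_interval).
#' @export
n_frames <- function(spec) as.integer(round(spec$duration / spec$frame_interval))

#' Condition presets for the microglial morphodynamics generator
#'
#' Each preset parameterises the stochastic cell model: soma size, number and
#' length of primary processes, territory radius, and the tip random-walk
#' (per-frame step sd, radial extension bias, retraction gain, soma area
#' pulsation). The four presets encode the orderings reported in vivo:
#' relative to control, the diabetic phenotype has a larger soma, shorter
#' processes and territory, larger tip steps and a higher retraction gain;
#' the liraglutide-treated diabetic phenotype retains diabetic morphology but
#' motility at or below control; LPS-driven inflammation moves motility to
#' diabetic-like levels. Absolute magnitudes are model configuration, not
#' measured claims.
#'
#' @param name one of `"control"`, `"diabetic"`, `"liraglutide"`, `"lps"`.
#' @param ... named overrides of individual preset fields.
#' @return An object of class `condition_preset`.
#' @examples
#' condition_preset("diabetic")$tip_step_sd > condition_preset("control")$tip_step_sd
#' @export
condition_preset <- function(name = c("control", "diabetic", "liraglutide", "lps"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    control = list(soma_radius_mean = 3.0, soma_radius_sd = 0.30,
                   n_primary_min = 4L, n_primary_max = 6L,
                   process_length_mean = 16, territory_scale = 20,
                   tip_step_sd = 0.35, extension_bias = 0,
                   retraction_speed_gain = 1.0, soma_pulsation_amp = 1.0),
    diabetic = list(soma_radius_mean = 3.9, soma_radius_sd = 0.35,
                    n_primary_min = 3L, n_primary_max = 5L,
                    process_length_mean = 11, territory_scale = 14,
                    tip_step_sd = 1.00, extension_bias = 0,
                    retraction_speed_gain = 1.6, soma_pulsation_amp = 1.2),
    liraglutide = list(soma_radius_mean = 3.8, soma_radius_sd = 0.35,
                       n_primary_min = 3L, n_primary_max = 5L,
                       process_length_mean = 12, territory_scale = 15,
                       tip_step_sd = 0.30, extension_bias = 0,
                       retraction_speed_gain = 1.0, soma_pulsation_amp = 1.0),
    lps = list(soma_radius_mean = 3.5, soma_radius_sd = 0.35,
               n_primary_min = 3L, n_primary_max = 5L,
               process_length_mean = 13, territory_scale = 16,
               tip_step_sd = 0.95, extension_bias = 0,
               retraction_speed_gain = 1.5, soma_pulsation_amp = 1.1))
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown preset fields: ", paste(bad, collapse = ", "))
  base[names(over)] <- over
  p <- c(list(name = name), base)
  scales <- c("soma_radius_mean", "soma_radius_sd", "process_length_mean",
              "territory_scale", "tip_step_sd")
  if (any(unlist(p[scales]) < 0)) stop("preset scale parameters must be >= 0")
  if (p$extension_bias < -1 || p$extension_bias > 1)
    stop("extension_bias must lie in [-1, 1]")
  if (p$retraction_speed_gain < 0) stop("retraction_speed_gain must be >= 0")
  structure(p, class = "condition_preset")
}

#' Photon/read noise and motion-artifact model
#'
#' Counts are generated as `rpois(photon_gain * signal) + background_offset +
#' N(0, read_noise_sd)`, rounded and clamped to the 16-bit range, so a
#' signal-free region has mean `background_offset` and variance
#' `read_noise_sd^2`, and a uniform-signal region has variance
#' `photon_gain * signal + read_noise_sd^2` (in counts). `motion_amplitude`
#' is the per-axis sd (pixels) of the lateral rigid motion artifact injected
#' identically into both channels.
#'
#' @param photon_gain counts per intensity unit (>= 0).
#' @param read_noise_sd Gaussian read noise sd, counts (>= 0).
#' @param background_offset detector baseline, counts (>= 0).
#' @param motion_amplitude per-frame translation sd, pixels (>= 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(photon_gain = 1, read_noise_sd = 8,
                        background_offset = 100, motion_amplitude = 2) {
  vals <- c(photon_gain, read_noise_sd, background_offset, motion_amplitude)
  if (any(vals < 0)) stop("all noise model parameters must be non-negative")
  structure(list(photon_gain = photon_gain, read_noise_sd = read_noise_sd,
                 background_offset = background_offset,
                 motion_amplitude = motion_amplitude),
            class = "noise_model")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("acquisition_spec: %d x %d px @ %.3g um/px, %g s/frame, %g s (%d frames), %d channels\n",
              x$frame_shape[1], x$frame_shape[2], x$pixel_size, x$frame_interval,
              x$duration, n_frames(x), x$n_channels))
  invisible(x)
}

#' @export
print.condition_preset <- function(x, ...) {
  cat(sprintf("condition_preset '%s': soma %.2g um, %d-%d processes of ~%g um, territory %g um,\n  tip step sd %g um/frame, retraction gain %g\n",
              x$name, x$soma_radius_mean, x$n_primary_min, x$n_primary_max,
              x$process_length_mean, x$territory_scale, x$tip_step_sd,
              x$retraction_speed_gain))
  invisible(x)
}
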