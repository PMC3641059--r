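# Synthetic FRAP traces and rendered bleach-recovery stacks.

#' Configuration for a synthetic FRAP experiment
#'
#' Generative model for the bleached anchor-site spot: before the bleach
#' frame the spot sits at its plateau; at the bleach a fraction
#' `bleach_depth` of the spot fluorescence is destroyed; afterwards only
#' the mobile part of the bleached signal recovers, by prey exchange at
#' rate `k_off`:
#' \deqn{I(t) = B(t) [\, (1 - d) + d\, m (1 - e^{-k_{off} (t - t_b)}) \,]}
#' relative to the plateau, with mobile fraction
#' `m = 1 - immobile_fraction`, bleach depth `d`, and the whole-field
#' acquisition-bleaching envelope `B(t) = exp(-acquisition_bleach_rate t)`.
#' Gaussian read noise is added to all reported traces.
#'
#' The defaults frame a 7.5-minute observation window (the span over which
#' a stable complex shows only minor exchange) at 1.5 s per frame.
#'
#' @param k_off prey exchange (dissociation) rate at the anchor site, 1/s.
#' @param immobile_fraction fraction of the spot signal that never
#'   exchanges, in `[0, 1]`.
#' @param bleach_depth fraction of spot intensity removed at the bleach.
#' @param acquisition_bleach_rate whole-field bleaching rate, 1/s.
#' @param frame_interval seconds between frames.
#' @param n_frames total frames; must exceed `bleach_frame`.
#' @param bleach_frame index (1-based) of the last pre-bleach frame; the
#'   bleach happens between it and the next frame.
#' @param spot_amplitude spot plateau intensity above background, ADU.
#' @param field_amplitude whole-field intensity above background, ADU.
#' @param background_level camera background, ADU.
#' @param noise_sd Gaussian noise on each reported sample, ADU.
#' @param seed integer RNG seed.
#' @return A `frap_sim_config` list.
#' @export
frap_sim_config <- function(k_off = 0.02, immobile_fraction = 0,
                            bleach_depth = 0.9,
                            acquisition_bleach_rate = 0.002,
                            frame_interval = 1.5, n_frames = 310,
                            bleach_frame = 10,
                            spot_amplitude = 200, field_amplitude = 120,
                            background_level = 50, noise_sd = 2,
                            seed = 1L) {
  check_scalar(k_off, "k_off", lower = 0)
  check_scalar(immobile_fraction, "immobile_fraction", lower = 0, upper = 1)
  check_scalar(bleach_depth, "bleach_depth", lower = 0, upper = 1)
  check_scalar(acquisition_bleach_rate, "acquisition_bleach_rate", lower = 0)
  check_scalar(frame_interval, "frame_interval", lower = 1e-9)
  check_scalar(n_frames, "n_frames", lower = 2, integer = TRUE)
  check_scalar(bleach_frame, "bleach_frame", lower = 1, integer = TRUE)
  stop_if(bleach_frame >= n_frames,
          "'n_frames' must exceed 'bleach_frame' (need post-bleach frames)")
  check_scalar(spot_amplitude, "spot_amplitude", lower = 0)
  check_scalar(field_amplitude, "field_amplitude", lower = 0)
  check_scalar(background_level, "background_level", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(k_off = k_off, immobile_fraction = immobile_fraction,
                 bleach_depth = bleach_depth,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 frame_interval = frame_interval, n_frames = n_frames,
                 bleach_frame = bleach_frame,
                 spot_amplitude = spot_amplitude,
                 field_amplitude = field_amplitude,
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "frap_sim_config")
}

# Noise-free relative spot recovery (fraction of plateau) at times t.
# The bleach lands exactly at the first post-bleach frame
# (t_bleach = bleach_frame * frame_interval), so that frame reads 1 - d and
# recovery time is measured from it.
frap_recovery_profile <- function(config, times) {
  t_bleach <- config$bleach_frame * config$frame_interval
  d <- config$bleach_depth
  m <- 1 - config$immobile_fraction
  rec <- ifelse(times < t_bleach, 1,
                (1 - d) + d * m * (1 - exp(-config$k_off * (times - t_bleach))))
  rec * exp(-config$acquisition_bleach_rate * times)
}

#' Simulate a FRAP bleach-recovery trace
#'
#' Returns the raw (uncorrected) traces an experiment would yield: the spot
#' intensity, a cell-free background trace, and the whole-field trace used
#' for acquisition-bleaching correction.
#'
#' @param config a [frap_sim_config()].
#' @return A `frap_trace`: list with `times` (s), `spot_intensity`,
#'   `background_intensity`, `whole_field_intensity` (ADU), and
#'   `bleach_frame`.
#' @export
#' @examples
#' tr <- simulate_frap_trace(frap_sim_config(k_off = 0.05, seed = 3))
#' plot(tr$times, tr$spot_intensity, type = "l")
simulate_frap_trace <- function(config) {
  stop_if(!inherits(config, "frap_sim_config"),
          "'config' must come from frap_sim_config()")
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  envelope <- exp(-config$acquisition_bleach_rate * times)
  spot <- config$background_level +
    config$spot_amplitude * frap_recovery_profile(config, times)
  field <- config$background_level + config$field_amplitude * envelope
  with_seed(config$seed, {
    noise <- function(x) x + rnorm(length(x), 0, config$noise_sd)
    structure(list(times = times,
                   spot_intensity = noise(spot),
                   background_intensity = noise(rep(config$background_level,
                                                    length(times))),
                   whole_field_intensity = noise(field),
                   bleach_frame = config$bleach_frame),
              class = "frap_trace")
  })
}

#' Render a FRAP experiment as an image stack
#'
#' Builds a small time-lapse stack containing one Gaussian bleach-recovery
#' spot on a central cell (a disk carrying the whole-field fluorescence)
#' over camera background, for exercising ROI-based trace extraction end to
#' end. The background ROI sits outside the cell.
#'
#' @param config a [frap_sim_config()].
#' @param dim stack frame size (height, width).
#' @param psf_sigma_px spot Gaussian sigma, pixels.
#' @return list with `stack` (height x width x frames array), `spot_roi`,
#'   `background_roi` (each `list(row, col, radius)`), `bleach_frame`,
#'   `times`, `cell_mask`, and `config`.
#' @export
render_frap_stack <- function(config, dim = c(48L, 48L), psf_sigma_px = 2) {
  stop_if(!inherits(config, "frap_sim_config"),
          "'config' must come from frap_sim_config()")
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  envelope <- exp(-config$acquisition_bleach_rate * times)
  rec <- frap_recovery_profile(config, times)
  center <- c(dim[1] / 2, dim[2] / 2)
  d2 <- outer((seq_len(dim[1]) - center[1])^2,
              (seq_len(dim[2]) - center[2])^2, `+`)
  kernel <- exp(-d2 / (2 * psf_sigma_px^2))
  cell <- d2 <= (min(dim) / 3)^2
  with_seed(config$seed, {
    stack <- array(0, c(dim[1], dim[2], config$n_frames))
    for (t in seq_len(config$n_frames)) {
      frame <- config$background_level +
        config$field_amplitude * envelope[t] * cell +
        config$spot_amplitude * rec[t] * kernel
      stack[, , t] <- pmax(frame + rnorm(length(frame), 0, config$noise_sd), 0)
    }
    list(stack = stack,
         spot_roi = list(row = center[1], col = center[2],
                         radius = 2 * psf_sigma_px),
         background_roi = list(row = 4, col = 4, radius = 3),
         bleach_frame = config$bleach_frame, times = times,
         cell_mask = cell, config = config)
  })
}
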