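# Synthetic two-channel PICT field generator.
#
# Emulates yeast cells with discrete static cortical anchor puncta
# (eisosome-like sites carrying the anchor-RFP), a prey-GFP channel that is
# cytosolic and/or punctate, and rapamycin-induced co-recruitment of prey to
# the anchor sites. Optics and detection follow the standard widefield CCD
# model: Gaussian point-spread blur of the photon image, Poisson shot noise,
# linear gain, additive camera offset and Gaussian read noise.

#' Configuration for one synthetic two-channel field
#'
#' All magnitudes are artifact choices: the assay this emulates published
#' its analysis parameters but no per-strain expression levels or
#' recruitment efficiencies, so the defaults are set to a regime a
#' practitioner would call realistic for yeast widefield imaging --
#' diffraction-limited cortical puncta (PSF sigma ~1.2 px), cytosolic prey
#' whose shot noise is a few ADU, anchor puncta several hundred ADU above
#' background.
#'
#' @param field_shape integer (height, width) in pixels, each >= 64.
#' @param n_cells number of cells per field.
#' @param cell_radius_px numeric (mean, sd) of the cell radius in pixels.
#' @param anchors_per_cell mean number of cortical anchor puncta per cell
#'   (Poisson, truncated at >= 1).
#' @param anchor_amplitude total photons emitted by one anchor punctum.
#' @param prey_expression mean cytosolic prey emission, photons per interior
#'   pixel.
#' @param prey_native_puncta mean number of native (anchor-independent)
#'   prey puncta per cell, for preys that also localize to cortical patches.
#' @param native_puncta_amplitude total photons per native prey punctum.
#' @param recruitment_efficiency fraction in `[0, 1]` of the cytosolic prey
#'   signal relocated to anchor sites under +RAP for an interactor.
#' @param psf_sigma_px Gaussian PSF standard deviation, pixels.
#' @param read_noise_sd camera read noise, ADU.
#' @param gain camera gain, ADU per photon.
#' @param background_level camera offset, ADU.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   fields.
#' @return A `sim_field_config` list.
#' @export
sim_field_config <- function(field_shape = c(256L, 256L),
                             n_cells = 12,
                             cell_radius_px = c(mean = 18, sd = 2),
                             anchors_per_cell = 4,
                             anchor_amplitude = 20000,
                             prey_expression = 600,
                             prey_native_puncta = 0,
                             native_puncta_amplitude = 30000,
                             recruitment_efficiency = 0.8,
                             psf_sigma_px = 1.2,
                             read_noise_sd = 2,
                             gain = 0.25,
                             background_level = 100,
                             seed = 1L) {
  stop_if(length(field_shape) != 2L || any(!is.finite(field_shape)),
          "'field_shape' must be (height, width)")
  stop_if(any(field_shape < 64), "'field_shape' must be at least 64 x 64")
  check_scalar(n_cells, "n_cells", lower = 1, integer = TRUE)
  stop_if(length(cell_radius_px) != 2L || any(!is.finite(cell_radius_px)) ||
            cell_radius_px[1] <= 0 || cell_radius_px[2] < 0,
          "'cell_radius_px' must be (mean > 0, sd >= 0)")
  check_scalar(anchors_per_cell, "anchors_per_cell", lower = 0)
  check_scalar(anchor_amplitude, "anchor_amplitude", lower = 0)
  check_scalar(prey_expression, "prey_expression", lower = 0)
  check_scalar(prey_native_puncta, "prey_native_puncta", lower = 0)
  check_scalar(native_puncta_amplitude, "native_puncta_amplitude", lower = 0)
  check_scalar(recruitment_efficiency, "recruitment_efficiency",
               lower = 0, upper = 1)
  check_scalar(psf_sigma_px, "psf_sigma_px", lower = 0)
  check_scalar(read_noise_sd, "read_noise_sd", lower = 0)
  check_scalar(gain, "gain", lower = 0)
  check_scalar(background_level, "background_level", lower = 0)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(field_shape = as.integer(field_shape), n_cells = n_cells,
                 cell_radius_px = unname(cell_radius_px),
                 anchors_per_cell = anchors_per_cell,
                 anchor_amplitude = anchor_amplitude,
                 prey_expression = prey_expression,
                 prey_native_puncta = prey_native_puncta,
                 native_puncta_amplitude = native_puncta_amplitude,
                 recruitment_efficiency = recruitment_efficiency,
                 psf_sigma_px = psf_sigma_px, read_noise_sd = read_noise_sd,
                 gain = gain, background_level = background_level,
                 seed = as.integer(seed)),
            class = "sim_field_config")
}

# Add diffraction-limited puncta: each spot contributes `amp` photons as a
# Gaussian patch of width sigma truncated at 4 sigma and renormalized to
# sum exactly to `amp` (photon-exact), evaluated at the true subpixel
# center. Returns the image with all spots added.
render_spots <- function(img, rows, cols, amps, sigma) {
  k <- ceiling(4 * sigma)
  for (i in seq_along(rows)) {
    r0 <- max(1L, floor(rows[i]) - k); r1 <- min(nrow(img), ceiling(rows[i]) + k)
    c0 <- max(1L, floor(cols[i]) - k); c1 <- min(ncol(img), ceiling(cols[i]) + k)
    kern <- exp(-outer((r0:r1 - rows[i])^2, (c0:c1 - cols[i])^2, `+`) /
                  (2 * sigma^2))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amps[i] * kern / sum(kern)
  }
  img
}

# Soft-edged filled disk (cell cytosol seen through the PSF): radial
# profile pnorm((radius - d) / sigma), the Gaussian blur of a step edge.
# Returns the patch and its index ranges so callers can scale and place it.
soft_disk_patch <- function(center, radius, sigma, dim) {
  ext <- radius + ceiling(4 * sigma)
  r0 <- max(1L, floor(center[1] - ext)); r1 <- min(dim[1], ceiling(center[1] + ext))
  c0 <- max(1L, floor(center[2] - ext)); c1 <- min(dim[2], ceiling(center[2] + ext))
  d <- sqrt(outer((r0:r1 - center[1])^2, (c0:c1 - center[2])^2, `+`))
  list(rows = r0:r1, cols = c0:c1,
       value = stats::pnorm((radius - d) / max(sigma, 1e-6)))
}

#' Simulate one two-channel PICT field
#'
#' Renders cells as filled disks of cytosolic prey with anchor puncta on the
#' perimeter (red channel). Under `condition = "plusRAP"` with
#' `interactor = TRUE`, a `recruitment_efficiency` fraction of each cell's
#' cytosolic prey photons is relocated to that cell's anchor sites, split
#' equally among them -- recruitment moves signal, it does not create it, so
#' the expected total prey photon count per cell is invariant to the
#' efficiency. Native prey puncta (if configured) are placed on the cell
#' perimeter independently of anchor sites, so chance colocalization is
#' represented. The photon image is blurred with a Gaussian PSF, then
#' converted to camera counts as `gain * Poisson(photons) + background +
#' N(0, read_noise_sd^2)`, clipped at 0.
#'
#' @param config a [sim_field_config()].
#' @param condition `"minusRAP"` (vehicle) or `"plusRAP"` (rapamycin).
#' @param interactor does this strain's prey follow the bait to the anchor?
#' @param noise apply shot/read noise (disable for photon-level tests).
#' @return A `pict_field`: list with `red`, `green` intensity matrices
#'   (ADU), `strain`, `condition`, `field_index`, and `truth` (a
#'   `field_truth` list: `anchor_coordinates` (n x 2, row/col),
#'   `cell_centers`, `cell_radii`, `native_puncta`, `is_interactor`,
#'   `condition`).
#' @export
#' @examples
#' f <- simulate_field(sim_field_config(seed = 7), "plusRAP", interactor = TRUE)
#' dim(f$red); nrow(f$truth$anchor_coordinates)
simulate_field <- function(config, condition = c("minusRAP", "plusRAP"),
                           interactor = FALSE, noise = TRUE) {
  stop_if(!inherits(config, "sim_field_config"),
          "'config' must be created with sim_field_config()")
  condition <- match.arg(condition)
  dim <- config$field_shape
  f_eff <- if (condition == "plusRAP" && interactor)
    config$recruitment_efficiency else 0
  with_seed(config$seed, {
    # margin keeps every emitter (cell + PSF support) inside the field
    margin <- config$cell_radius_px[1] + 3 * config$cell_radius_px[2] +
      ceiling(4 * config$psf_sigma_px) + 1
    radii <- pmax(stats::rnorm(config$n_cells, config$cell_radius_px[1],
                               config$cell_radius_px[2]), 4)
    radii <- pmin(radii, config$cell_radius_px[1] + 3 * config$cell_radius_px[2])
    # cells are solid: place centers by rejection so interiors do not
    # interpenetrate (after many failed draws the constraint is relaxed,
    # mimicking a crowded field)
    centers <- matrix(NA_real_, config$n_cells, 2)
    for (i in seq_len(config$n_cells)) {
      for (try in 1:60) {
        cand <- c(stats::runif(1, margin, dim[1] - margin),
                  stats::runif(1, margin, dim[2] - margin))
        ok <- i == 1L ||
          all(sqrt(rowSums(sweep(centers[seq_len(i - 1L), , drop = FALSE],
                                 2, cand)^2)) > radii[seq_len(i - 1L)] + radii[i])
        if (ok || try == 60L) break
      }
      centers[i, ] <- cand
    }
    red_ph <- matrix(0, dim[1], dim[2])
    green_ph <- matrix(0, dim[1], dim[2])
    anchors <- NULL
    natives <- NULL
    sigma <- config$psf_sigma_px
    for (i in seq_len(config$n_cells)) {
      n_anchor <- max(1L, stats::rpois(1, config$anchors_per_cell))
      # eisosome-like sites are quasi-regularly spaced along the membrane:
      # jittered regular angles keep planted puncta optically resolvable
      theta <- 2 * pi * (seq_len(n_anchor) - 1 +
                           stats::runif(n_anchor, -0.25, 0.25)) / n_anchor +
        stats::runif(1, 0, 2 * pi)
      ar <- centers[i, 1] + radii[i] * sin(theta)
      ac <- centers[i, 2] + radii[i] * cos(theta)
      anchors <- rbind(anchors, cbind(row = ar, col = ac))
      red_ph <- render_spots(red_ph, ar, ac,
                             rep(config$anchor_amplitude, n_anchor), sigma)
      # cytosolic prey through the PSF; a recruited fraction f_eff of the
      # cell's total is relocated, photon-exactly, to its anchor sites
      patch <- soft_disk_patch(centers[i, ], radii[i], sigma, dim)
      cyto_total <- config$prey_expression * sum(patch$value)
      if (config$prey_expression > 0) {
        green_ph[patch$rows, patch$cols] <-
          green_ph[patch$rows, patch$cols] +
          config$prey_expression * (1 - f_eff) * patch$value
        if (f_eff > 0)
          green_ph <- render_spots(green_ph, ar, ac,
                                   rep(f_eff * cyto_total / n_anchor,
                                       n_anchor), sigma)
      }
      n_native <- if (config$prey_native_puncta > 0)
        stats::rpois(1, config$prey_native_puncta) else 0L
      if (n_native > 0) {
        phi <- stats::runif(n_native, 0, 2 * pi)
        nr <- centers[i, 1] + radii[i] * sin(phi)
        nc <- centers[i, 2] + radii[i] * cos(phi)
        natives <- rbind(natives, cbind(row = nr, col = nc))
        green_ph <- render_spots(green_ph, nr, nc,
                                 rep(config$native_puncta_amplitude, n_native),
                                 sigma)
      }
    }
    to_adu <- function(ph) {
      if (noise) {
        counts <- matrix(stats::rpois(length(ph), pmax(ph, 0)), nrow(ph))
        pmax(config$gain * counts + config$background_level +
               stats::rnorm(length(ph), 0, config$read_noise_sd), 0)
      } else {
        config$gain * ph + config$background_level
      }
    }
    red <- to_adu(red_ph)
    green <- to_adu(green_ph)
    truth <- structure(list(anchor_coordinates = anchors,
                            cell_centers = centers, cell_radii = radii,
                            native_puncta = natives,
                            is_interactor = interactor,
                            condition = condition),
                       class = "field_truth")
    structure(list(red = red, green = green, strain = NA_character_,
                   condition = condition, field_index = NA_integer_,
                   truth = truth),
              class = "pict_field")
  })
}

#' @export
print.pict_field <- function(x, ...) {
  cat(sprintf("pict_field: %d x %d, strain %s, %s (field %s), %d anchors\n",
              nrow(x$red), ncol(x$red), x$strain, x$condition,
              x$field_index, nrow(x$truth$anchor_coordinates)))
  invisible(x)
}

#' Merge planted coordinates closer than a resolution limit
#'
#' Coordinates nearer than `min_sep` (typically twice the PSF sigma) blur
#' into one detectable punctum; this collapses such groups to their mean so
#' truth counts can be compared with segmentation counts.
#'
#' @param coords n x 2 matrix (row, col).
#' @param min_sep merge distance in pixels.
#' @return m x 2 matrix with m <= n.
#' @export
merge_close_points <- function(coords, min_sep) {
  if (is.null(coords) || nrow(coords) < 2L) return(coords)
  d <- as.matrix(stats::dist(coords))
  grp <- seq_len(nrow(coords))
  find <- function(i) { while (grp[i] != i) { grp[i] <<- grp[grp[i]]; i <- grp[i] }; i }
  close <- which(d < min_sep & upper.tri(d), arr.ind = TRUE)
  for (k in seq_len(nrow(close))) {
    a <- find(close[k, 1]); b <- find(close[k, 2])
    if (a != b) grp[max(a, b)] <- min(a, b)
  }
  roots <- vapply(seq_len(nrow(coords)), find, 1L)
  out <- rowsum(coords, roots) / as.vector(table(roots)[as.character(sort(unique(roots)))])
  unname(as.matrix(out))
}
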