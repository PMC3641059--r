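# Local-mean thresholding and connected-component patch detection.

# Local mean over a disk or square neighborhood, reflective border.
# The neighborhood is encoded as a per-row-offset column half-width: for a
# disk of radius rho, rows at offset d contribute a run of half-width
# floor(sqrt(rho^2 - d^2)); a square contributes constant half-width.
local_mean <- function(image, radius_px, window = c("disk", "square")) {
  window <- match.arg(window)
  r <- as.integer(floor(radius_px))
  d <- -r:r
  hw <- if (window == "square") rep(r, length(d))
        else ifelse(d^2 <= radius_px^2,
                    floor(sqrt(radius_px^2 - d^2)), -1L)
  n_px <- sum(ifelse(hw >= 0, 2 * hw + 1, 0))
  acc <- local_sum_cpp(pad_reflect(image, r), as.integer(hw), r,
                       nrow(image), ncol(image))
  acc / n_px
}

#' Local adaptive threshold for punctate structures
#'
#' Segments small bright patches by comparing each pixel to the mean of its
#' neighborhood: a pixel is foreground iff
#' `image > local_mean(image; radius) + offset`. This matches the mean
#' variant of ImageJ's auto local threshold, where the first parameter is
#' the value subtracted from the local mean -- so the screen pipeline's
#' historical setting "Parameter 1 = -12" corresponds to `offset = 12`
#' here (pixels must exceed the local mean by 12 intensity units). The
#' neighborhood is a disk by default; a square window is available and is
#' what a brute-force per-pixel oracle most naturally computes. Borders are
#' handled by reflective padding.
#'
#' @param image numeric matrix (ADU), typically background-subtracted.
#' @param radius_px neighborhood radius in pixels (pipeline default 5).
#' @param offset intensity excess over the local mean required for
#'   foreground (pipeline default 12; finite, may be negative).
#' @param window `"disk"` (default) or `"square"` neighborhood.
#' @param source_channel optional label (`"red"` or `"green"`) carried in
#'   the result for bookkeeping.
#' @return A `pict_mask`: list with `mask` (logical matrix),
#'   `source_channel`, and `params`.
#' @export
#' @examples
#' img <- matrix(0, 16, 16); img[8, 8] <- 100
#' m <- local_threshold(img, radius_px = 5, offset = 12)
#' sum(m$mask) # the single bright pixel
local_threshold <- function(image, radius_px = 5, offset = 12,
                            window = c("disk", "square"),
                            source_channel = NA_character_) {
  check_image(image)
  check_scalar(radius_px, "radius_px", lower = 1)
  stop_if(!is.numeric(offset) || length(offset) != 1L || !is.finite(offset),
          "'offset' must be a single finite number")
  window <- match.arg(window)
  lm <- local_mean(image, radius_px, window)
  structure(list(mask = image > lm + offset,
                 source_channel = source_channel,
                 params = list(radius_px = radius_px, offset = offset,
                               window = window)),
            class = "pict_mask")
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "pict_mask")) mask <- mask$mask
  stop_if(!is.matrix(mask) || !(is.logical(mask) || all(mask %in% c(0, 1))),
          "mask must be a logical (or 0/1) matrix or a 'pict_mask'")
  mask <- mask > 0
  mask
}

#' @export
print.pict_mask <- function(x, ...) {
  cat(sprintf("pict_mask: %d x %d, %d foreground px (channel: %s)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              x$source_channel))
  invisible(x)
}

# 8-connected labeling: EBImage::bwlabel (4-connected) followed by a
# union-find merge of labels that touch diagonally.
label_components <- function(mask) {
  mask <- as_mask_matrix(mask)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  h <- nrow(lab); w <- ncol(lab)
  for (shift in list(c(1L, 1L), c(1L, -1L))) {
    dr <- shift[1]; dc <- shift[2]
    rows <- seq_len(h - 1L)
    cols <- if (dc > 0) seq_len(w - 1L) else 2L:w
    a <- lab[rows, cols, drop = FALSE]
    b <- lab[rows + dr, cols + dc, drop = FALSE]
    touch <- which(a > 0L & b > 0L & a != b)
    if (length(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) union_(pairs[k, 1], pairs[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[out > 0L] <- relab[out[out > 0L]]
  out
}

#' Detect punctate patches in a binary mask
#'
#' Extracts 8-connected components of a segmentation mask, computes their
#' pixel areas and centroids (arithmetic mean of member-pixel row/column
#' coordinates, 1-based), and keeps components with area inside
#' `[min_area_px, max_area_px]`. The defaults bracket diffraction-limited
#' puncta at the simulated pixel scale while rejecting single-pixel noise
#' and large non-punctate structures.
#'
#' @param mask `pict_mask` or logical matrix.
#' @param min_area_px,max_area_px inclusive area filter in pixels.
#' @return A `pict_patches` data.frame with columns `centroid_row`,
#'   `centroid_col`, `area_px`; attribute `connectivity = 8`.
#' @export
detect_patches <- function(mask, min_area_px = 4, max_area_px = 200) {
  check_scalar(min_area_px, "min_area_px", lower = 0)
  stop_if(!is.numeric(max_area_px) || length(max_area_px) != 1L ||
            is.na(max_area_px), "'max_area_px' must be a number (Inf allowed)")
  stop_if(min_area_px > max_area_px, "'min_area_px' must be <= 'max_area_px'")
  lab <- label_components(mask)
  n <- max(lab)
  empty <- data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
                      area_px = integer(0))
  if (n == 0L) {
    return(structure(empty, class = c("pict_patches", "data.frame"),
                     connectivity = 8L))
  }
  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  area <- tabulate(labs, n)
  cr <- rowsum(as.numeric(rows), labs)[, 1] / area
  cc <- rowsum(as.numeric(cols), labs)[, 1] / area
  keep <- area >= min_area_px & area <= max_area_px
  out <- data.frame(centroid_row = cr[keep], centroid_col = cc[keep],
                    area_px = as.integer(area[keep]))
  rownames(out) <- NULL
  structure(out, class = c("pict_patches", "data.frame"), connectivity = 8L)
}
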