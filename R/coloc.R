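# Area-based colocalization scoring: mask intersection, anchor-area
# normalization, +RAP/-RAP recruitment ratio, and the patch-level manual
# scoring rule.

#' Colocalization area between the prey and anchor masks
#'
#' The colocalization readout is the number of pixels in the intersection
#' of the green (prey) and red (anchor) segmentation masks. Because the
#' anchor's localization and expression are unaffected by rapamycin, the
#' red-mask area -- proportional to the number of cells in the field --
#' normalizes the intersection, giving the per-field score
#' `s = A_inter / A_red`.
#'
#' @param green_mask,red_mask `pict_mask` objects or logical matrices of
#'   identical shape; the red mask must be non-empty.
#' @param strain,condition,field_index optional metadata carried through.
#' @return A one-row data.frame (`coloc_record`): `strain`, `condition`,
#'   `field_index`, `A_inter`, `A_red`, `s`.
#' @export
#' @examples
#' g <- matrix(FALSE, 8, 8); g[2:4, 2:4] <- TRUE
#' r <- matrix(FALSE, 8, 8); r[3:5, 3:5] <- TRUE
#' colocalization_area(g, r)
colocalization_area <- function(green_mask, red_mask, strain = NA_character_,
                                condition = NA_character_,
                                field_index = NA_integer_) {
  g <- as_mask_matrix(green_mask)
  r <- as_mask_matrix(red_mask)
  stop_if(!identical(dim(g), dim(r)), "masks must have identical shape")
  a_red <- sum(r)
  stop_if(a_red == 0, "red (anchor) mask is empty: cannot normalize")
  a_inter <- sum(g & r)
  data.frame(strain = strain, condition = condition,
             field_index = field_index,
             A_inter = a_inter, A_red = a_red, s = a_inter / a_red)
}

#' Recruitment ratio between +RAP and -RAP colocalization
#'
#' Ratio of the mean per-field normalized colocalization scores, rapamycin
#' over vehicle. When the vehicle mean is exactly zero the ratio is instead
#' computed from pooled intersection counts with a one-pixel pseudocount in
#' both conditions (`(sum A_inter + 1) / sum A_red`), which preserves the
#' ordering, avoids infinities, and is flagged in the result.
#'
#' @param records_plus,records_minus data.frames of per-field records from
#'   [colocalization_area()] for the +RAP and -RAP conditions of one strain.
#' @return list with `ratio`, `strain`, `pseudocount` (logical flag).
#' @export
recruitment_ratio <- function(records_plus, records_minus) {
  stop_if(nrow(records_plus) == 0 || nrow(records_minus) == 0,
          "both conditions need at least one record")
  strains <- unique(c(records_plus$strain, records_minus$strain))
  strains <- strains[!is.na(strains)]
  stop_if(length(strains) > 1, "records mix strains")
  m_minus <- mean(records_minus$s)
  if (m_minus > 0) {
    list(ratio = mean(records_plus$s) / m_minus,
         strain = if (length(strains)) strains else NA_character_,
         pseudocount = FALSE)
  } else {
    pooled <- function(rec) (sum(rec$A_inter) + 1) / sum(rec$A_red)
    list(ratio = pooled(records_plus) / pooled(records_minus),
         strain = if (length(strains)) strains else NA_character_,
         pseudocount = TRUE)
  }
}

#' Fraction of prey patches colocalizing with the anchor mask
#'
#' Implements the manual scoring metric: the fraction of green-channel
#' membrane patches whose centroid lies on (or within `tolerance_px` of)
#' the red anchor mask. An empty patch set has no defined fraction and is
#' an error, distinct from a fraction of 0.
#'
#' @param green_patches a `pict_patches` data.frame from [detect_patches()].
#' @param red_mask `pict_mask` or logical matrix.
#' @param tolerance_px centroid-to-mask distance tolerance (default 0:
#'   the centroid pixel itself must be foreground).
#' @return fraction in `[0, 1]`.
#' @export
patch_colocalization_fraction <- function(green_patches, red_mask,
                                          tolerance_px = 0) {
  check_scalar(tolerance_px, "tolerance_px", lower = 0)
  stop_if(nrow(green_patches) == 0,
          "no prey patches: colocalization fraction undefined")
  mask <- as_mask_matrix(red_mask)
  if (tolerance_px > 0) {
    off <- disk_offsets(tolerance_px)
    dil <- matrix(FALSE, nrow(mask), ncol(mask))
    r <- max(abs(off$dr))
    p <- pad_const(mask, r, FALSE)
    for (i in seq_len(nrow(off))) {
      dil <- dil | p[(r + 1L + off$dr[i]):(r + nrow(mask) + off$dr[i]),
                     (r + 1L + off$dc[i]):(r + ncol(mask) + off$dc[i])]
    }
    mask <- dil
  }
  rows <- pmin(pmax(round(green_patches$centroid_row), 1L), nrow(mask))
  cols <- pmin(pmax(round(green_patches$centroid_col), 1L), ncol(mask))
  mean(mask[cbind(rows, cols)])
}

#' Manual interaction call from the patch colocalization fraction
#'
#' A prey scores as interacting when strictly more than `cutoff` (default
#' 90%) of its membrane patches colocalize with the anchor.
#'
#' @param fraction patch colocalization fraction in `[0, 1]`.
#' @param cutoff decision cutoff (default 0.9).
#' @return logical.
#' @export
score_manual <- function(fraction, cutoff = 0.9) {
  check_scalar(fraction, "fraction", lower = 0, upper = 1)
  check_scalar(cutoff, "cutoff", lower = 0, upper = 1)
  fraction > cutoff
}

#' Segment and score one field of view
#'
#' The per-field pipeline: rolling-ball background subtraction of each
#' channel, local-mean thresholding of each channel, then the normalized
#' intersection score of the two masks.
#'
#' @param field a `pict_field`.
#' @param params a [pict_params()] configuration.
#' @return one-row `coloc_record` data.frame (see [colocalization_area()]).
#' @export
score_field <- function(field, params = pict_params()) {
  stop_if(!inherits(field, "pict_field"), "'field' must be a pict_field")
  seg <- function(ch, label) {
    bg <- subtract_background(ch, params$bg_radius_px)
    local_threshold(bg, params$thr_radius_px, params$thr_offset,
                    window = params$thr_window, source_channel = label)
  }
  colocalization_area(seg(field$green, "green"), seg(field$red, "red"),
                      strain = field$strain, condition = field$condition,
                      field_index = field$field_index)
}
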