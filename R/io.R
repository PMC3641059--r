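# TIFF and manifest I/O. Images are held in ADU; 16-bit TIFFs store
# ADU / 65535 as the tiff package works in [0, 1].

ADU_MAX <- 65535

#' Write one channel as a 16-bit grayscale TIFF
#'
#' @param image numeric matrix in ADU; values are clipped to
#'   `[0, 65535]` and stored at 16-bit depth.
#' @param path output file path.
#' @export
write_channel_tiff <- function(image, path) {
  check_image(image)
  tiff::writeTIFF(pmin(pmax(image, 0), ADU_MAX) / ADU_MAX, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' Read a grayscale TIFF channel back into ADU
#'
#' @param path TIFF file path (8- or 16-bit grayscale).
#' @return numeric matrix in ADU.
#' @export
read_channel_tiff <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1] # tolerate gray stored with extra plane
  x * ADU_MAX
}

#' Read a plate-layout manifest
#'
#' Expected columns: `strain`, `condition` (`minusRAP`/`plusRAP`),
#' `field_index`, `red_path`, `green_path`. Malformed rows (missing values,
#' unknown condition, missing files) are dropped with a warning naming the
#' row numbers; processing continues with the valid rows.
#'
#' @param path CSV file path.
#' @param check_files verify that the image files exist.
#' @return data.frame of valid manifest rows.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  stop_if(!file.exists(path), sprintf("no such manifest: %s", path))
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("strain", "condition", "field_index", "red_path", "green_path")
  stop_if(!all(need %in% names(m)),
          paste("manifest must have columns:", paste(need, collapse = ", ")))
  bad <- !stats::complete.cases(m[need]) |
    !m$condition %in% c("minusRAP", "plusRAP")
  if (check_files) {
    bad <- bad | !file.exists(m$red_path) | !file.exists(m$green_path)
  }
  if (any(bad)) {
    warning(sprintf("dropping %d malformed manifest row(s): %s",
                    sum(bad), paste(which(bad), collapse = ", ")),
            call. = FALSE)
    m <- m[!bad, , drop = FALSE]
  }
  m
}

#' Read a field of view from a manifest row
#'
#' @param row one manifest row (data.frame with the manifest columns).
#' @return a `pict_field` (without ground truth).
#' @export
read_field <- function(row) {
  structure(list(red = read_channel_tiff(row$red_path),
                 green = read_channel_tiff(row$green_path),
                 strain = row$strain, condition = row$condition,
                 field_index = row$field_index, truth = NULL),
            class = "pict_field")
}
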