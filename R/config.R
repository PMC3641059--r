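# Pipeline configuration.

#' Pipeline parameters
#'
#' Bundles the tunable parameters of the imaging pipeline. The defaults are
#' the assay's published analysis settings where those exist: rolling-ball
#' radius 115 px, local-threshold radius 5 px with an offset of 12
#' intensity units above the local mean, significance cutoff p < 0.02
#' (equivalently log10(1/p) > 1.699), and 9 fields of view per condition.
#' The remaining knobs (patch-area filter, neighborhood shape, minimum
#' recruitment ratio) are artifact choices documented in the package
#' vignette.
#'
#' @param bg_radius_px rolling-ball radius, pixels.
#' @param thr_radius_px local-threshold neighborhood radius, pixels.
#' @param thr_offset intensity excess over the local mean, ADU.
#' @param thr_window `"disk"` or `"square"` neighborhood.
#' @param p_cut one-tailed significance cutoff for the Welch test.
#' @param min_ratio minimum +RAP/-RAP ratio for a hit; the quantitative
#'   surrogate for the original visual negligible-recruitment screen-out.
#' @param fields_per_condition expected fields of view per condition.
#' @param min_area_px,max_area_px patch-area filter, pixels.
#' @param seed integer seed for any stochastic step.
#' @return A `pict_params` list.
#' @export
pict_params <- function(bg_radius_px = 115, thr_radius_px = 5,
                        thr_offset = 12, thr_window = "disk",
                        p_cut = 0.02, min_ratio = 1.5,
                        fields_per_condition = 9,
                        min_area_px = 4, max_area_px = 200, seed = 1L) {
  check_scalar(bg_radius_px, "bg_radius_px", lower = 1)
  check_scalar(thr_radius_px, "thr_radius_px", lower = 1)
  check_scalar(thr_offset, "thr_offset")
  thr_window <- match.arg(thr_window, c("disk", "square"))
  check_scalar(p_cut, "p_cut", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(min_ratio, "min_ratio", lower = 0)
  check_scalar(fields_per_condition, "fields_per_condition", lower = 2,
               integer = TRUE)
  check_scalar(min_area_px, "min_area_px", lower = 0)
  check_scalar(max_area_px, "max_area_px", lower = min_area_px)
  check_scalar(seed, "seed", integer = TRUE)
  structure(list(bg_radius_px = bg_radius_px, thr_radius_px = thr_radius_px,
                 thr_offset = thr_offset, thr_window = thr_window,
                 p_cut = p_cut, min_ratio = min_ratio,
                 fields_per_condition = fields_per_condition,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 seed = as.integer(seed)),
            class = "pict_params")
}

#' Read / write pipeline parameters as YAML
#'
#' Round-trips a [pict_params()] object through a structured text file so a
#' run is fully described by its config and seed.
#'
#' @param params a `pict_params` object.
#' @param path YAML file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `pict_params`.
#' @export
write_params <- function(params, path) {
  stop_if(!inherits(params, "pict_params"), "'params' must be pict_params")
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  stop_if(!file.exists(path), sprintf("no such config: %s", path))
  vals <- yaml::read_yaml(path)
  do.call(pict_params, vals)
}
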