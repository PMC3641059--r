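# Synthetic PPI screen generator: strains x conditions x fields with
# ground-truth interaction labels.

#' Configuration for a synthetic PICT screen
#'
#' The defaults reproduce the structure of the published exocyst screen: 227
#' GFP-prey strains imaged in 9 fields of view per condition, with induced
#' recruitment planted only for the six exocyst subunit preys present in
#' that collection (Sec3, Sec5, Sec6, Sec8, Sec15, Exo84). Every field
#' draws from its own RNG stream derived from
#' `(master_seed, strain, condition, field)`, so any strain or field can be
#' regenerated in isolation and the whole screen is reproducible from one
#' integer.
#'
#' @param n_strains number of prey strains (default 227).
#' @param interactor_ids labels of strains given induced recruitment; must
#'   be a subset of `strain_ids`.
#' @param strain_ids optional strain labels; defaults to the interactor ids
#'   followed by `prey_001 ...` filler to `n_strains`.
#' @param fields_per_condition fields of view per strain and condition
#'   (default 9; at least 2, the t-test needs within-group variance).
#' @param field_config a [sim_field_config()] used for every field; its
#'   `seed` is overridden per field. `prey_native_puncta` defaults to 2
#'   here: screen preys commonly show native cortical patches in addition
#'   to cytosol, which exercises chance colocalization in the null strains.
#' @param master_seed integer seed for the whole screen.
#' @return A `sim_screen_config` list.
#' @export
sim_screen_config <- function(n_strains = 227,
                              interactor_ids = c("Sec3", "Sec5", "Sec6",
                                                 "Sec8", "Sec15", "Exo84"),
                              strain_ids = NULL,
                              fields_per_condition = 9,
                              field_config = sim_field_config(prey_native_puncta = 2),
                              master_seed = 1L) {
  check_scalar(n_strains, "n_strains", lower = 1, integer = TRUE)
  check_scalar(fields_per_condition, "fields_per_condition", lower = 2,
               integer = TRUE)
  check_scalar(master_seed, "master_seed", integer = TRUE)
  stop_if(!inherits(field_config, "sim_field_config"),
          "'field_config' must come from sim_field_config()")
  if (is.null(strain_ids)) {
    filler <- sprintf("prey_%03d", seq_len(n_strains))
    strain_ids <- c(interactor_ids,
                    filler[seq_len(max(0, n_strains - length(interactor_ids)))])
    strain_ids <- strain_ids[seq_len(n_strains)]
  }
  stop_if(length(strain_ids) != n_strains,
          "'strain_ids' must have length n_strains")
  stop_if(anyDuplicated(strain_ids) > 0, "duplicate strain labels")
  stop_if(!all(interactor_ids %in% strain_ids),
          "'interactor_ids' must be a subset of the strain labels")
  structure(list(n_strains = n_strains, strain_ids = strain_ids,
                 interactor_ids = interactor_ids,
                 fields_per_condition = fields_per_condition,
                 field_config = field_config,
                 master_seed = as.integer(master_seed)),
            class = "sim_screen_config")
}

#' Enumerate the fields of a synthetic screen
#'
#' @param config a [sim_screen_config()].
#' @return data.frame with one row per field: `strain`, `condition`,
#'   `field_index`, `interactor`, `seed` (the derived per-field RNG seed).
#' @export
screen_plan <- function(config) {
  stop_if(!inherits(config, "sim_screen_config"),
          "'config' must come from sim_screen_config()")
  plan <- expand.grid(field_index = seq_len(config$fields_per_condition),
                      condition = c("minusRAP", "plusRAP"),
                      strain = config$strain_ids,
                      stringsAsFactors = FALSE)
  plan <- plan[, c("strain", "condition", "field_index")]
  plan$interactor <- plan$strain %in% config$interactor_ids
  plan$seed <- mapply(derive_seed, plan$strain, plan$condition,
                      plan$field_index,
                      MoreArgs = list(master_seed = config$master_seed))
  plan
}

# Simulate the field described by one plan row.
simulate_planned_field <- function(config, plan_row, noise = TRUE) {
  fc <- config$field_config
  fc$seed <- as.integer(plan_row$seed)
  f <- simulate_field(fc, plan_row$condition,
                      interactor = isTRUE(plan_row$interactor), noise = noise)
  f$strain <- plan_row$strain
  f$field_index <- plan_row$field_index
  f
}

#' Simulate a full synthetic screen
#'
#' Either returns the fields in memory (practical for small configurations)
#' or, if `out_dir` is given, writes each field as two 16-bit grayscale
#' TIFFs plus a plate-layout manifest (`manifest.csv`: strain, condition,
#' field_index, red_path, green_path) and a ground-truth table
#' (`truth.csv`: strain, interactor), and returns the manifest.
#'
#' @param config a [sim_screen_config()].
#' @param out_dir optional directory for TIFF output.
#' @return If `out_dir` is `NULL`, a list of `pict_field` objects named
#'   `strain/condition/field`; otherwise the manifest data.frame
#'   (invisibly, with the files on disk).
#' @export
simulate_screen <- function(config, out_dir = NULL) {
  plan <- screen_plan(config)
  if (is.null(out_dir)) {
    fields <- vector("list", nrow(plan))
    for (i in seq_len(nrow(plan))) {
      fields[[i]] <- simulate_planned_field(config, plan[i, ])
    }
    names(fields) <- sprintf("%s/%s/%d", plan$strain, plan$condition,
                             plan$field_index)
    return(fields)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan$red_path <- file.path(out_dir, sprintf("%s_%s_f%d_red.tif",
                                              plan$strain, plan$condition,
                                              plan$field_index))
  plan$green_path <- sub("_red\\.tif$", "_green.tif", plan$red_path)
  for (i in seq_len(nrow(plan))) {
    f <- simulate_planned_field(config, plan[i, ])
    write_channel_tiff(f$red, plan$red_path[i])
    write_channel_tiff(f$green, plan$green_path[i])
  }
  manifest <- plan[, c("strain", "condition", "field_index",
                       "red_path", "green_path")]
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  truth <- data.frame(strain = config$strain_ids,
                      interactor = config$strain_ids %in% config$interactor_ids)
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
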