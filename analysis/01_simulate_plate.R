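#!/usr/bin/env Rscript
# Simulate a small demonstration plate (6 strains, one planted interactor,
# 9 fields of view per condition) and write it to disk as 16-bit TIFFs with
# a plate manifest and ground-truth table. The full-size screen in
# 02_exocyst_screen.R is simulated in memory instead; this plate exists so
# the disk-based path (TIFF in, CSV out) is exercised and inspectable.

suppressPackageStartupMessages(library(pictscreen))

out_dir <- "results/demo_plate"
config <- sim_screen_config(
  n_strains = 6,
  interactor_ids = "Sec5",
  strain_ids = c("Sec5", sprintf("prey_%03d", 1:5)),
  fields_per_condition = 9,
  field_config = sim_field_config(prey_native_puncta = 2),
  master_seed = 101L)

manifest <- simulate_screen(config, out_dir)
cat(sprintf("wrote %d fields (%d strains x 2 conditions x %d fields) to %s\n",
            nrow(manifest), config$n_strains, config$fields_per_condition,
            out_dir))
cat("manifest:", file.path(out_dir, "manifest.csv"), "\n")
cat("truth:   ", file.path(out_dir, "truth.csv"), "\n")
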