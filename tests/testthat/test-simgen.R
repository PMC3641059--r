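test_that("field config rejects invalid parameters", {
  expect_error(sim_field_config(anchor_amplitude = -1), "anchor_amplitude")
  expect_error(sim_field_config(recruitment_efficiency = 1.2),
               "recruitment_efficiency")
  expect_error(sim_field_config(field_shape = c(32, 256)), "64 x 64")
  expect_error(sim_field_config(prey_expression = NaN), "prey_expression")
  expect_error(sim_field_config(gain = Inf), "gain")
})

test_that("identical config and seed give bit-identical fields", {
  cfg <- test_field_config(seed = 11, prey_native_puncta = 2)
  f1 <- simulate_field(cfg, "plusRAP", interactor = TRUE)
  f2 <- simulate_field(cfg, "plusRAP", interactor = TRUE)
  expect_identical(f1$red, f2$red)
  expect_identical(f1$green, f2$green)
  expect_identical(f1$truth$anchor_coordinates, f2$truth$anchor_coordinates)
})

test_that("zero prey expression leaves the green channel at background", {
  cfg <- test_field_config(prey_expression = 0, seed = 3)
  f <- simulate_field(cfg, "plusRAP", interactor = TRUE)
  expect_lt(abs(mean(f$green) - cfg$background_level), 1)
  mask <- local_threshold(subtract_background(f$green, 115))
  expect_equal(sum(mask$mask), 0)
})

test_that("zero recruitment efficiency makes +RAP identical to -RAP", {
  cfg <- test_field_config(recruitment_efficiency = 0, seed = 5)
  fp <- simulate_field(cfg, "plusRAP", interactor = TRUE)
  fm <- simulate_field(cfg, "minusRAP", interactor = TRUE)
  expect_identical(fp$green, fm$green)
  expect_identical(fp$red, fm$red)
})

test_that("recruitment relocates prey photons without creating them", {
  totals <- vapply(c(0, 0.3, 0.6, 1), function(f_eff) {
    cfg <- test_field_config(recruitment_efficiency = f_eff, seed = 21)
    f <- simulate_field(cfg, "plusRAP", interactor = TRUE, noise = FALSE)
    sum(f$green - cfg$background_level) / cfg$gain
  }, 0)
  expect_lt(max(abs(totals - totals[1])) / totals[1], 1e-6)
})

test_that("anchor truth is recovered by the default segmentation", {
  cfg <- sim_field_config(anchors_per_cell = 5, n_cells = 10, seed = 1)
  counts_ok <- recovered <- c()
  for (seed in 1:5) {
    cfg$seed <- seed
    f <- simulate_field(cfg, "minusRAP", noise = FALSE)
    patches <- detect_patches(local_threshold(subtract_background(f$red)))
    truth <- merge_close_points(f$truth$anchor_coordinates,
                                2 * cfg$psf_sigma_px)
    counts_ok <- c(counts_ok,
                   abs(nrow(patches) - nrow(truth)) <= 0.1 * nrow(truth))
    d <- sqrt(outer(truth[, 1], patches$centroid_row, "-")^2 +
                outer(truth[, 2], patches$centroid_col, "-")^2)
    recovered <- c(recovered, mean(apply(d, 1, min) <= 2))
  }
  expect_true(all(counts_ok))
  expect_gte(mean(recovered), 0.95)
})

test_that("screen plans count strains, conditions and fields correctly", {
  small <- sim_screen_config(n_strains = 3, interactor_ids = "s1",
                             strain_ids = c("s1", "s2", "s3"),
                             fields_per_condition = 9)
  expect_equal(nrow(screen_plan(small)), 54)
  full <- sim_screen_config()
  plan <- screen_plan(full)
  expect_equal(full$n_strains, 227)
  expect_equal(nrow(plan), 227 * 2 * 9)
  expect_setequal(unique(plan$condition), c("minusRAP", "plusRAP"))
  expect_equal(sum(plan$interactor), 6 * 2 * 9)
  expect_setequal(full$interactor_ids,
                  c("Sec3", "Sec5", "Sec6", "Sec8", "Sec15", "Exo84"))
})

test_that("screen config rejects inconsistent strain sets", {
  expect_error(sim_screen_config(n_strains = 2, strain_ids = c("a", "a"),
                                 interactor_ids = "a"), "duplicate")
  expect_error(sim_screen_config(n_strains = 2, strain_ids = c("a", "b"),
                                 interactor_ids = "z"), "subset")
  expect_error(sim_screen_config(fields_per_condition = 1), "fields_per_condition")
})

test_that("the same master seed reproduces identical screen pixels", {
  cfg <- sim_screen_config(n_strains = 2, interactor_ids = "s1",
                           strain_ids = c("s1", "s2"),
                           fields_per_condition = 2,
                           field_config = test_field_config(),
                           master_seed = 99)
  expect_identical(lapply(simulate_screen(cfg), `[[`, "green"),
                   lapply(simulate_screen(cfg), `[[`, "green"))
})

test_that("FRAP trace follows its generative equation", {
  # no exchange: post-bleach trace is flat at (1 - depth) x envelope
  cfg <- frap_sim_config(k_off = 0, immobile_fraction = 0.4,
                         bleach_depth = 0.8, acquisition_bleach_rate = 0,
                         noise_sd = 0, n_frames = 60)
  tr <- simulate_frap_trace(cfg)
  post <- (cfg$bleach_frame + 1):cfg$n_frames
  expect_equal(diff(range(tr$spot_intensity[post])), 0)
  expect_equal(tr$spot_intensity[post][1],
               cfg$background_level + cfg$spot_amplitude * (1 - 0.8))

  # no bleach: plateau times the acquisition-bleaching envelope throughout
  cfg0 <- frap_sim_config(bleach_depth = 0, acquisition_bleach_rate = 0.003,
                          noise_sd = 0, n_frames = 60)
  tr0 <- simulate_frap_trace(cfg0)
  expect_equal(tr0$spot_intensity,
               cfg0$background_level +
                 cfg0$spot_amplitude * exp(-0.003 * tr0$times))

  # closed form one time constant after the bleach
  cfg1 <- frap_sim_config(k_off = 0.02, immobile_fraction = 0.25,
                          bleach_depth = 0.9, acquisition_bleach_rate = 0,
                          noise_sd = 0, frame_interval = 1, n_frames = 100,
                          bleach_frame = 10)
  tr1 <- simulate_frap_trace(cfg1)
  t_eval <- 10 + 50 # bleach lands at frame 11, t = 10 s; evaluate at +50 s
  idx <- which(tr1$times == t_eval)
  expect_equal(tr1$spot_intensity[idx],
               cfg1$background_level + cfg1$spot_amplitude *
                 (0.1 + 0.9 * 0.75 * (1 - exp(-1))),
               tolerance = 1e-12)
})

test_that("FRAP config needs room for post-bleach frames", {
  expect_error(frap_sim_config(n_frames = 10, bleach_frame = 10), "exceed")
  expect_error(frap_sim_config(immobile_fraction = -0.1), "immobile_fraction")
})
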