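test_that("trace extraction averages ROIs and validates its input", {
  stack <- array(7, c(20, 20, 6))
  tr <- extract_trace(stack, list(row = 10, col = 10, radius = 3),
                      list(row = 3, col = 3, radius = 2),
                      bleach_frame = 2, frame_interval = 1.5)
  expect_equal(tr$spot_intensity, rep(7, 6))
  expect_equal(tr$background_intensity, rep(7, 6))
  expect_equal(tr$whole_field_intensity, rep(7, 6))
  expect_equal(tr$times, (0:5) * 1.5)

  expect_error(extract_trace(array(1, c(20, 20, 1)),
                             list(row = 10, col = 10, radius = 3),
                             list(row = 3, col = 3, radius = 2), 1),
               ">= 2")
  expect_error(extract_trace(stack, list(row = 1, col = 10, radius = 3),
                             list(row = 3, col = 3, radius = 2), 2),
               "outside")
  expect_error(extract_trace(stack, list(row = 10, col = 10, radius = 6),
                             list(row = 8, col = 8, radius = 2), 2),
               "overlap")
})

test_that("extraction recovers the generative trace from rendered pixels", {
  cfg <- frap_sim_config(k_off = 0.05, immobile_fraction = 0.2,
                         noise_sd = 0.5, n_frames = 80, seed = 21)
  rs <- render_frap_stack(cfg)
  tr <- extract_trace(rs$stack, rs$spot_roi, rs$background_roi,
                      rs$bleach_frame, cfg$frame_interval)
  # expected ROI mean: background + cell field + spot kernel average
  d2 <- outer((seq_len(48) - 24)^2, (seq_len(48) - 24)^2, `+`)
  kern <- exp(-d2 / (2 * 2^2))
  roi <- d2 <= (2 * 2)^2
  envelope <- exp(-cfg$acquisition_bleach_rate * rs$times)
  rec <- ifelse(rs$times < rs$bleach_frame * cfg$frame_interval, 1,
                (1 - cfg$bleach_depth) + cfg$bleach_depth *
                  (1 - cfg$immobile_fraction) *
                  (1 - exp(-cfg$k_off * (rs$times - rs$bleach_frame *
                                           cfg$frame_interval))))
  expected <- cfg$background_level + cfg$field_amplitude * envelope +
    cfg$spot_amplitude * rec * envelope * mean(kern[roi])
  expect_lt(max(abs(tr$spot_intensity - expected)), 1)
})

test_that("normalization pins the pre-bleach mean at 1 and bleach at 0", {
  cfg <- frap_sim_config(k_off = 0.02, immobile_fraction = 0.3,
                         noise_sd = 0, seed = 2)
  nz <- normalize_frap(simulate_frap_trace(cfg))
  expect_equal(mean(nz$value[!nz$post]), 1, tolerance = 1e-12)
  expect_equal(nz$value[which(nz$post)[1]], 0, tolerance = 1e-12)
  # closed form: mobile * (1 - exp(-k t')) with t' from the bleach frame
  tp <- nz$times[nz$post] - nz$times[which(nz$post)[1]]
  expect_equal(nz$value[nz$post], 0.7 * (1 - exp(-0.02 * tp)),
               tolerance = 1e-6)
})

test_that("no exchange gives a flat zero curve; fast exchange approaches 1", {
  stable <- normalize_frap(simulate_frap_trace(
    frap_sim_config(k_off = 0, immobile_fraction = 0.5, noise_sd = 0)))
  expect_equal(max(abs(stable$value[stable$post])), 0, tolerance = 1e-12)

  fast <- normalize_frap(simulate_frap_trace(
    frap_sim_config(k_off = 1, immobile_fraction = 0, noise_sd = 0)))
  expect_equal(fast$value[length(fast$value)], 1, tolerance = 1e-3)
})

test_that("normalization rejects field traces at or below background", {
  tr <- structure(list(times = 0:9, spot_intensity = rep(10, 10),
                       background_intensity = rep(10, 10),
                       whole_field_intensity = rep(10, 10),
                       bleach_frame = 3L), class = "frap_trace")
  expect_error(normalize_frap(tr), "whole-field")
})

test_that("aggregation is the pointwise mean and sample SD", {
  mk <- function(v) list(times = 0:4, value = rep(v, 5), bleach_frame = 2L,
                         post = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  same <- aggregate_curves(list(mk(0.4), mk(0.4)))
  expect_equal(same$mean, rep(0.4, 5))
  expect_equal(same$sd, rep(0, 5))
  expect_equal(same$n, 2)

  ab <- aggregate_curves(list(mk(0), mk(1)))
  expect_equal(ab$mean, rep(0.5, 5))
  expect_equal(ab$sd, rep(sqrt(0.5), 5))

  shifted <- mk(1); shifted$times <- shifted$times + 0.1
  expect_error(aggregate_curves(list(mk(0), shifted)), "time grid")
  expect_error(aggregate_curves(list(mk(0))), "at least 2")
})

test_that("recovery fitting brackets the kinetic regimes", {
  # flat curve: essentially no mobile signal
  flat <- simulate_frap_experiment(
    frap_sim_config(k_off = 0, immobile_fraction = 0.8, seed = 12), n = 8)
  expect_lt(fit_recovery(flat)$mobile_fraction, 0.1)

  # parameter recovery in a well-conditioned regime
  cv <- simulate_frap_experiment(
    frap_sim_config(k_off = 0.05, immobile_fraction = 0.1, seed = 11), n = 12)
  fit <- fit_recovery(cv)
  expect_lt(abs(fit$k_app - 0.05) / 0.05, 0.10)
  expect_lt(abs(fit$mobile_fraction - 0.9), 0.05)

  # instantaneous full recovery: mobile ~ 1, rate at its bound
  inst <- list(times = 0:19, mean = c(rep(1, 5), rep(1, 15)),
               bleach_frame = 5L)
  class(inst) <- "frap_curve"
  f <- fit_recovery(inst, k_max = 10)
  expect_gt(f$mobile_fraction, 0.99)
  expect_equal(f$k_app, 10, tolerance = 1e-6)
})

test_that("replicate experiments mirror the published study sizes", {
  stable <- simulate_frap_experiment(
    frap_sim_config(k_off = 0, immobile_fraction = 0.9, seed = 8), n = 8)
  transient <- simulate_frap_experiment(
    frap_sim_config(k_off = 0.1, immobile_fraction = 0.1, seed = 9), n = 12)
  expect_equal(stable$n, 8)
  expect_equal(transient$n, 12)
  expect_lt(fit_recovery(stable)$mobile_fraction, 0.2)
  expect_gt(fit_recovery(transient)$mobile_fraction, 0.7)
})
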