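square_mask <- function(dim, rows, cols) {
  m <- matrix(FALSE, dim[1], dim[2]); m[rows, cols] <- TRUE; m
}

test_that("colocalization area counts intersecting pixels and normalizes", {
  g <- square_mask(c(20, 20), 3:10, 3:7)          # 40 px
  expect_equal(colocalization_area(g, g)$s, 1)
  expect_equal(colocalization_area(g, g)$A_inter, 40)

  r <- square_mask(c(20, 20), 13:17, 13:17)
  rec <- colocalization_area(g, r)
  expect_equal(rec$A_inter, 0)
  expect_equal(rec$s, 0)

  # green: two 3x3 squares; red: one of them plus a disjoint 5x5
  g2 <- square_mask(c(30, 30), 2:4, 2:4) | square_mask(c(30, 30), 10:12, 10:12)
  r2 <- square_mask(c(30, 30), 2:4, 2:4) | square_mask(c(30, 30), 20:24, 20:24)
  rec2 <- colocalization_area(g2, r2)
  expect_equal(rec2$A_inter, 9)
  expect_equal(rec2$A_red, 34)
  expect_equal(rec2$s, 9 / 34)
})

test_that("colocalization rejects empty red masks and shape mismatches", {
  g <- square_mask(c(10, 10), 2:3, 2:3)
  expect_error(colocalization_area(g, matrix(FALSE, 10, 10)), "empty")
  expect_error(colocalization_area(g, matrix(TRUE, 12, 12)), "shape")
})

test_that("the score is invariant under joint translation", {
  set.seed(5)
  # content confined to the interior so a 4-px shift loses no pixels
  g <- r <- matrix(FALSE, 30, 30)
  g[5:20, 5:20] <- matrix(runif(256) < 0.2, 16)
  r[5:20, 5:20] <- matrix(runif(256) < 0.2, 16)
  r[5, 5] <- TRUE
  shift <- function(m, d) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + d):nrow(m), (1 + d):ncol(m)] <-
      m[1:(nrow(m) - d), 1:(ncol(m) - d)]
    out
  }
  s0 <- colocalization_area(g, r)$s
  expect_equal(colocalization_area(shift(g, 4), shift(r, 4))$s, s0)
})

test_that("recruitment ratio is the ratio of mean scores", {
  rec <- function(s, cond) data.frame(strain = "x", condition = cond,
                                      field_index = seq_along(s),
                                      A_inter = round(s * 100), A_red = 100,
                                      s = s)
  expect_equal(recruitment_ratio(rec(c(0.2, 0.2, 0.2), "plusRAP"),
                                 rec(c(0.1, 0.1, 0.1), "minusRAP"))$ratio, 2)
  same <- recruitment_ratio(rec(c(0.1, 0.3), "plusRAP"),
                            rec(c(0.1, 0.3), "minusRAP"))
  expect_equal(same$ratio, 1)
  expect_false(same$pseudocount)
})

test_that("a zero vehicle mean falls back to a flagged pseudocount ratio", {
  rec <- function(a_inter) data.frame(strain = "x", condition = "c",
                                      field_index = seq_along(a_inter),
                                      A_inter = a_inter, A_red = 500,
                                      s = a_inter / 500)
  lo <- recruitment_ratio(rec(c(10, 12, 11)), rec(c(0, 0, 0)))
  hi <- recruitment_ratio(rec(c(40, 42, 41)), rec(c(0, 0, 0)))
  expect_true(lo$pseudocount && hi$pseudocount)
  expect_gt(lo$ratio, 1)
  expect_gt(hi$ratio, lo$ratio) # monotone in the +RAP mean
})

test_that("patch colocalization fraction counts centroids on the mask", {
  r <- square_mask(c(40, 40), 10:30, 10:30)
  inside <- data.frame(centroid_row = seq(11, 29, length.out = 7),
                       centroid_col = seq(11, 29, length.out = 7),
                       area_px = 9L)
  outside <- data.frame(centroid_row = c(2, 3, 35), centroid_col = c(2, 35, 3),
                        area_px = 9L)
  expect_equal(patch_colocalization_fraction(inside, r), 1)
  expect_equal(patch_colocalization_fraction(outside, r), 0)
  expect_equal(patch_colocalization_fraction(rbind(inside, outside), r), 0.7)
  expect_error(patch_colocalization_fraction(inside[0, ], r), "undefined")
})

test_that("a tolerance widens the acceptance zone around the mask", {
  r <- square_mask(c(20, 20), 8:12, 8:12)
  near <- data.frame(centroid_row = 6, centroid_col = 10, area_px = 9L)
  expect_equal(patch_colocalization_fraction(near, r, tolerance_px = 0), 0)
  expect_equal(patch_colocalization_fraction(near, r, tolerance_px = 2), 1)
})

test_that("the manual scoring rule is strict at its 90% cutoff", {
  expect_true(score_manual(0.95))
  expect_false(score_manual(0.90))
  expect_false(score_manual(0))
})

test_that("induced recruitment raises the mean score and nulls stay null", {
  cfg <- test_field_config(recruitment_efficiency = 0.5, prey_native_puncta = 2)
  s_plus <- s_minus <- c()
  for (seed in 1:10) {
    cfg$seed <- seed
    s_plus <- c(s_plus, score_field(simulate_field(cfg, "plusRAP", TRUE))$s)
    cfg$seed <- seed + 1000
    s_minus <- c(s_minus, score_field(simulate_field(cfg, "minusRAP", TRUE))$s)
  }
  expect_gt(mean(s_plus), mean(s_minus))
  expect_lt(welch_one_tailed(s_plus, s_minus)$p_one_tailed, 0.01)

  # non-interactors: one-tailed Welch p across independent null strains is
  # roughly uniform -- no systematic +RAP excess
  p_null <- vapply(1:24, function(k) {
    sp <- sm <- numeric(4)
    for (j in 1:4) {
      cfg$seed <- derive_seed(500 + k, "p", j)
      sp[j] <- score_field(simulate_field(cfg, "plusRAP", FALSE))$s
      cfg$seed <- derive_seed(500 + k, "m", j)
      sm[j] <- score_field(simulate_field(cfg, "minusRAP", FALSE))$s
    }
    welch_one_tailed(sp, sm)$p_one_tailed
  }, 0)
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  expect_gt(mean(p_null), 0.25)
})
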