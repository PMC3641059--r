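# Per-strain hit calling: one-tailed heteroscedastic (Welch) t-test across
# fields of view, the +RAP/-RAP ratio, and assembly of the screen table.

#' One-tailed heteroscedastic (Welch) t-test
#'
#' Tests whether the +RAP colocalization scores exceed the -RAP scores:
#' `t = (mean(x_plus) - mean(x_minus)) / sqrt(var(x_plus)/n1 +
#' var(x_minus)/n2)` with sample (n-1) variances, degrees of freedom by the
#' Welch--Satterthwaite formula, and the upper-tail Student-t probability
#' (alternative: plus > minus).
#'
#' @param x_plus,x_minus numeric vectors of per-field scores, each with at
#'   least 2 finite values; at least one group must have positive variance.
#' @return list with `t_stat`, `df`, `p_one_tailed`.
#' @export
#' @examples
#' welch_one_tailed(c(2, 3, 4), c(1, 1, 1.5))
welch_one_tailed <- function(x_plus, x_minus) {
  stop_if(length(x_plus) < 2 || length(x_minus) < 2,
          "each group needs at least 2 values")
  stop_if(any(!is.finite(x_plus)) || any(!is.finite(x_minus)),
          "scores must be finite")
  n1 <- length(x_plus); n2 <- length(x_minus)
  v1 <- var(x_plus); v2 <- var(x_minus)
  stop_if(v1 == 0 && v2 == 0,
          "both groups have zero variance: test undefined")
  se2 <- v1 / n1 + v2 / n2
  t_stat <- (mean(x_plus) - mean(x_minus)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t_stat = t_stat, df = df, p_one_tailed = pt(t_stat, df, lower.tail = FALSE))
}

#' Call hits from per-strain ratios and p-values
#'
#' A strain is `significant` when its one-tailed p-value is below `p_cut`
#' (default 0.02, equivalently log10(1/p) > 1.699); it is `negligible` when
#' its +RAP/-RAP ratio falls below `min_ratio`, the quantitative surrogate
#' for screening out statistically significant strains whose recruitment is
#' visually negligible. A `hit` is significant and not negligible.
#'
#' @param results data.frame with at least `strain`, `ratio`, `p` (and
#'   optionally `t_stat`, `df`, carried through).
#' @param p_cut significance cutoff in (0, 1).
#' @param min_ratio minimum ratio for non-negligible recruitment.
#' @return data.frame with added columns `log_inv_p`, `significant`,
#'   `negligible`, `hit`, sorted by decreasing `log_inv_p`.
#' @export
call_hits <- function(results, p_cut = 0.02, min_ratio = 1.5) {
  check_scalar(p_cut, "p_cut", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(min_ratio, "min_ratio", lower = 0)
  stop_if(!all(c("strain", "ratio", "p") %in% names(results)),
          "'results' needs columns strain, ratio, p")
  out <- results
  out$log_inv_p <- -log10(out$p)
  out$significant <- !is.na(out$p) & out$p < p_cut
  out$negligible <- out$ratio < min_ratio
  out$hit <- out$significant & !out$negligible
  out[order(-out$log_inv_p), , drop = FALSE]
}

# Welch test with the screen-level degenerate-input policy: two identical
# constant groups carry no evidence either way (t = 0, p = 0.5); unequal
# constant groups leave p undefined (NA, never significant).
welch_screen <- function(x_plus, x_minus) {
  if (var(x_plus) == 0 && var(x_minus) == 0) {
    if (isTRUE(all.equal(mean(x_plus), mean(x_minus))))
      return(list(t_stat = 0, df = NA_real_, p_one_tailed = 0.5, degenerate = TRUE))
    return(list(t_stat = NA_real_, df = NA_real_, p_one_tailed = NA_real_,
                degenerate = TRUE))
  }
  c(welch_one_tailed(x_plus, x_minus), degenerate = FALSE)
}

#' Assemble the screen table from per-field colocalization records
#'
#' For each strain, runs the one-tailed Welch test of the +RAP against the
#' -RAP per-field scores, computes the recruitment ratio, and calls hits.
#' Strains missing a condition or with fewer than 2 fields in either
#' condition are skipped with a warning.
#'
#' @param records data.frame of per-field records ([colocalization_area()]
#'   rows) covering both conditions.
#' @param params a [pict_params()]; supplies `p_cut` and `min_ratio`.
#' @param test_on `"score"` (normalized s, default) or `"area"` (raw
#'   intersection pixels).
#' @return Screen table sorted by decreasing `log_inv_p`, with columns
#'   `strain`, `ratio`, `t_stat`, `df`, `p`, `log_inv_p`, `significant`,
#'   `negligible`, `hit`, `pseudocount`, `n_plus`, `n_minus`.
#' @export
screen_from_records <- function(records, params = pict_params(),
                                test_on = c("score", "area")) {
  test_on <- match.arg(test_on)
  need <- c("strain", "condition", "field_index", "A_inter", "A_red", "s")
  stop_if(!all(need %in% names(records)),
          paste("'records' needs columns:", paste(need, collapse = ", ")))
  col <- if (test_on == "score") "s" else "A_inter"
  rows <- lapply(unique(records$strain), function(st) {
    rec <- records[records$strain == st, , drop = FALSE]
    plus <- rec[rec$condition == "plusRAP", , drop = FALSE]
    minus <- rec[rec$condition == "minusRAP", , drop = FALSE]
    if (nrow(plus) < 2 || nrow(minus) < 2) {
      warning(sprintf("strain %s skipped: needs >= 2 fields per condition", st),
              call. = FALSE)
      return(NULL)
    }
    w <- welch_screen(plus[[col]], minus[[col]])
    rr <- recruitment_ratio(plus, minus)
    data.frame(strain = st, ratio = rr$ratio, t_stat = w$t_stat, df = w$df,
               p = w$p_one_tailed, pseudocount = rr$pseudocount,
               n_plus = nrow(plus), n_minus = nrow(minus))
  })
  tab <- do.call(rbind, rows)
  stop_if(is.null(tab), "no strain had enough fields in both conditions")
  out <- call_hits(tab, p_cut = params$p_cut, min_ratio = params$min_ratio)
  out <- out[, c("strain", "ratio", "t_stat", "df", "p", "log_inv_p",
                 "significant", "negligible", "hit", "pseudocount",
                 "n_plus", "n_minus")]
  rownames(out) <- NULL
  out
}

#' Run the screen from a plate manifest on disk
#'
#' Reads every field named in the manifest, segments both channels with the
#' pipeline defaults, computes per-field colocalization records, and calls
#' hits per strain.
#'
#' @param manifest manifest data.frame (see [read_manifest()]) or a path to
#'   a manifest CSV.
#' @param params a [pict_params()].
#' @param test_on see [screen_from_records()].
#' @return list with `table` (the screen table) and `records` (per-field
#'   records).
#' @export
run_screen <- function(manifest, params = pict_params(),
                       test_on = c("score", "area")) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  records <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    score_field(read_field(manifest[i, ]), params)
  }))
  list(table = screen_from_records(records, params, test_on),
       records = records)
}

#' Simulate and score a synthetic screen without touching disk
#'
#' Streams over the fields of a [sim_screen_config()] one at a time
#' (simulate, segment, score, discard), so full-size screens run in modest
#' memory.
#'
#' @param config a [sim_screen_config()].
#' @param params a [pict_params()].
#' @param test_on see [screen_from_records()].
#' @return list with `table`, `records`, and `truth` (strain, interactor).
#' @export
run_screen_sim <- function(config, params = pict_params(),
                           test_on = c("score", "area")) {
  plan <- screen_plan(config)
  records <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    f <- simulate_planned_field(config, plan[i, ])
    records[[i]] <- score_field(f, params)
  }
  records <- do.call(rbind, records)
  list(table = screen_from_records(records, params, test_on),
       records = records,
       truth = data.frame(strain = config$strain_ids,
                          interactor = config$strain_ids %in%
                            config$interactor_ids))
}
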