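# FRAP quantification: ROI trace extraction, double normalization,
# replicate aggregation (mean +/- SD), and single-exponential recovery fit.

roi_mask <- function(roi, dim) {
  stop_if(!is.list(roi) || !all(c("row", "col", "radius") %in% names(roi)),
          "ROI must be list(row, col, radius)")
  stop_if(roi$row - roi$radius < 1 || roi$row + roi$radius > dim[1] ||
            roi$col - roi$radius < 1 || roi$col + roi$radius > dim[2],
          "ROI extends outside the frame")
  d2 <- outer((seq_len(dim[1]) - roi$row)^2, (seq_len(dim[2]) - roi$col)^2, `+`)
  d2 <= roi$radius^2
}

#' Extract a raw FRAP trace from an image stack
#'
#' Per-frame mean intensity over the bleached-spot ROI, a background ROI
#' (cell-free region) and the whole field. No correction is applied here;
#' see [normalize_frap()].
#'
#' @param stack height x width x frames array (or list of matrices).
#' @param spot_roi,background_roi `list(row, col, radius)` disk ROIs inside
#'   the frame, disjoint from each other.
#' @param bleach_frame 1-based index of the last pre-bleach frame.
#' @param frame_interval seconds per frame (builds the time axis).
#' @return A `frap_trace` (see [simulate_frap_trace()]).
#' @export
extract_trace <- function(stack, spot_roi, background_roi, bleach_frame,
                          frame_interval = 1) {
  if (is.list(stack)) stack <- simplify2array(stack)
  stop_if(!is.array(stack) || length(dim(stack)) != 3L,
          "'stack' must be a height x width x frames array")
  nt <- dim(stack)[3]
  stop_if(nt < 2L, "a FRAP stack needs pre- and post-bleach frames (>= 2)")
  check_scalar(bleach_frame, "bleach_frame", lower = 1, upper = nt - 1,
               integer = TRUE)
  dim2 <- dim(stack)[1:2]
  sm <- roi_mask(spot_roi, dim2)
  bm <- roi_mask(background_roi, dim2)
  stop_if(any(sm & bm), "spot and background ROIs overlap")
  flat <- matrix(stack, prod(dim2), nt)
  structure(list(times = (seq_len(nt) - 1) * frame_interval,
                 spot_intensity = colMeans(flat[as.vector(sm), , drop = FALSE]),
                 background_intensity = colMeans(flat[as.vector(bm), , drop = FALSE]),
                 whole_field_intensity = colMeans(flat),
                 bleach_frame = as.integer(bleach_frame)),
            class = "frap_trace")
}

#' Normalize a FRAP trace
#'
#' Double normalization followed by full-scale rescaling: the
#' background-subtracted spot trace is divided by the background-subtracted
#' whole-field trace (removing acquisition photobleaching), then affinely
#' scaled so the pre-bleach mean is 1 and the first post-bleach point is 0.
#' On this scale the curve reads directly as the recovered fraction of the
#' bleached signal, and its asymptote is the mobile fraction.
#'
#' @param trace a `frap_trace` with at least 2 pre-bleach frames.
#' @return list with `times`, `value` (normalized intensity),
#'   `bleach_frame`, and `post` (logical, post-bleach frames).
#' @export
normalize_frap <- function(trace) {
  stop_if(!inherits(trace, "frap_trace"), "'trace' must be a frap_trace")
  stop_if(trace$bleach_frame < 2, "need at least 2 pre-bleach frames")
  spot <- trace$spot_intensity - trace$background_intensity
  field <- trace$whole_field_intensity - trace$background_intensity
  stop_if(any(field <= 0),
          "whole-field intensity does not exceed background at some frame")
  x <- spot / field
  pre <- seq_len(trace$bleach_frame)
  first_post <- trace$bleach_frame + 1L
  x_pre <- mean(x[pre])
  x0 <- x[first_post]
  stop_if(isTRUE(all.equal(x_pre, x0)),
          "no bleach detected: pre-bleach mean equals first post-bleach value")
  list(times = trace$times, value = (x - x0) / (x_pre - x0),
       bleach_frame = trace$bleach_frame,
       post = seq_along(x) > trace$bleach_frame)
}

#' Aggregate replicate FRAP curves as mean and SD
#'
#' @param curves list (n >= 2) of normalized curves from [normalize_frap()],
#'   all on the identical time grid (no resampling is attempted).
#' @return A `frap_curve`: list with `times`, `mean`, `sd` (pointwise
#'   sample SD), `n`, `bleach_frame`.
#' @export
aggregate_curves <- function(curves) {
  stop_if(length(curves) < 2, "need at least 2 replicate curves")
  times <- curves[[1]]$times
  for (cv in curves) {
    stop_if(!isTRUE(all.equal(cv$times, times)),
            "curves are not on a common time grid")
  }
  vals <- do.call(rbind, lapply(curves, `[[`, "value"))
  structure(list(times = times, mean = colMeans(vals),
                 sd = apply(vals, 2, sd), n = length(curves),
                 bleach_frame = curves[[1]]$bleach_frame),
            class = "frap_curve")
}

#' @export
print.frap_curve <- function(x, ...) {
  cat(sprintf("frap_curve: %d frames, n = %d replicates, final recovery %.3f\n",
              length(x$times), x$n, x$mean[length(x$mean)]))
  invisible(x)
}

#' Fit single-exponential recovery kinetics
#'
#' Least-squares fit of `mobile * (1 - exp(-k_app * t'))` to the
#' post-bleach portion of a normalized FRAP curve, with `t'` measured from
#' the first post-bleach frame, `mobile` bounded to `[0, 1]` and `k_app`
#' to `[0, k_max]`. An essentially flat curve (stable complex) fits
#' `mobile ~ 0` with an unidentifiable rate; an instantaneous full recovery
#' drives `k_app` to the bound.
#'
#' @param curve a `frap_curve` (or a single normalized curve) with at least
#'   5 post-bleach points.
#' @param k_max upper bound for the apparent rate, 1/s.
#' @return A `recovery_fit` list: `k_app` (1/s), `mobile_fraction`, `rss`.
#' @export
fit_recovery <- function(curve, k_max = 10) {
  y_all <- if (inherits(curve, "frap_curve")) curve$mean else curve$value
  post <- seq_along(y_all) > curve$bleach_frame
  stop_if(sum(post) < 5, "need at least 5 post-bleach points")
  t_post <- curve$times[post] - curve$times[which(post)[1]]
  y <- y_all[post]
  dat <- data.frame(t = t_post, y = y)
  starts <- list(list(mobile = 0.5, k = 0.01), list(mobile = 0.9, k = 0.1),
                 list(mobile = 0.1, k = 0.001))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ mobile * (1 - exp(-k * t)), data = dat,
                        start = st, lower = c(0, 0), upper = c(1, k_max),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(resid(fit)^2)
      if (is.null(best) || rss < best$rss) {
        cf <- coef(fit)
        best <- list(k_app = unname(cf["k"]),
                     mobile_fraction = unname(cf["mobile"]), rss = rss)
      }
    }
  }
  if (is.null(best)) {
    # flat or degenerate curves have an unidentifiable rate and defeat the
    # gradient-based fit; fall back to bounded direct minimization from the
    # best point of a coarse grid
    rss_fn <- function(p) sum((y - p[1] * (1 - exp(-p[2] * t_post)))^2)
    grid <- expand.grid(mobile = seq(0, 1, 0.1),
                        k = c(1e-6, 10^seq(-4, log10(k_max), length.out = 20)))
    rss <- vapply(seq_len(nrow(grid)), function(i)
      rss_fn(c(grid$mobile[i], grid$k[i])), 0)
    i0 <- which.min(rss)
    opt <- tryCatch(
      stats::optim(c(grid$mobile[i0], grid$k[i0]), rss_fn,
                   method = "L-BFGS-B", lower = c(0, 0), upper = c(1, k_max)),
      error = function(e) NULL)
    if (is.null(opt)) {
      stop(sprintf("recovery fit did not converge (best grid rss = %.4g)",
                   min(rss)), call. = FALSE)
    }
    best <- list(k_app = opt$par[2], mobile_fraction = opt$par[1],
                 rss = opt$value)
  }
  structure(best, class = "recovery_fit")
}

#' Simulate, normalize and aggregate a replicate FRAP experiment
#'
#' Convenience wrapper for the full FRAP arm: simulates `n` replicate
#' traces from one kinetic configuration (distinct derived seeds),
#' normalizes each, and aggregates them as mean +/- SD.
#'
#' @param config a [frap_sim_config()]; its seed acts as the master seed.
#' @param n number of replicates (>= 2).
#' @return A `frap_curve`.
#' @export
simulate_frap_experiment <- function(config, n = 12) {
  check_scalar(n, "n", lower = 2, integer = TRUE)
  curves <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, "frap-replicate", i)
    normalize_frap(simulate_frap_trace(cfg))
  })
  aggregate_curves(curves)
}
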