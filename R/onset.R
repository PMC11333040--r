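## The onset-temperature statistic: the temperature where the hydrated
## sample's curve deviates from the dry sample's.  Differencing against the
## dry companion removes hydration-independent anharmonicity (e.g. methyl
## rotations) before any onset is estimated.

#' Difference curve between hydrated and dry series
#'
#' Both series are linearly interpolated onto the coarser of the two
#' temperature grids, restricted to the overlapping range.  For intensity
#' series the difference is `dry - hydrated` (the hydration-induced drop
#' grows positive); for MSD series it is `hydrated - dry`.
#'
#' @param hydrated,dry Two [summed_series()] or two [msd_series()].
#' @return A list of class `difference_series` with `temperatures`, `values`
#'   and the orientation used.
#' @export
difference_curve <- function(hydrated, dry) {
  if (!identical(class(hydrated), class(dry))) {
    stop("hydrated and dry series must be of the same type", call. = FALSE)
  }
  is_msd <- inherits(hydrated, "msd_series")
  yh <- if (is_msd) hydrated$msd else hydrated$values
  yd <- if (is_msd) dry$msd else dry$values
  th <- hydrated$temperatures
  td <- dry$temperatures
  lo <- max(min(th), min(td))
  hi <- min(max(th), max(td))
  if (hi <= lo) stop("temperature ranges do not overlap", call. = FALSE)
  # coarser grid = larger median spacing
  base <- if (stats::median(diff(th)) >= stats::median(diff(td))) th else td
  grid <- base[base >= lo & base <= hi]
  if (length(grid) < 10L) {
    stop("fewer than 10 overlapping temperature points", call. = FALSE)
  }
  vh <- stats::approx(th, yh, xout = grid)$y
  vd <- stats::approx(td, yd, xout = grid)$y
  d <- if (is_msd) vh - vd else vd - vh
  structure(
    list(temperatures = grid, values = d,
         orientation = if (is_msd) "hydrated - dry" else "dry - hydrated",
         provenance = c(hydrated = hydrated$provenance, dry = dry$provenance)),
    class = "difference_series"
  )
}

# Continuous two-segment (hinge) fit with breakpoint tb:
# y = c0 [+ c1 (T - tb)] + c2 max(0, T - tb).  Returns SSE and internals.
.bilinear_fit <- function(tt, y, tb, constrain_first) {
  hinge <- pmax(0, tt - tb)
  X <- if (constrain_first) cbind(1, hinge) else cbind(1, tt - tb, hinge)
  fit <- stats::.lm.fit(X, y)
  list(sse = sum(fit$residuals^2), coef = fit$coefficients,
       fitted = y - fit$residuals, residuals = fit$residuals)
}

# Stage-2 search: grid over candidates inside [tb0 - W/2, tb0 + W/2] on the
# windowed data, then continuous refinement between the neighbours of the
# best grid point.  Returns the refined breakpoint and its local fit.
.bilinear_local <- function(tt, y, tb0, window_K, constrain_first,
                            min_seg_points) {
  sel <- abs(tt - tb0) <= window_K
  tl <- tt[sel]
  yl <- y[sel]
  nl <- length(tl)
  idx <- seq_len(nl)
  ok <- abs(tl - tb0) <= window_K / 2 &
    idx >= min_seg_points & (nl - idx + 1L) >= min_seg_points
  cand <- idx[ok]
  if (!length(cand)) cand <- which.min(abs(tl - tb0))
  sses <- vapply(tl[cand], function(tb)
    .bilinear_fit(tl, yl, tb, constrain_first)$sse, numeric(1))
  best <- cand[which.min(sses)]
  lo <- tl[max(best - 1L, 1L)]
  hi <- tl[min(best + 1L, nl)]
  tb <- if (hi > lo) {
    stats::optimize(function(b) .bilinear_fit(tl, yl, b, constrain_first)$sse,
                    c(lo, hi), tol = 1e-6)$minimum
  } else tl[best]
  # keep the grid point if refinement did not improve (flat SSE valley)
  if (.bilinear_fit(tl, yl, tb, constrain_first)$sse >
      .bilinear_fit(tl, yl, tl[best], constrain_first)$sse) {
    tb <- tl[best]
  }
  list(t_on = tb, fit = .bilinear_fit(tl, yl, tb, constrain_first),
       temperatures = tl, values = yl)
}

#' Detect the onset temperature of a difference curve
#'
#' Two estimators:
#' \describe{
#'   \item{bilinear}{Continuous two-segment linear fit.  Stage 1 is an
#'     exhaustive grid search of the breakpoint over interior sample
#'     points (each candidate must have at least `min_margin_K` of data
#'     and `min_seg_points` points on both sides), minimizing total SSE.
#'     Stage 2 refits inside a window of `refine_window_K` around the
#'     stage-1 breakpoint and refines it continuously; the local refit
#'     keeps the estimate from being dragged by curvature far from the
#'     break (the post-onset difference curve is only locally linear).
#'     The first segment's slope can be constrained to 0.  Ties go to the
#'     lower temperature.}
#'   \item{threshold}{First temperature where the difference exceeds
#'     `k` times the baseline noise (sd over the lowest-quartile
#'     temperature window) for `m` consecutive points.}
#' }
#'
#' @param d A `difference_series` from [difference_curve()].
#' @param method `"bilinear"` (default) or `"threshold"`.
#' @param constrain_first Logical, bilinear only: force the pre-onset
#'   segment flat. Default `FALSE`.
#' @param k,m Threshold parameters (defaults 3 and 3).
#' @param min_margin_K Minimum data span required on each side of a
#'   stage-1 candidate breakpoint, K. Default 30.
#' @param min_seg_points Minimum points per segment. Default 3.
#' @param refine_window_K Half-width of the stage-2 local refit window, K.
#'   `Inf` disables the local stage (pure global grid search). Default 40.
#' @return An [onset_result()]; its `details` carry the fit internals the
#'   bootstrap needs.
#' @export
detect_onset <- function(d, method = c("bilinear", "threshold"),
                         constrain_first = FALSE, k = 3, m = 3,
                         min_margin_K = 30, min_seg_points = 3,
                         refine_window_K = 40) {
  method <- match.arg(method)
  tt <- d$temperatures
  y <- d$values
  n <- length(tt)
  if (method == "bilinear") {
    idx <- seq_len(n)
    ok <- (tt - tt[1]) >= min_margin_K & (tt[n] - tt) >= min_margin_K &
      idx >= min_seg_points & (n - idx + 1L) >= min_seg_points
    cand <- idx[ok]
    if (!length(cand)) stop("no onset detected: no admissible breakpoint",
                            call. = FALSE)
    sses <- vapply(cand, function(i)
      .bilinear_fit(tt, y, tt[i], constrain_first)$sse, numeric(1))
    best <- cand[which.min(sses)]  # which.min takes the first = lowest T
    tb0 <- tt[best]
    if (is.finite(refine_window_K) && refine_window_K > 0) {
      loc <- .bilinear_local(tt, y, tb0, refine_window_K, constrain_first,
                             min_seg_points)
    } else {
      loc <- list(t_on = tb0, fit = .bilinear_fit(tt, y, tb0, constrain_first),
                  temperatures = tt, values = y)
    }
    onset_result(
      t_on = loc$t_on, method = "bilinear", sse = loc$fit$sse, n_points = n,
      details = list(coef = loc$fit$coef, fitted = loc$fit$fitted,
                     residuals = loc$fit$residuals,
                     local_temperatures = loc$temperatures,
                     grid_breakpoint = tb0,
                     constrain_first = constrain_first,
                     min_margin_K = min_margin_K,
                     min_seg_points = min_seg_points,
                     refine_window_K = refine_window_K)
    )
  } else {
    base_hi <- tt[1] + 0.25 * (tt[n] - tt[1])
    base <- y[tt <= base_hi]
    sigma <- stats::sd(base)
    if (!is.finite(sigma)) sigma <- 0
    thr <- k * sigma
    above <- y > thr
    run <- 0L
    hit <- NA_integer_
    for (i in seq_len(n)) {
      run <- if (above[i]) run + 1L else 0L
      if (run >= m) { hit <- i - m + 1L; break }
    }
    if (is.na(hit) || hit == 1L || hit == n) {
      stop("no onset detected: threshold never exceeded for ", m,
           " consecutive points", call. = FALSE)
    }
    onset_result(t_on = tt[hit], method = "threshold", sse = NA_real_,
                 n_points = n,
                 details = list(k = k, m = m, sigma_baseline = sigma))
  }
}

#' Residual-resampling bootstrap interval for the bilinear breakpoint
#'
#' Resamples the residuals of the accepted local bilinear fit with
#' replacement, re-runs the breakpoint search (local stage + continuous
#' refinement) on each synthetic curve, and returns the percentile 95%
#' interval of the breakpoint draws.
#'
#' @param d A `difference_series`.
#' @param n_boot Number of bootstrap replicates (warning below 100).
#' @param seed Integer seed (required; identical seeds give identical
#'   intervals).
#' @param ... Passed to [detect_onset()] (bilinear parameters).
#' @return Named numeric `c(ci_low, ci_high)` in K, with the bootstrap
#'   breakpoint draws attached as attribute `"draws"`.
#' @export
bootstrap_onset <- function(d, n_boot = 500, seed = 1, ...) {
  if (n_boot < 100) warning("n_boot < 100 gives unstable intervals", call. = FALSE)
  fit <- detect_onset(d, method = "bilinear", ...)
  det <- fit$details
  tl <- det$local_temperatures
  fitted <- det$fitted
  res <- det$residuals
  W <- det$refine_window_K
  if (!is.finite(W)) W <- diff(range(tl))
  draws <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      yb <- fitted + sample(res, length(res), replace = TRUE)
      .bilinear_local(tl, yb, fit$t_on, W, det$constrain_first,
                      det$min_seg_points)$t_on
    }, numeric(1))
  })
  ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  structure(c(ci_low = ci[1], ci_high = ci[2]), draws = draws)
}
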