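## Glass-transition midpoint extraction from DSC thermograms: two linear
## baselines fitted below and above the step, and T_DSC taken where the
## heat-flow curve crosses the mean of the extrapolated baselines (for a
## symmetric step this is exactly the equal-area construction).

#' Fit linear baselines below and above a DSC step
#'
#' @param curve A [dsc_curve()].
#' @param low_window,high_window Length-2 numeric temperature windows, K.
#'   Must be disjoint, with the low window entirely below the high one,
#'   and contain at least 5 points each. Defaults `c(160, 190)` and
#'   `c(260, 290)`.
#' @return List with `low` and `high` baselines (each `(intercept mW,
#'   slope mW/K)`) and the pooled residual sd `noise_sd`.
#' @export
fit_baselines <- function(curve, low_window = c(160, 190),
                          high_window = c(260, 290)) {
  stopifnot(inherits(curve, "dsc_curve"))
  if (low_window[2] >= high_window[1]) {
    stop("baseline windows must be disjoint with low below high", call. = FALSE)
  }
  fit_one <- function(win) {
    sel <- curve$temperatures >= win[1] & curve$temperatures <= win[2]
    if (sum(sel) < 5L) stop("baseline window has fewer than 5 points", call. = FALSE)
    f <- stats::lm(curve$heat_flow[sel] ~ curve$temperatures[sel])
    list(coef = c(unname(stats::coef(f)[1]), unname(stats::coef(f)[2])),
         resid = stats::residuals(f))
  }
  lo <- fit_one(low_window)
  hi <- fit_one(high_window)
  list(low = lo$coef, high = hi$coef,
       noise_sd = stats::sd(c(lo$resid, hi$resid)),
       low_window = low_window, high_window = high_window)
}

#' Extract the glass-transition midpoint from a DSC curve
#'
#' `T_DSC` is the temperature where the heat-flow curve crosses the mean
#' of the two extrapolated baselines, found by linear interpolation
#' between the bracketing samples inside the inter-baseline gap.  The
#' step height is the baseline separation at `T_DSC`.
#'
#' @param curve A [dsc_curve()].
#' @param baselines Result of [fit_baselines()]; computed with default
#'   windows when omitted.
#' @param min_sep_factor The extrapolated baselines must be separated by
#'   more than this multiple of the baseline noise sd in the gap region,
#'   else there is no transition. Default 3.
#' @return A [dsc_result()].
#' @export
detect_tdsc <- function(curve, baselines = NULL, min_sep_factor = 3) {
  stopifnot(inherits(curve, "dsc_curve"))
  if (is.null(baselines)) baselines <- fit_baselines(curve)
  tt <- curve$temperatures
  gap <- tt > baselines$low_window[2] & tt < baselines$high_window[1]
  if (!any(gap)) stop("no transition: empty gap between baseline windows",
                      call. = FALSE)
  lo <- baselines$low[1] + baselines$low[2] * tt
  hi <- baselines$high[1] + baselines$high[2] * tt
  sep <- abs(hi - lo)[gap]
  noise <- baselines$noise_sd
  if (!is.finite(noise)) noise <- 0
  # floor at machine precision of the heat-flow scale: two fits of the same
  # line differ by rounding, which is not a step
  floor_mW <- sqrt(.Machine$double.eps) * max(abs(curve$heat_flow), 1)
  if (max(sep) <= max(min_sep_factor * noise, floor_mW)) {
    stop("no transition: baselines not separated beyond noise", call. = FALSE)
  }
  mid <- (lo + hi) / 2
  g <- (curve$heat_flow - mid)[gap]
  tg <- tt[gap]
  sgn <- sign(g)
  cross <- which(sgn[-1] * sgn[-length(sgn)] <= 0 & sgn[-1] != sgn[-length(sgn)])
  if (!length(cross)) {
    # allow an exact zero hit
    z <- which(g == 0)
    if (length(z)) {
      t_dsc <- tg[z[1]]
    } else {
      stop("no transition: curve never crosses the baseline midline", call. = FALSE)
    }
  } else {
    i <- cross[1]
    # linear interpolation between the bracketing samples
    t_dsc <- tg[i] - g[i] * (tg[i + 1] - tg[i]) / (g[i + 1] - g[i])
  }
  step <- abs((baselines$high[1] + baselines$high[2] * t_dsc) -
              (baselines$low[1] + baselines$low[2] * t_dsc))
  dsc_result(t_dsc = t_dsc, baseline_low = baselines$low,
             baseline_high = baselines$high, step_height = step)
}
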