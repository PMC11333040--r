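## Normalization to the low-temperature baseline, q-summation, and
## Gaussian-approximation MSD extraction.

#' Normalize a scan to its low-temperature baseline
#'
#' Each q column is divided by its mean intensity over the base-temperature
#' window, so that intensities near the lowest measured temperatures map
#' to ~1.  This is the standard normalization of elastic fixed-window
#' scans to the ~10 K harmonic reference.
#'
#' @param scan An [elastic_scan()].
#' @param base_window Length-2 numeric, the (closed) temperature window in K
#'   whose mean defines the baseline. Default `c(0, 20)`.
#' @return The normalized [elastic_scan()] (errors scaled accordingly).
#' @export
normalize_to_base <- function(scan, base_window = c(0, 20)) {
  stopifnot(inherits(scan, "elastic_scan"), length(base_window) == 2L)
  in_base <- scan$temperatures >= base_window[1] & scan$temperatures <= base_window[2]
  if (!any(in_base)) {
    stop("no temperatures inside the base window", call. = FALSE)
  }
  base <- colMeans(scan$intensities[in_base, , drop = FALSE])
  if (any(base <= 0)) stop("zero base-window mean in a q column", call. = FALSE)
  out <- scan
  out$intensities <- sweep(scan$intensities, 2, base, "/")
  if (!is.null(scan$intensity_errors)) {
    out$intensity_errors <- sweep(scan$intensity_errors, 2, base, "/")
  }
  out$normalized <- TRUE
  out$meta$base_window <- base_window
  out
}

#' Sum a normalized scan over a q range
#'
#' The per-temperature "q-summed" elastic intensity: the mean of the
#' normalized q columns with q in the closed interval `q_range`.  Mean
#' rather than sum so the series stays comparable across instruments with
#' different q grids (the two differ by a constant that the normalization
#' makes irrelevant).
#'
#' @param scan A normalized [elastic_scan()].
#' @param q_range Length-2 numeric, default `c(0.45, 1.75)` (1/Angstrom).
#' @return A [summed_series()].
#' @export
sum_over_q <- function(scan, q_range = c(0.45, 1.75)) {
  stopifnot(inherits(scan, "elastic_scan"))
  if (!scan$normalized) {
    stop("scan must be normalized before q-summation (normalize_to_base)",
         call. = FALSE)
  }
  sel <- scan$q_values >= q_range[1] & scan$q_values <= q_range[2]
  if (sum(sel) < 2L) stop("fewer than 2 q points inside q_range", call. = FALSE)
  summed_series(
    temperatures = scan$temperatures,
    values = rowMeans(scan$intensities[, sel, drop = FALSE]),
    q_range = q_range,
    provenance = sprintf("%s|%s|h=%g|dt=%g", scan$sample_id, scan$state,
                         scan$hydration_h, scan$resolution_time)
  )
}

#' Gaussian-approximation mean-squared displacement
#'
#' At each temperature, ordinary least squares of `ln S` on `q^2` over the
#' fit range; under the Gaussian approximation
#' `S(q) = exp(-q^2 <x^2> / 6)` the MSD is `-6 x slope`.  The intercept is
#' left free so EISF curvature is absorbed rather than biasing the slope.
#'
#' @param scan A normalized [elastic_scan()].
#' @param q_range Fit range, default `c(0.45, 0.9)` (1/Angstrom).
#' @return An [msd_series()]; temperatures where any intensity in range is
#'   non-positive get `NA` MSD.
#' @export
gaussian_msd <- function(scan, q_range = c(0.45, 0.9)) {
  stopifnot(inherits(scan, "elastic_scan"))
  if (!scan$normalized) {
    stop("scan must be normalized before MSD extraction", call. = FALSE)
  }
  sel <- scan$q_values >= q_range[1] & scan$q_values <= q_range[2]
  if (sum(sel) < 3L) stop("fewer than 3 q points inside q_range", call. = FALSE)
  q2 <- scan$q_values[sel]^2
  X <- cbind(1, q2)
  n_t <- length(scan$temperatures)
  msd <- rep(NA_real_, n_t)
  r2 <- rep(NA_real_, n_t)
  for (i in seq_len(n_t)) {
    s <- scan$intensities[i, sel]
    if (any(s <= 0)) next  # flagged: MSD undefined at this temperature
    y <- log(s)
    fit <- stats::.lm.fit(X, y)
    msd[i] <- -6 * fit$coefficients[2]
    ss_tot <- sum((y - mean(y))^2)
    r2[i] <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
  }
  msd_series(scan$temperatures, msd, fit_q_range = q_range, r_squared = r2,
             provenance = sprintf("%s|%s|h=%g|dt=%g", scan$sample_id,
                                  scan$state, scan$hydration_h,
                                  scan$resolution_time))
}
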