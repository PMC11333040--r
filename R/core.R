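#' @keywords internal
"_PACKAGE"

## Physical constants ---------------------------------------------------------

#' Gas constant, J/(mol K)
#'
#' Used to convert Arrhenius slopes (K) into molar activation energies.
#' @export
R_GAS <- 8.314462

#' hbar in spectroscopic units, ueV ps
#'
#' Energy-time conversion factor for the fallback resolution mapping
#' `alpha * hbar / dE`.
#' @export
HBAR_UEV_PS <- 658.2

# Printed energy <-> time correspondences for the backscattering
# spectrometers the elastic scans come from (HFBS, DNA, OSIRIS).  These are
# the canonical values; they are deliberately NOT hbar/dE (instrument
# resolution functions are not pure Lorentzians), so a lookup table is
# authoritative and the formula only a fallback.
.RESOLUTION_LOOKUP <- data.frame(
  energy_ueV = c(1, 13, 25.4, 100),
  time_ps    = c(1000, 80, 40, 10)
)

## Arrhenius primitives -------------------------------------------------------

#' Arrhenius relaxation time
#'
#' Evaluates the Arrhenius law `tau(T) = tau0 * exp(dU / (R T))` for a
#' thermally activated relaxation process.
#'
#' @param temperature Temperature(s), K. Must be positive.
#' @param delta_u Activation energy, kJ/mol. Must be non-negative.
#' @param tau0 Pre-exponential (infinite-temperature) time, ps. Positive.
#' @return Relaxation time(s) in ps, same length as `temperature`.
#' @examples
#' arrhenius_tau(250, delta_u = 38, tau0 = 1.15e-7)
#' @export
arrhenius_tau <- function(temperature, delta_u, tau0) {
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("`temperature` must be positive and finite", call. = FALSE)
  }
  if (!is.finite(tau0) || tau0 <= 0) {
    stop("`tau0` must be positive", call. = FALSE)
  }
  if (!is.finite(delta_u) || delta_u < 0) {
    stop("`delta_u` must be non-negative", call. = FALSE)
  }
  tau0 * exp(delta_u * 1000 / (R_GAS * temperature))
}

#' Map an instrument energy resolution to its resolution time
#'
#' The four canonical backscattering resolutions 1, 13, 25.4 and 100 ueV map
#' to their published resolution times 1000, 80, 40 and 10 ps exactly.  Any
#' other energy falls back to `alpha * hbar / dE` with `hbar = 658.2 ueV ps`.
#'
#' @param energy_ueV Energy resolution (FWHM), ueV. Positive.
#' @param alpha Dimensionless scale for the fallback formula. Default 1.
#' @return Resolution time, ps.
#' @examples
#' resolution_to_time(1)    # 1000 ps
#' resolution_to_time(100)  # 10 ps
#' @export
resolution_to_time <- function(energy_ueV, alpha = 1) {
  if (any(!is.finite(energy_ueV)) || any(energy_ueV <= 0)) {
    stop("`energy_ueV` must be positive", call. = FALSE)
  }
  vapply(energy_ueV, function(e) {
    hit <- which(abs(.RESOLUTION_LOOKUP$energy_ueV - e) < 1e-9)
    if (length(hit) == 1L) .RESOLUTION_LOOKUP$time_ps[hit] else alpha * HBAR_UEV_PS / e
  }, numeric(1))
}

## ElasticScan ----------------------------------------------------------------

#' Construct an elastic fixed-window scan
#'
#' Container for the elastic intensity `S(q, dt)` on a temperature x q grid,
#' with the sample metadata (component, hydration, instrument resolution)
#' that the downstream analysis keys on.
#'
#' @param sample_id Character label for the sample.
#' @param component `"protein"` or `"water"` — which component dominates the
#'   incoherent signal (set by the isotope-labelling scheme).
#' @param state `"dry"` or `"hydrated"`.
#' @param hydration_h Hydration level, g water / g protein (>= 0).
#' @param resolution_time Instrument resolution time, ps (> 0).
#' @param temperatures Strictly increasing temperature grid, K.
#' @param q_values Strictly increasing scattering-vector grid, 1/Angstrom.
#' @param intensities Matrix `[temperature, q]` of elastic intensities (>= 0).
#' @param intensity_errors Optional matrix of 1-sigma errors, same shape.
#' @param resolution_energy Optional energy resolution, ueV.
#' @param normalized Logical; TRUE once the scan is normalized to its
#'   low-temperature baseline.
#' @param meta Optional named list of provenance metadata (e.g. seeds).
#' @return An object of class `elastic_scan`.
#' @export
elastic_scan <- function(sample_id, component, state, hydration_h,
                         resolution_time, temperatures, q_values, intensities,
                         intensity_errors = NULL, resolution_energy = NULL,
                         normalized = FALSE, meta = list()) {
  component <- match.arg(component, c("protein", "water"))
  state <- match.arg(state, c("dry", "hydrated"))
  stopifnot(is.numeric(hydration_h), length(hydration_h) == 1L, hydration_h >= 0)
  if (!is.numeric(resolution_time) || resolution_time <= 0) {
    stop("`resolution_time` must be a positive number of ps", call. = FALSE)
  }
  temperatures <- as.numeric(temperatures)
  q_values <- as.numeric(q_values)
  if (length(temperatures) < 2L || any(diff(temperatures) <= 0)) {
    stop("`temperatures` must be strictly increasing", call. = FALSE)
  }
  if (length(q_values) < 1L || any(diff(q_values) <= 0)) {
    stop("`q_values` must be strictly increasing", call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  if (!all(dim(intensities) == c(length(temperatures), length(q_values)))) {
    stop("`intensities` must be |temperatures| x |q_values|", call. = FALSE)
  }
  if (any(intensities < 0)) stop("intensities must be >= 0", call. = FALSE)
  if (!is.null(intensity_errors)) {
    intensity_errors <- as.matrix(intensity_errors)
    if (!all(dim(intensity_errors) == dim(intensities))) {
      stop("`intensity_errors` must match the intensity matrix shape", call. = FALSE)
    }
    if (any(intensity_errors < 0)) stop("intensity errors must be >= 0", call. = FALSE)
  }
  structure(
    list(
      sample_id = as.character(sample_id), component = component,
      state = state, hydration_h = hydration_h,
      resolution_energy = resolution_energy,
      resolution_time = resolution_time,
      temperatures = temperatures, q_values = q_values,
      intensities = intensities, intensity_errors = intensity_errors,
      normalized = isTRUE(normalized), meta = meta
    ),
    class = "elastic_scan"
  )
}

#' @export
print.elastic_scan <- function(x, ...) {
  cat(sprintf(
    "<elastic_scan> %s [%s, %s] h = %.2f g/g, dt = %g ps\n  %d temperatures (%.0f-%.0f K) x %d q (%.2f-%.2f 1/A)%s\n",
    x$sample_id, x$component, x$state, x$hydration_h, x$resolution_time,
    length(x$temperatures), min(x$temperatures), max(x$temperatures),
    length(x$q_values), min(x$q_values), max(x$q_values),
    if (x$normalized) ", normalized" else ""
  ))
  invisible(x)
}

## Series containers ----------------------------------------------------------

#' Per-temperature series of q-summed normalized elastic intensity
#'
#' @param temperatures Temperature grid, K.
#' @param values Normalized intensity values.
#' @param q_range Length-2 numeric, the q interval summed over.
#' @param provenance Character tag pointing back to the source scan.
#' @return An object of class `summed_series`.
#' @export
summed_series <- function(temperatures, values, q_range, provenance = NA_character_) {
  stopifnot(length(temperatures) == length(values), length(q_range) == 2L)
  structure(
    list(temperatures = as.numeric(temperatures), values = as.numeric(values),
         q_range = as.numeric(q_range), provenance = provenance),
    class = "summed_series"
  )
}

#' Per-temperature mean-squared displacement series
#'
#' @param temperatures Temperature grid, K.
#' @param msd Mean-squared displacement, Angstrom^2 (NA where undefined).
#' @param fit_q_range q interval used in the Gaussian fit.
#' @param r_squared Per-temperature coefficient of determination of the
#'   `ln S` vs `q^2` fit.
#' @param provenance Character tag pointing back to the source scan.
#' @return An object of class `msd_series`.
#' @export
msd_series <- function(temperatures, msd, fit_q_range, r_squared = NULL,
                       provenance = NA_character_) {
  stopifnot(length(temperatures) == length(msd))
  structure(
    list(temperatures = as.numeric(temperatures), msd = as.numeric(msd),
         fit_q_range = as.numeric(fit_q_range),
         r_squared = if (is.null(r_squared)) rep(NA_real_, length(msd)) else as.numeric(r_squared),
         provenance = provenance),
    class = "msd_series"
  )
}

## Result containers ----------------------------------------------------------

#' Onset-detection result
#'
#' @param t_on Detected onset temperature, K.
#' @param method `"bilinear"` or `"threshold"`.
#' @param sse Residual sum of squares of the accepted fit (bilinear) or NA.
#' @param n_points Number of points in the difference series.
#' @param ci_low,ci_high Optional bootstrap 95% interval bounds, K.
#' @param details Optional list of method internals (fit coefficients,
#'   residuals, candidate grid) used by the bootstrap.
#' @return An object of class `onset_result`.
#' @export
onset_result <- function(t_on, method, sse, n_points,
                         ci_low = NA_real_, ci_high = NA_real_, details = list()) {
  structure(
    list(t_on = t_on, method = method, sse = sse, n_points = n_points,
         ci_low = ci_low, ci_high = ci_high, details = details),
    class = "onset_result"
  )
}

#' @export
print.onset_result <- function(x, ...) {
  ci <- if (is.finite(x$ci_low)) sprintf(" [95%% CI %.1f-%.1f K]", x$ci_low, x$ci_high) else ""
  cat(sprintf("<onset_result> T_on = %.1f K (%s)%s, n = %d\n",
              x$t_on, x$method, ci, x$n_points))
  invisible(x)
}

#' Arrhenius fit result
#'
#' @param delta_u Activation energy, kJ/mol.
#' @param tau0 Pre-exponential time, ps.
#' @param slope Arrhenius slope `dU/R`, K.
#' @param points Data frame of fitted `(temperature_K, tau_ps)` points.
#' @param residual_rms RMS residual on the `ln tau` scale.
#' @param assumed_tau_eq_resolution Logical flag: TRUE when the (T, tau)
#'   points were built by identifying the relaxation time at the detected
#'   onset with the instrument resolution time.
#' @return An object of class `arrhenius_fit`.
#' @export
arrhenius_fit <- function(delta_u, tau0, slope, points, residual_rms,
                          assumed_tau_eq_resolution = FALSE) {
  structure(
    list(delta_u = delta_u, tau0 = tau0, slope = slope, points = points,
         residual_rms = residual_rms,
         assumed_tau_eq_resolution = assumed_tau_eq_resolution),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> dU = %.2f kJ/mol, tau0 = %.3g ps (slope %.1f K, %d points, rms(ln tau) = %.3g)\n",
    x$delta_u, x$tau0, x$slope, nrow(x$points), x$residual_rms))
  if (isTRUE(x$assumed_tau_eq_resolution)) {
    cat("  assumption: tau(T_on) = instrument resolution time\n")
  }
  invisible(x)
}

#' DSC thermogram
#'
#' @param temperatures Strictly increasing temperature grid, K.
#' @param heat_flow Heat flow, mW.
#' @param heating_rate Heating rate, K/min (metadata; default 1).
#' @param sample_id Character label.
#' @param meta Optional named list of provenance metadata.
#' @return An object of class `dsc_curve`.
#' @export
dsc_curve <- function(temperatures, heat_flow, heating_rate = 1,
                      sample_id = NA_character_, meta = list()) {
  temperatures <- as.numeric(temperatures)
  if (any(diff(temperatures) <= 0)) {
    stop("DSC temperatures must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(temperatures) == length(heat_flow))
  structure(
    list(temperatures = temperatures, heat_flow = as.numeric(heat_flow),
         heating_rate = heating_rate, sample_id = as.character(sample_id),
         meta = meta),
    class = "dsc_curve"
  )
}

#' DSC glass-transition midpoint result
#'
#' @param t_dsc Midpoint temperature, K.
#' @param baseline_low,baseline_high Length-2 numeric `(intercept mW, slope
#'   mW/K)` of the fitted low/high-temperature baselines.
#' @param step_height Baseline separation at `t_dsc`, mW.
#' @return An object of class `dsc_result`.
#' @export
dsc_result <- function(t_dsc, baseline_low, baseline_high, step_height) {
  structure(
    list(t_dsc = t_dsc, baseline_low = baseline_low,
         baseline_high = baseline_high, step_height = step_height),
    class = "dsc_result"
  )
}

#' @export
print.dsc_result <- function(x, ...) {
  cat(sprintf("<dsc_result> T_DSC = %.1f K, step height = %.3g mW\n",
              x$t_dsc, x$step_height))
  invisible(x)
}
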