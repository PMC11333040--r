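## Synthetic elastic scans and DSC thermograms.
##
## Two forward models generate the study conditions the analysis is designed
## to discriminate:
##   * water_model(): NO transition — a single thermally activated relaxation
##     whose time tau(T) follows the Arrhenius law.  Any onset seen in its
##     elastic intensity is created by tau(T) crossing the instrument
##     resolution time (a resolution effect).
##   * protein_model(): a TRUE transition — a hydration-dependent kink
##     temperature T_g(h) above which anharmonic mean-squared displacement
##     grows, independent of the instrument resolution.

#' Hydration-water forward model (resolution-effect scenario)
#'
#' Parameters of the noiseless kernel
#' `I(q, T) = exp(-q^2 vib_slope T / 6) * [A0 + (1 - A0) exp(-dt / tau(T))]`
#' with `tau(T)` Arrhenius.  The default `tau0` is chosen so that
#' `tau(250 K) = 10 ps`, anchoring the relaxation map to the fastest
#' instrument window.
#'
#' @param delta_u Activation energy, kJ/mol. Default 38.
#' @param tau0 Pre-exponential time, ps. Default solves `tau(250) = 10 ps`.
#' @param eisf_a0 Elastic incoherent structure factor plateau A0 in (0, 1).
#' @param vib_slope Harmonic (Debye-Waller) MSD slope, Angstrom^2/K.
#' @param noise_sigma Relative sd of multiplicative Gaussian noise.
#' @return An object of class `water_model`.
#' @export
water_model <- function(delta_u = 38,
                        tau0 = 10 / exp(delta_u * 1000 / (R_GAS * 250)),
                        eisf_a0 = 0.7, vib_slope = 1.5e-3,
                        noise_sigma = 0.005) {
  stopifnot(eisf_a0 > 0, eisf_a0 < 1, tau0 > 0, delta_u >= 0,
            vib_slope >= 0, noise_sigma >= 0)
  structure(list(delta_u = delta_u, tau0 = tau0, eisf_a0 = eisf_a0,
                 vib_slope = vib_slope, noise_sigma = noise_sigma),
            class = "water_model")
}

#' Protein forward model (intrinsic-transition scenario)
#'
#' The hydrated protein's MSD is harmonic below a hydration-dependent
#' glass-transition-like temperature `T_g(h)` and gains an anharmonic
#' contribution above it:
#' `MSD(T) = vib_slope * T + anh_slope * max(0, T - T_g(h))`,
#' with `T_g(h)` linearly interpolated between anchor points.  The dry
#' companion keeps `anh_slope = 0`.  Default anchors (0.2, 248 K) and
#' (0.4, 228 K) describe a CYP-like globular protein.
#'
#' @param tg_anchors Data frame or 2-column matrix of `(h, T_g)` anchor
#'   pairs; `T_g` must strictly decrease with `h`.
#' @param vib_slope Harmonic MSD slope, Angstrom^2/K.
#' @param anh_slope Anharmonic MSD slope above `T_g`, Angstrom^2/K.
#' @param noise_sigma Relative sd of multiplicative Gaussian noise.
#' @return An object of class `protein_model`.
#' @export
protein_model <- function(tg_anchors = data.frame(h = c(0.2, 0.4),
                                                  t_g = c(248, 228)),
                          vib_slope = 1.5e-3, anh_slope = 5e-3,
                          noise_sigma = 0.005) {
  tg_anchors <- as.data.frame(tg_anchors)
  names(tg_anchors) <- c("h", "t_g")
  if (nrow(tg_anchors) < 1L) stop("`tg_anchors` must not be empty", call. = FALSE)
  tg_anchors <- tg_anchors[order(tg_anchors$h), , drop = FALSE]
  if (nrow(tg_anchors) > 1L && any(diff(tg_anchors$t_g) >= 0)) {
    stop("T_g must strictly decrease with hydration across anchors", call. = FALSE)
  }
  stopifnot(vib_slope >= 0, anh_slope >= 0, noise_sigma >= 0)
  structure(list(tg_anchors = tg_anchors, vib_slope = vib_slope,
                 anh_slope = anh_slope, noise_sigma = noise_sigma),
            class = "protein_model")
}

#' Kink temperature T_g at a hydration level
#'
#' Linear interpolation between the model's anchors; constant extrapolation
#' outside their hull, with a warning.
#'
#' @param model A [protein_model()].
#' @param h Hydration level, g/g.
#' @return T_g in K.
#' @export
protein_tg <- function(model, h) {
  a <- model$tg_anchors
  if (nrow(a) == 1L) return(a$t_g)
  if (h < min(a$h) || h > max(a$h)) {
    warning(sprintf("h = %.2f outside anchor hull [%.2f, %.2f]; extrapolating flat",
                    h, min(a$h), max(a$h)), call. = FALSE)
  }
  stats::approx(a$h, a$t_g, xout = h, rule = 2)$y
}

# Multiplicative noise applied under a caller-supplied seed; the seed is a
# hard requirement whenever noise_sigma > 0 so every scan is reproducible.
.apply_noise <- function(intensity, noise_sigma, seed) {
  if (noise_sigma == 0) return(intensity)
  if (is.null(seed)) {
    stop("a `seed` is required when noise_sigma > 0 (reproducibility contract)",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    intensity * (1 + matrix(stats::rnorm(length(intensity), sd = noise_sigma),
                            nrow = nrow(intensity)))
  })
}

.default_temperatures <- function() seq(10, 300, by = 2)
.default_q <- function() seq(0.3, 1.8, by = 0.05)

#' Simulate an elastic scan of hydration water
#'
#' Noiseless kernel
#' `I(q, T) = exp(-q^2 vib_slope T / 6) * [A0 + (1 - A0) exp(-dt / tau(T))]`;
#' the dry companion (obtained with `state = "dry"`) carries the
#' Debye-Waller factor only.  Multiplicative Gaussian noise of relative sd
#' `noise_sigma` is applied under `seed`.
#'
#' @param model A [water_model()].
#' @param resolution_time Instrument resolution time dt, ps.
#' @param temperatures,q_values Measurement grids (increasing).
#' @param seed Integer seed for the noise (required when noisy).
#' @param state `"hydrated"` (relaxation active) or `"dry"` (Debye-Waller
#'   only).
#' @param hydration_h Hydration level recorded in the metadata.
#' @param sample_id Sample label.
#' @return An [elastic_scan()].
#' @export
simulate_water_scan <- function(model, resolution_time,
                                temperatures = .default_temperatures(),
                                q_values = .default_q(),
                                seed = NULL, state = "hydrated",
                                hydration_h = 0.4, sample_id = "D-protein") {
  state <- match.arg(state, c("hydrated", "dry"))
  stopifnot(length(temperatures) > 0, length(q_values) > 0)
  dw <- exp(-outer(model$vib_slope * temperatures, q_values^2) / 6)
  if (state == "hydrated") {
    tau <- arrhenius_tau(temperatures, model$delta_u, model$tau0)
    relax <- model$eisf_a0 + (1 - model$eisf_a0) * exp(-resolution_time / tau)
    kernel <- dw * relax
  } else {
    kernel <- dw
  }
  intens <- .apply_noise(kernel, model$noise_sigma, seed)
  elastic_scan(
    sample_id = sample_id, component = "water", state = state,
    hydration_h = if (state == "dry") 0 else hydration_h,
    resolution_time = resolution_time,
    temperatures = temperatures, q_values = q_values,
    intensities = intens,
    meta = list(generator = "water_model", seed = seed,
                noise_sigma = model$noise_sigma, delta_u = model$delta_u,
                tau0 = model$tau0)
  )
}

#' Simulate an elastic scan of a protein
#'
#' `MSD(T) = vib_slope T + anh_slope max(0, T - T_g(h))` with the Gaussian
#' kernel `I(q, T) = exp(-q^2 MSD(T) / 6)`.  The kernel does not depend on
#' the instrument resolution time (the transition is intrinsic); the
#' `resolution_time` argument only labels the scan.  The dry companion has
#' `anh_slope = 0`.
#'
#' @param model A [protein_model()].
#' @param h Hydration level, g/g.
#' @param resolution_time Resolution-time label, ps.
#' @param temperatures,q_values Measurement grids (increasing).
#' @param seed Integer seed for the noise (required when noisy).
#' @param state `"hydrated"` or `"dry"`.
#' @param sample_id Sample label.
#' @return An [elastic_scan()].
#' @export
simulate_protein_scan <- function(model, h, resolution_time,
                                  temperatures = .default_temperatures(),
                                  q_values = .default_q(),
                                  seed = NULL, state = "hydrated",
                                  sample_id = "H-protein") {
  state <- match.arg(state, c("hydrated", "dry"))
  stopifnot(length(temperatures) > 0, length(q_values) > 0)
  msd <- model$vib_slope * temperatures
  if (state == "hydrated") {
    tg <- protein_tg(model, h)
    msd <- msd + model$anh_slope * pmax(0, temperatures - tg)
  }
  kernel <- exp(-outer(msd, q_values^2) / 6)
  intens <- .apply_noise(kernel, model$noise_sigma, seed)
  elastic_scan(
    sample_id = sample_id, component = "protein", state = state,
    hydration_h = if (state == "dry") 0 else h,
    resolution_time = resolution_time,
    temperatures = temperatures, q_values = q_values,
    intensities = intens,
    meta = list(generator = "protein_model", seed = seed,
                noise_sigma = model$noise_sigma,
                t_g = if (state == "hydrated") protein_tg(model, h) else NA_real_)
  )
}

#' Simulate a DSC thermogram with a glass-transition step
#'
#' Heat flow blends between two linear baselines through a logistic sigmoid
#' centred at `t_g` with scale `width`, plus additive Gaussian noise.
#'
#' @param t_g Step midpoint, K.
#' @param step_height Unused directly; the separation is set by the
#'   baselines. Kept as an explicit scale check: if the extrapolated
#'   baselines differ by less than `step_height` at `t_g` an error is
#'   raised. Default 0 disables the check.
#' @param width Sigmoid scale, K (> 0).
#' @param baseline_low,baseline_high Length-2 numeric `(intercept mW,
#'   slope mW/K)` of the low/high-temperature baselines.
#' @param temperatures Temperature grid, K.
#' @param heating_rate Heating rate, K/min (metadata).
#' @param noise_sigma Additive noise sd, mW.
#' @param seed Integer seed (required when noisy).
#' @param sample_id Sample label.
#' @return A [dsc_curve()].
#' @export
simulate_dsc_curve <- function(t_g, width = 4,
                               baseline_low = c(-1, 0), baseline_high = c(-2, 0),
                               temperatures = seq(150, 300, by = 0.5),
                               heating_rate = 1, noise_sigma = 0,
                               seed = NULL, step_height = 0,
                               sample_id = "DSC") {
  stopifnot(width > 0)
  lo <- baseline_low[1] + baseline_low[2] * temperatures
  hi <- baseline_high[1] + baseline_high[2] * temperatures
  sep_at_tg <- abs((baseline_high[1] + baseline_high[2] * t_g) -
                   (baseline_low[1] + baseline_low[2] * t_g))
  if (step_height > 0 && sep_at_tg < step_height) {
    stop("baseline separation at t_g smaller than requested step_height",
         call. = FALSE)
  }
  s <- stats::plogis((temperatures - t_g) / width)
  hf <- lo + (hi - lo) * s
  if (noise_sigma > 0) {
    if (is.null(seed)) {
      stop("a `seed` is required when noise_sigma > 0 (reproducibility contract)",
           call. = FALSE)
    }
    hf <- withr::with_seed(seed, hf + stats::rnorm(length(hf), sd = noise_sigma))
  }
  dsc_curve(temperatures, hf, heating_rate = heating_rate,
            sample_id = sample_id,
            meta = list(t_g = t_g, width = width, seed = seed,
                        noise_sigma = noise_sigma))
}

#' Default synthetic study configuration
#'
#' The experimental design the generators reproduce: protein scans (dry +
#' D2O-hydrated) and water scans (dry + H2O-hydrated perdeuterated protein)
#' at resolution times 1000, 40 and 10 ps, hydration levels 0.2-0.4, and
#' DSC curves at dry, 0.2 and 0.4 g/g.
#'
#' @param seed Base integer seed; per-scan seeds are derived from it.
#' @param noise_sigma Relative intensity noise for all scans (0 = noiseless).
#' @return A named list understood by [make_study()] and [run_study()].
#' @export
default_study_config <- function(seed = 1, noise_sigma = 0.005) {
  list(
    seed = seed,
    noise_sigma = noise_sigma,
    resolutions_ps = c(1000, 40, 10),
    protein_h = c(0.2, 0.3, 0.4),
    water_h = c(0.2, 0.4),
    dsc_h = c(0, 0.2, 0.4),
    # calorimetric midpoints sit a few K below the 1 ns neutron onsets
    dsc_anchors = data.frame(h = c(0.2, 0.4), t_g = c(245, 225)),
    dsc_noise_mW = 0,
    temperatures = .default_temperatures(),
    q_values = .default_q(),
    protein = protein_model(noise_sigma = noise_sigma),
    water = water_model(noise_sigma = noise_sigma)
  )
}

# Deterministic per-scan seed derived from the base seed; kept < 2^31.
.derive_seed <- function(base, i) {
  if (is.null(base)) return(NULL)
  as.integer((as.numeric(base) * 7919 + i * 104729) %% 2147483647)
}

#' Generate the full synthetic study bundle
#'
#' One dry and one hydrated scan per (component, resolution, hydration)
#' cell, plus DSC curves.  Identical seeds give bit-identical bundles.
#'
#' @param config Configuration list, see [default_study_config()].
#' @return List with elements `scans` (list of [elastic_scan()]) and
#'   `dsc` (list of [dsc_curve()]), plus the `config` used.
#' @export
make_study <- function(config = default_study_config()) {
  scans <- list()
  keys <- character()
  i <- 0L
  add_scan <- function(scan, key) {
    if (key %in% keys) stop("duplicate study cell: ", key, call. = FALSE)
    keys[[length(keys) + 1L]] <<- key
    scans[[length(scans) + 1L]] <<- scan
  }
  for (res in config$resolutions_ps) {
    # protein: one dry companion per resolution + hydrated scans over h
    i <- i + 1L
    add_scan(simulate_protein_scan(
      config$protein, h = 0, resolution_time = res,
      temperatures = config$temperatures, q_values = config$q_values,
      seed = .derive_seed(config$seed, i), state = "dry"),
      sprintf("protein|dry|%g", res))
    for (h in config$protein_h) {
      i <- i + 1L
      add_scan(simulate_protein_scan(
        config$protein, h = h, resolution_time = res,
        temperatures = config$temperatures, q_values = config$q_values,
        seed = .derive_seed(config$seed, i)),
        sprintf("protein|h=%g|%g", h, res))
    }
    i <- i + 1L
    add_scan(simulate_water_scan(
      config$water, resolution_time = res,
      temperatures = config$temperatures, q_values = config$q_values,
      seed = .derive_seed(config$seed, i), state = "dry"),
      sprintf("water|dry|%g", res))
    for (h in config$water_h) {
      i <- i + 1L
      add_scan(simulate_water_scan(
        config$water, resolution_time = res,
        temperatures = config$temperatures, q_values = config$q_values,
        seed = .derive_seed(config$seed, i), hydration_h = h),
        sprintf("water|h=%g|%g", h, res))
    }
  }
  dsc <- list()
  for (h in config$dsc_h) {
    i <- i + 1L
    if (h == 0) {
      # dry: no step, single baseline continued across the range
      dsc[[length(dsc) + 1L]] <- simulate_dsc_curve(
        t_g = 225, width = 4, baseline_low = c(-1, -0.002),
        baseline_high = c(-1, -0.002), noise_sigma = config$dsc_noise_mW,
        seed = .derive_seed(config$seed, i), sample_id = "DSC dry")
    } else {
      tg <- stats::approx(config$dsc_anchors$h, config$dsc_anchors$t_g,
                          xout = h, rule = 2)$y
      dsc[[length(dsc) + 1L]] <- simulate_dsc_curve(
        t_g = tg, width = 4, baseline_low = c(-1, -0.002),
        baseline_high = c(-2.2, -0.002), noise_sigma = config$dsc_noise_mW,
        seed = .derive_seed(config$seed, i),
        sample_id = sprintf("DSC h=%g", h))
      dsc[[length(dsc)]]$meta$h <- h
    }
  }
  list(scans = scans, dsc = dsc, config = config)
}
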