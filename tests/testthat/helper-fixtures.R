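# Shared fixtures, all built in code.

# small rectangular scan with known intensities
tiny_scan <- function(temps = c(10, 20, 30), qs = c(0.5, 1.0),
                      intens = matrix(seq_len(length(temps) * length(qs)),
                                      length(temps), length(qs)),
                      component = "protein", state = "dry", h = 0,
                      res = 1000, errors = NULL) {
  elastic_scan("S1", component, state, h, res, temps, qs, intens,
               intensity_errors = errors)
}

# noiseless dry/hydrated difference series from the protein generator
protein_difference <- function(h = 0.4, res = 1000, noise = 0, seed = NULL,
                               q_range = c(0.45, 1.75), ...) {
  pm <- protein_model(noise_sigma = noise, ...)
  hyd <- simulate_protein_scan(pm, h = h, resolution_time = res, seed = seed)
  dry <- simulate_protein_scan(pm, h = h, resolution_time = res,
                               seed = if (is.null(seed)) NULL else seed + 1,
                               state = "dry")
  difference_curve(sum_over_q(normalize_to_base(hyd), q_range),
                   sum_over_q(normalize_to_base(dry), q_range))
}

water_difference <- function(res, noise = 0, seed = NULL, ...) {
  wm <- water_model(noise_sigma = noise, ...)
  hyd <- simulate_water_scan(wm, resolution_time = res, seed = seed)
  dry <- simulate_water_scan(wm, resolution_time = res,
                             seed = if (is.null(seed)) NULL else seed + 1,
                             state = "dry")
  difference_curve(sum_over_q(normalize_to_base(hyd)),
                   sum_over_q(normalize_to_base(dry)))
}

# exact piecewise-linear difference series
piecewise_series <- function(break_T = 210, slope = 0.002,
                             temps = seq(100, 300, by = 2)) {
  structure(
    list(temperatures = temps,
         values = slope * pmax(0, temps - break_T),
         orientation = "dry - hydrated", provenance = "synthetic"),
    class = "difference_series"
  )
}
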