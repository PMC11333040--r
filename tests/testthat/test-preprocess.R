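test_that("normalization maps the base window to ~1 and is scale invariant", {
  wm <- water_model(noise_sigma = 0)
  sc <- simulate_water_scan(wm, 40)
  ns <- normalize_to_base(sc)
  in_base <- ns$temperatures <= 20
  expect_equal(mean(ns$intensities[in_base, ]), 1, tolerance = 1e-3)

  scaled <- sc
  scaled$intensities <- sc$intensities * 37.5
  expect_equal(normalize_to_base(scaled)$intensities, ns$intensities,
               tolerance = 1e-12)

  short <- tiny_scan(temps = c(100, 150, 200))
  expect_error(normalize_to_base(short), "base window")
})

test_that("normalized noiseless water scan plateaus at A0 x Debye-Waller ratio", {
  wm <- water_model(noise_sigma = 0)
  sc <- normalize_to_base(simulate_water_scan(wm, 1000))
  i300 <- which(sc$temperatures == 300)
  dw_ratio <- exp(-sc$q_values^2 * wm$vib_slope * (300 - mean(sc$temperatures[sc$temperatures <= 20])) / 6)
  expect_equal(sc$intensities[i300, ], wm$eisf_a0 * dw_ratio,
               tolerance = 1e-4)
})

test_that("q-summation averages columns and commutes with rescaling", {
  sc <- tiny_scan(temps = c(5, 10, 15), qs = c(0.5, 0.8, 1.2),
                  intens = matrix(rep(c(2, 4, 6), 3), 3, 3))
  sc$normalized <- TRUE
  s <- sum_over_q(sc, c(0.45, 1.75))
  expect_equal(s$values, c(2, 4, 6))

  expect_error(sum_over_q(sc, c(1.5, 1.75)), "fewer than 2")
  expect_error(sum_over_q(tiny_scan(), c(0.45, 1.75)), "normalized")
})

test_that("the detected onset is stable across q-summation ranges", {
  t_on <- vapply(
    list(c(0.45, 1.75), c(0.45, 0.9), c(1.1, 1.75)),
    function(qr) detect_onset(protein_difference(h = 0.4, res = 1000, q_range = qr),
                              constrain_first = TRUE)$t_on,
    numeric(1)
  )
  expect_lt(max(t_on) - min(t_on), 1)
})

test_that("gaussian_msd inverts the Gaussian forward model exactly", {
  qs <- seq(0.3, 1.0, by = 0.05)
  temps <- seq(10, 100, by = 10)
  for (msd_true in c(0.05, 0.3, 1.2)) {
    sc <- elastic_scan("g", "protein", "dry", 0, 1000, temps, qs,
                       matrix(exp(-outer(rep(msd_true, length(temps)), qs^2) / 6),
                              length(temps), length(qs)),
                       normalized = TRUE)
    out <- gaussian_msd(sc)
    expect_equal(out$msd, rep(msd_true, length(temps)), tolerance = 1e-10)
    expect_true(all(out$r_squared > 1 - 1e-10))
  }
  # S == 1 -> zero MSD
  sc1 <- elastic_scan("g", "protein", "dry", 0, 1000, temps, qs,
                      matrix(1, length(temps), length(qs)), normalized = TRUE)
  expect_equal(gaussian_msd(sc1)$msd, rep(0, length(temps)), tolerance = 1e-12)
})

test_that("water MSD at low temperature is the harmonic line", {
  wm <- water_model(noise_sigma = 0)
  sc <- normalize_to_base(simulate_water_scan(wm, 1000))
  out <- gaussian_msd(sc)
  low <- sc$temperatures <= 100   # tau >> dt, pure Debye-Waller regime
  base_T <- mean(sc$temperatures[sc$temperatures <= 20])
  expect_lt(max(abs(out$msd[low] - wm$vib_slope * (sc$temperatures[low] - base_T))),
            1e-5)
})

test_that("non-positive intensities flag the temperature instead of failing", {
  qs <- seq(0.45, 0.95, by = 0.05)
  m <- matrix(0.9, 4, length(qs))
  m[2, 3] <- 0
  sc <- elastic_scan("g", "protein", "dry", 0, 1000, c(10, 20, 30, 40), qs, m,
                     normalized = TRUE)
  out <- gaussian_msd(sc)
  expect_true(is.na(out$msd[2]))
  expect_false(anyNA(out$msd[-2]))
})
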