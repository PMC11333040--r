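test_that("water kernel matches its analytic form", {
  wm <- water_model(noise_sigma = 0)
  # at T = 250 K the default model has tau = 10 ps; with dt = 10 ps the
  # relaxational factor is A0 + (1 - A0) e^-1
  s <- simulate_water_scan(wm, resolution_time = 10,
                           temperatures = c(10, 250), q_values = c(0.5, 1))
  dw <- exp(-outer(wm$vib_slope * c(10, 250), c(0.5, 1)^2) / 6)
  relax <- s$intensities / dw
  expect_equal(unname(relax[2, ]), rep(0.7 + 0.3 * exp(-1), 2),
               tolerance = 1e-6)
  # low-temperature limit: tau >> dt, intensity -> pure Debye-Waller
  expect_equal(s$intensities[1, ], dw[1, ], tolerance = 1e-12)
  dry <- simulate_water_scan(wm, resolution_time = 10,
                             temperatures = c(10, 250),
                             q_values = c(0.5, 1), state = "dry")
  expect_equal(s$intensities[1, ], dry$intensities[1, ], tolerance = 1e-12)
})

test_that("water kernel is monotone non-increasing in T at fixed q", {
  wm <- water_model(noise_sigma = 0)
  s <- simulate_water_scan(wm, resolution_time = 40)
  expect_true(all(apply(s$intensities, 2, function(col) all(diff(col) <= 1e-12))))
})

test_that("water onset moves with the resolution window by tens of K", {
  t10 <- detect_onset(water_difference(10), constrain_first = TRUE)$t_on
  t1000 <- detect_onset(water_difference(1000), constrain_first = TRUE)$t_on
  expect_gte(t10 - t1000, 40)
})

test_that("protein scans are resolution independent and kink at T_g(h)", {
  pm <- protein_model(noise_sigma = 0)
  expect_equal(protein_tg(pm, 0.2), 248)
  expect_equal(protein_tg(pm, 0.4), 228)
  expect_equal(protein_tg(pm, 0.3), 238)  # linear interpolation
  expect_warning(protein_tg(pm, 0.5), "extrapolating")

  hyd <- simulate_protein_scan(pm, h = 0.4, resolution_time = 10)
  dry <- simulate_protein_scan(pm, h = 0.4, resolution_time = 10, state = "dry")
  below <- hyd$temperatures < 228
  expect_identical(hyd$intensities[below, ], dry$intensities[below, ])
  above <- hyd$temperatures > 228
  expect_true(all(hyd$intensities[above, ] < dry$intensities[above, ]))
  # hydrated - dry difference strictly increasing above T_g
  d <- protein_difference(h = 0.4, res = 10)
  expect_true(all(abs(d$values[d$temperatures < 228]) < 1e-12))
  expect_true(all(diff(d$values[d$temperatures >= 228]) > 0))

  # detected onset equal within 2 K across a 100x resolution span
  ta <- detect_onset(protein_difference(h = 0.4, res = 10),
                     constrain_first = TRUE)$t_on
  tb <- detect_onset(protein_difference(h = 0.4, res = 1000),
                     constrain_first = TRUE)$t_on
  expect_lt(abs(ta - tb), 2)
})

test_that("noiseless normalized intensities lie in (0, 1]", {
  pm <- protein_model(noise_sigma = 0)
  wm <- water_model(noise_sigma = 0)
  for (s in list(simulate_protein_scan(pm, 0.4, 40),
                 simulate_water_scan(wm, 40))) {
    ns <- normalize_to_base(s)
    expect_true(all(ns$intensities > 0))
    # the base-window mean normalization leaves the very lowest temperatures
    # marginally above 1, bounded by the Debye-Waller decay across the
    # window itself (largest at the largest q)
    bound <- exp(max(s$q_values)^2 * 1.5e-3 * (15 - 10) / 6)
    expect_true(all(ns$intensities <= bound))
    expect_true(all(ns$intensities[ns$temperatures > 20, ] <= 1 + 1e-9))
  }
})

test_that("noise requires a seed and is reproducible", {
  wm <- water_model(noise_sigma = 0.01)
  expect_error(simulate_water_scan(wm, 40), "seed")
  a <- simulate_water_scan(wm, 40, seed = 7)
  b <- simulate_water_scan(wm, 40, seed = 7)
  expect_identical(a$intensities, b$intensities)
  c2 <- simulate_water_scan(wm, 40, seed = 8)
  expect_false(identical(a$intensities, c2$intensities))
})

test_that("simulate_dsc_curve midpoints are recovered by detect_tdsc", {
  for (tg in c(225, 245)) {
    cv <- simulate_dsc_curve(t_g = tg, baseline_low = c(-1, 0),
                             baseline_high = c(-2, 0))
    expect_equal(detect_tdsc(cv)$t_dsc, tg, tolerance = 0.5)
  }
  flat <- simulate_dsc_curve(t_g = 225, baseline_low = c(-1, 0),
                             baseline_high = c(-1, 0))
  expect_error(detect_tdsc(flat), "no transition")
})

test_that("make_study emits one dry + hydrated scan per cell, deterministically", {
  cfg <- default_study_config(seed = 3, noise_sigma = 0.005)
  st <- make_study(cfg)
  n_res <- length(cfg$resolutions_ps)
  expect_length(st$scans,
                n_res * (2 + length(cfg$protein_h) + length(cfg$water_h)))
  expect_length(st$dsc, length(cfg$dsc_h))

  st2 <- make_study(cfg)
  expect_identical(st, st2)

  # different seed: noisy intensities differ, noiseless kernels identical
  st3 <- make_study(default_study_config(seed = 4, noise_sigma = 0.005))
  expect_false(identical(st$scans[[1]]$intensities,
                         st3$scans[[1]]$intensities))
  k1 <- make_study(default_study_config(seed = 3, noise_sigma = 0))
  k2 <- make_study(default_study_config(seed = 4, noise_sigma = 0))
  expect_identical(lapply(k1$scans, `[[`, "intensities"),
                   lapply(k2$scans, `[[`, "intensities"))
})
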