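test_that("printed (T, tau) pairs give the ~38 kJ/mol activation energy", {
  pts <- data.frame(temperature_K = c(250, 234, 200), tau_ps = c(10, 40, 1000))
  fit <- fit_arrhenius(pts)
  expect_equal(fit$delta_u, 37.99, tolerance = 0.01)
  expect_equal(fit$delta_u, fit$slope * R_GAS / 1000, tolerance = 1e-12)
})

test_that("two-point fits are exact and match the hand-computed slope", {
  fit <- fit_arrhenius(data.frame(temperature_K = c(250, 200),
                                  tau_ps = c(10, 1000)))
  expect_equal(fit$slope, log(100) / 0.001, tolerance = 1e-9)  # 4605.2 K
  expect_equal(fit$delta_u, 38.29, tolerance = 0.001)
  expect_equal(fit$residual_rms, 0, tolerance = 1e-12)
})

test_that("fit o evaluate is the identity on noiseless Arrhenius points", {
  for (p in list(c(20, 1), c(38, 1e-7), c(5, 100))) {
    tt <- seq(150, 280, length.out = 5)
    fit <- fit_arrhenius(data.frame(temperature_K = tt,
                                    tau_ps = arrhenius_tau(tt, p[1], p[2])))
    expect_equal(fit$delta_u, p[1], tolerance = 1e-10)
    expect_equal(fit$tau0, p[2], tolerance = 1e-8)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_arrhenius(data.frame(temperature_K = 250, tau_ps = 10)),
               "at least 2")
  expect_error(fit_arrhenius(data.frame(temperature_K = c(250, 250),
                                        tau_ps = c(10, 40))), "singular")
})

test_that("crossing temperatures match the closed form", {
  fa <- fit_arrhenius(data.frame(temperature_K = c(250, 234),
                                 tau_ps = c(10, 40)))
  expect_equal(crossing_temperature(fa, 1000), 203.7, tolerance = 0.05)
  fb <- fit_arrhenius(data.frame(temperature_K = c(250, 200),
                                 tau_ps = c(10, 1000)))
  expect_equal(crossing_temperature(fb, 40), 232.5, tolerance = 0.05)
  # a fitted point's tau maps back to its own temperature
  expect_equal(crossing_temperature(fb, 10), 250, tolerance = 1e-9)
  expect_equal(crossing_temperature(fb, 1000), 200, tolerance = 1e-9)
  # strictly decreasing in the resolution time
  dts <- c(5, 20, 100, 1000, 1e4)
  expect_true(all(diff(vapply(dts, function(dt)
    crossing_temperature(fb, dt), numeric(1))) < 0))
  expect_error(crossing_temperature(fb, fb$tau0 / 2), "no crossing")
})

test_that("onsets at several resolutions recover the activation energy", {
  wm <- water_model()  # noise 0.005
  onsets <- lapply(c(1000, 40, 10), function(r) {
    hyd <- simulate_water_scan(wm, r, seed = 100 + r)
    dry <- simulate_water_scan(wm, r, seed = 200 + r, state = "dry")
    d <- difference_curve(sum_over_q(normalize_to_base(hyd)),
                          sum_over_q(normalize_to_base(dry)))
    o <- detect_onset(d, method = "threshold")
    o$details$resolution_time <- r
    o
  })
  fit <- onsets_to_arrhenius(onsets)
  expect_true(fit$resolution_limited)
  expect_true(fit$assumed_tau_eq_resolution)
  # bias from onset-vs-crossing mismatch is expected; 20% band
  expect_lt(abs(fit$delta_u - 38) / 38, 0.2)
})

test_that("resolution-independent onsets are flagged, not force-fitted", {
  df <- data.frame(t_on = c(228.1, 227.9, 228.0),
                   resolution_ps = c(1000, 40, 10))
  fit <- onsets_to_arrhenius(df)
  expect_false(fit$resolution_limited)
  expect_true(is.na(fit$delta_u))
  expect_lt(abs(fit$ton_vs_lndt_slope), 2)

  expect_error(onsets_to_arrhenius(df[1, ]), ">= 2")
  expect_error(
    onsets_to_arrhenius(data.frame(t_on = c(200, 210),
                                   resolution_ps = c(40, 40))),
    ">= 2 distinct")
})
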