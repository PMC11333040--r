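test_that("baselines are recovered on noiseless data with a sharp step", {
  # width 2 K: the logistic tails are < 3e-8 inside the default windows
  cv <- simulate_dsc_curve(225, width = 2, baseline_low = c(-1, 0),
                           baseline_high = c(-2, 0))
  b <- fit_baselines(cv)
  expect_equal(b$low, c(-1, 0), tolerance = 1e-6)
  expect_equal(b$high, c(-2, 0), tolerance = 1e-6)

  cv2 <- simulate_dsc_curve(225, width = 2, baseline_low = c(-0.5, -0.004),
                            baseline_high = c(-1.8, -0.001))
  b2 <- fit_baselines(cv2)
  expect_equal(b2$low, c(-0.5, -0.004), tolerance = 1e-5)
  expect_equal(b2$high, c(-1.8, -0.001), tolerance = 1e-5)
})

test_that("baseline windows are validated", {
  cv <- simulate_dsc_curve(225)
  expect_error(fit_baselines(cv, c(160, 240), c(230, 290)), "disjoint")
  expect_error(fit_baselines(cv, c(160, 161), c(260, 290)), "fewer than 5")
})

test_that("midpoint recovery within 1 K for steps of any width <= 10 K", {
  # baseline windows must clear the logistic tails (~5 widths from t_g)
  for (w in c(1, 3, 6, 10)) {
    for (tg in c(215, 235)) {
      cv <- simulate_dsc_curve(tg, width = w)
      b <- fit_baselines(cv, low_window = c(150, min(190, tg - 5 * w)),
                         high_window = c(max(260, tg + 5 * w), 300))
      expect_lt(abs(detect_tdsc(cv, b)$t_dsc - tg), 1)
    }
  }
})

test_that("midpoint construction is invariant under a common linear trend", {
  cv <- simulate_dsc_curve(230, baseline_low = c(-1, 0), baseline_high = c(-2, 0))
  base <- detect_tdsc(cv)$t_dsc
  trended <- simulate_dsc_curve(230, baseline_low = c(-1 + 4, 0.01),
                                baseline_high = c(-2 + 4, 0.01))
  expect_equal(detect_tdsc(trended)$t_dsc, base, tolerance = 1e-6)
})

test_that("step height is the baseline separation at the midpoint", {
  cv <- simulate_dsc_curve(225, baseline_low = c(-1, 0), baseline_high = c(-2, 0))
  r <- detect_tdsc(cv)
  expect_equal(r$step_height, 1, tolerance = 1e-3)
  expect_equal(cv$heat_flow[which.min(abs(cv$temperatures - r$t_dsc))],
               -1.5, tolerance = 0.01)  # curve sits on the midline at T_DSC
})

test_that("absence of a step is reported as no transition", {
  flat <- simulate_dsc_curve(225, baseline_low = c(-1.5, 0),
                             baseline_high = c(-1.5, 0))
  expect_error(detect_tdsc(flat), "no transition")
  # noisy but stepless curve: separation below 3x noise
  noisy <- simulate_dsc_curve(225, baseline_low = c(-1.5, 0),
                              baseline_high = c(-1.52, 0),
                              noise_sigma = 0.05, seed = 5)
  expect_error(detect_tdsc(noisy), "no transition")
})
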