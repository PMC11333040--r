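test_that("difference_curve obeys its orientation and grid rules", {
  a <- summed_series(seq(10, 300, 2), rep(0.5, 146), c(0.45, 1.75))
  expect_true(all(difference_curve(a, a)$values == 0))

  # coarser grid wins: 2 K vs 5 K -> 5 K output
  fine <- summed_series(seq(10, 300, 2), seq(10, 300, 2) / 300, c(0.45, 1.75))
  coarse <- summed_series(seq(20, 290, 5), rep(0.2, 55), c(0.45, 1.75))
  d <- difference_curve(fine, coarse)
  expect_equal(unique(diff(d$temperatures)), 5)
  expect_true(min(d$temperatures) >= 20 && max(d$temperatures) <= 290)

  # MSD series difference is hydrated - dry
  mh <- msd_series(seq(10, 100, 10), seq(0.1, 1, 0.1), c(0.45, 0.9))
  md <- msd_series(seq(10, 100, 10), rep(0.05, 10), c(0.45, 0.9))
  dm <- difference_curve(mh, md)
  expect_identical(dm$orientation, "hydrated - dry")
  expect_equal(dm$values, seq(0.1, 1, 0.1) - 0.05)

  short <- summed_series(seq(10, 40, 2), rep(1, 16), c(0.45, 1.75))
  far <- summed_series(seq(200, 300, 2), rep(1, 51), c(0.45, 1.75))
  expect_error(difference_curve(short, far), "overlap")
})

test_that("bilinear detector recovers exact piecewise-linear breakpoints", {
  for (brk in c(170, 210, 252)) {
    d <- piecewise_series(break_T = brk)
    got <- detect_onset(d, method = "bilinear")$t_on
    expect_equal(got, brk, tolerance = 1e-6)
    got_grid <- detect_onset(d, method = "bilinear", refine_window_K = Inf)$t_on
    expect_lte(abs(got_grid - brk), 2)  # within one grid step
  }
})

test_that("bilinear detector is equivariant under affine rescaling", {
  d <- piecewise_series(break_T = 214, slope = 0.0017)
  base <- detect_onset(d)$t_on
  d2 <- d
  d2$values <- 5.3 * d$values - 0.7
  expect_equal(detect_onset(d2)$t_on, base, tolerance = 1e-8)
})

test_that("threshold detector finds steps and refuses pure noise", {
  d <- piecewise_series(break_T = 210, slope = 0.002)
  d$values <- d$values + withr::with_seed(1, rnorm(length(d$values), sd = 1e-4))
  t_thr <- detect_onset(d, method = "threshold")$t_on
  expect_gte(t_thr, 208)
  expect_lte(t_thr, 230)

  flat <- piecewise_series(break_T = 210, slope = 0)
  flat$values <- withr::with_seed(2, rnorm(length(flat$values), sd = 1e-4))
  expect_error(detect_onset(flat, method = "threshold"), "no onset")
})

test_that("onset lies strictly inside the series range or detection errors", {
  # no admissible breakpoint when margins cannot be satisfied
  tiny <- piecewise_series(break_T = 120, temps = seq(100, 140, 2))
  expect_error(detect_onset(tiny, min_margin_K = 30), "no onset")
  d <- piecewise_series(break_T = 210)
  t_on <- detect_onset(d)$t_on
  expect_gt(t_on, min(d$temperatures))
  expect_lt(t_on, max(d$temperatures))
})

test_that("bootstrap intervals are deterministic and collapse without noise", {
  d <- piecewise_series(break_T = 210)
  ci <- suppressWarnings(bootstrap_onset(d, n_boot = 50, seed = 4))
  expect_equal(unname(ci["ci_high"] - ci["ci_low"]), 0, tolerance = 1e-6)

  dn <- protein_difference(h = 0.4, res = 1000, noise = 0.005, seed = 11)
  ci1 <- bootstrap_onset(dn, n_boot = 150, seed = 9, constrain_first = TRUE)
  ci2 <- bootstrap_onset(dn, n_boot = 150, seed = 9, constrain_first = TRUE)
  expect_identical(ci1, ci2)
  expect_warning(bootstrap_onset(dn, n_boot = 99, seed = 1), "n_boot")
})

test_that("onset detection separates intrinsic from resolution-limited behaviour", {
  # the decoupling signature at the estimator level, noiseless
  prot <- vapply(c(10, 1000), function(r)
    detect_onset(protein_difference(h = 0.4, res = r), constrain_first = TRUE)$t_on,
    numeric(1))
  expect_lt(abs(diff(prot)), 3)
  wat <- vapply(c(1000, 40, 10), function(r)
    detect_onset(water_difference(r), constrain_first = TRUE)$t_on, numeric(1))
  expect_true(all(diff(wat) > 0))
})
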