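test_that("barycentric mean matches hand-computed values", {
  # flat spectrum over a symmetric window
  wl <- seq(320, 400, by = 1)
  expect_equal(barycentric_mean(wl, rep(5, length(wl))), 360)
  # single nonzero point
  inten <- rep(0, length(wl)); inten[wl == 350] <- 2
  expect_equal(barycentric_mean(wl, inten), 350)
  # two equal points, then 1:3 weights
  expect_equal(barycentric_mean(c(330, 350, 370), c(1, 0, 1)), 350)
  expect_equal(barycentric_mean(c(330, 350, 370), c(1, 0, 3)), 360)
  expect_error(barycentric_mean(wl, rep(0, length(wl))), "zero")
})

test_that("barycentric mean is scale-invariant and shift-linear", {
  set.seed(11)
  wl <- seq(300, 450, by = 1)
  inten <- runif(length(wl))
  b <- barycentric_mean(wl, inten)
  expect_equal(barycentric_mean(wl, 7.3 * inten), b)
  expect_equal(barycentric_mean(wl + 12, inten), b + 12)
  expect_true(b >= min(wl) && b <= max(wl))
})

test_that("melt curves are built per temperature, sorted", {
  g <- gen_melt_spectra(55, 2, noise_sd = 0)
  curve <- build_melt_curve(g$spectra)
  expect_equal(nrow(curve), 66L)
  expect_true(all(diff(curve$temperature) > 0))
  # monotone sigmoid input yields monotone bcm
  expect_true(all(diff(curve$bcm) >= -1e-9))
  # generator's analytic bcm is reproduced
  expect_equal(curve$bcm, g$truth$model_bcm, tolerance = 0.02)
  # unsorted input is sorted
  shuf <- g$spectra[sample(nrow(g$spectra)), ]
  expect_equal(build_melt_curve(shuf)$bcm, curve$bcm)
  # duplicated spectra at one temperature error
  dup <- rbind(g$spectra, g$spectra[g$spectra$temperature == 30, ])
  expect_error(build_melt_curve(dup), "duplicate")
})

test_that("single-transition fit recovers noiseless parameters", {
  g <- gen_melt_spectra(tm1 = 55, a = 2, bcm_n = 352, bcm_d = 360,
                        noise_sd = 0)
  f <- fit_single_transition(build_melt_curve(g$spectra))
  expect_true(f$converged)
  expect_equal(f$tm1, 55, tolerance = 0.05)
  expect_equal(f$a, 2, tolerance = 0.05)
  expect_equal(f$i_d - f$i_n, 8, tolerance = 0.05)
  expect_lt(f$rss, 1e-6)
})

test_that("single-transition fit is robust to noise across seeds", {
  errs <- vapply(1:20, function(s) {
    g <- gen_melt_spectra(55, 2, 352.2, 360, noise_sd = 0.1, seed = s)
    f <- fit_single_transition(build_melt_curve(g$spectra))
    abs(f$tm1 - 55)
  }, numeric(1))
  expect_true(mean(errs <= 0.5) >= 0.95)
})

test_that("a flat curve is flagged, not fitted", {
  curve <- data.frame(temperature = 25:90, bcm = rep(355, 66))
  f <- fit_single_transition(curve)
  expect_false(f$converged)
  expect_match(f$message, "flat")
  expect_error(red_shift(f), "flagged")
})

test_that("two-transition fit recovers well-separated transitions", {
  g <- gen_melt_spectra(45, 2, 352, 360, tm2 = 65, b = 2, bcm_2 = 356,
                        noise_sd = 0)
  f <- fit_two_transition(build_melt_curve(g$spectra))
  expect_true(f$converged)
  expect_equal(f$tm1, 45, tolerance = 0.1)
  expect_equal(f$tm2, 65, tolerance = 0.1)
  expect_lt(f$tm1, f$tm2)
})

test_that("two-transition T_m1 holds up under noise", {
  errs <- vapply(1:10, function(s) {
    g <- gen_melt_spectra(45, 2, 352, 360, tm2 = 60, b = 2, bcm_2 = 356,
                          noise_sd = 0.1, seed = s)
    f <- fit_two_transition(build_melt_curve(g$spectra))
    abs(f$tm1 - 45)
  }, numeric(1))
  expect_true(all(errs <= 0.5))
})

test_that("model selection prefers the generating model", {
  g1 <- gen_melt_spectra(55, 2, 352, 360, noise_sd = 0.05, seed = 2)
  c1 <- build_melt_curve(g1$spectra)
  expect_equal(select_model(fit_single_transition(c1),
                            fit_two_transition(c1))$model, "single")
  g2 <- gen_melt_spectra(45, 2, 352, 360, tm2 = 65, b = 2, bcm_2 = 356,
                         noise_sd = 0.05, seed = 2)
  c2 <- build_melt_curve(g2$spectra)
  expect_equal(select_model(fit_single_transition(c2),
                            fit_two_transition(c2))$model, "two_transition")
  # two flagged fits stay flagged
  flat <- data.frame(temperature = 25:90, bcm = rep(355, 66))
  sel <- select_model(fit_single_transition(flat), fit_two_transition(flat))
  expect_false(sel$converged)
})

test_that("red-shift is the fitted baseline difference", {
  g <- gen_melt_spectra(55, 2, bcm_n = 352.2, bcm_d = 360, noise_sd = 0)
  f <- fit_single_transition(build_melt_curve(g$spectra))
  expect_equal(red_shift(f), 7.8, tolerance = 0.01)
  # misfolded-scale generator round-trip
  g2 <- gen_melt_spectra(55, 2, bcm_n = 355, bcm_d = 360, noise_sd = 0.1,
                         seed = 4)
  f2 <- fit_single_transition(build_melt_curve(g2$spectra))
  expect_equal(red_shift(f2), 5, tolerance = 0.2)
  # doubling intensities changes nothing
  sp <- g$spectra; sp$intensity <- 2 * sp$intensity
  f3 <- fit_single_transition(build_melt_curve(sp))
  expect_equal(red_shift(f3), red_shift(f))
  # raw-average mode agrees on a saturated-baseline curve
  expect_equal(red_shift_raw(build_melt_curve(g$spectra)), 7.8,
               tolerance = 0.2)
})

test_that("replicate fitting summarises per variant", {
  sp <- do.call(rbind, lapply(1:2, function(r) {
    g <- gen_melt_spectra(55, 2, noise_sd = 0.05, seed = r)
    cbind(variant = "WT", replicate = r, g$spectra)
  }))
  res <- fit_melt_replicates(sp)
  expect_equal(nrow(res$fits), 2L)
  expect_equal(res$summary$variant, "WT")
  expect_equal(res$summary$tm1, 55, tolerance = 0.3)
  expect_equal(res$summary$n_converged, 2L)
})
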