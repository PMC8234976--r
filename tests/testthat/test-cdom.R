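test_that("model-matched noiseless CDOM parameters are recovered exactly", {
  lib <- test_library()
  sp <- simulate_spectrum(0, 0, 0, lib, cdom_params(0.05, 0.018, 0.002),
                          noise_sd = 0)
  f <- fit_cdom(sp)
  expect_true(f$converged)
  expect_equal(f$params$a0, 0.05, tolerance = 1e-8)
  expect_equal(f$params$s, 0.018, tolerance = 1e-8)
  expect_equal(f$params$k, 0.002, tolerance = 1e-8)
  expect_lt(f$rss, 1e-16)
})

test_that("flat or empty windows raise a degenerate-fit error", {
  sp <- absorbance_spectrum(test_grid(), rep(0.01, 101))
  expect_error(fit_cdom(sp), "degenerate.*skip", ignore.case = TRUE)
  sp0 <- absorbance_spectrum(test_grid(), rep(0, 101))
  expect_error(fit_cdom(sp0), "degenerate", ignore.case = TRUE)
})

test_that("spectral slope is recovered from noisy tails (Monte Carlo)", {
  lib <- test_library()
  rel <- vapply(1:100, function(i) {
    sp <- simulate_spectrum(0, 0, 0, lib, cdom_params(0.05, 0.018, 0.002),
                            noise_sd = 1e-4, seed = i)
    abs(fit_cdom(sp)$params$s - 0.018) / 0.018
  }, numeric(1L))
  expect_lt(median(rel), 0.05)
  expect_lt(mean(rel), 0.10)
})

test_that("steeper true slopes give steeper fitted slopes on average", {
  lib <- test_library()
  svals <- c(0.015, 0.02, 0.025, 0.03)
  means <- vapply(svals, function(s) {
    mean(vapply(1:20, function(i) {
      sp <- simulate_spectrum(0, 0, 0, lib, cdom_params(0.05, s, 0.002),
                              noise_sd = 1e-4, seed = 400 + i)
      fit_cdom(sp)$params$s
    }, numeric(1L)))
  }, numeric(1L))
  expect_false(is.unsorted(means))
})

test_that("subtracting a fitted pure exponential leaves near-zero residual", {
  grid <- test_grid()
  cd <- cdom_params(0.08, 0.022, 0.003)
  sp <- absorbance_spectrum(grid, cdom_absorbance(cd, grid))
  f <- fit_cdom(sp)
  out <- subtract_cdom(sp, f, 200, 240)
  idx <- grid >= 200 & grid <= 240
  expect_lt(max(abs(out$absorbance[idx])), 1e-8)
  expect_equal(out$absorbance[!idx], sp$absorbance[!idx])
})

test_that("a zero-amplitude fit is an identity transform and unconverged fits are refused", {
  grid <- test_grid()
  sp <- absorbance_spectrum(grid, runif(101))
  null_fit <- structure(list(params = cdom_params(0, 0.02, 0),
                             fit_lo = 275, fit_hi = 295, rss = 0,
                             converged = TRUE), class = "cdom_fit")
  expect_equal(subtract_cdom(sp, null_fit)$absorbance, sp$absorbance)
  bad <- null_fit; bad$converged <- FALSE
  expect_error(subtract_cdom(sp, bad), "unconverged")
})

test_that("fit-subtract on zero-noise generator output recovers the pure mixture", {
  lib <- test_library()
  cd <- cdom_params(0.06, 0.02, 0.002)
  # nitrate and nitrite are attenuated to ~1e-7 AU above 275 nm; those
  # tails are amplified ~100x by the extrapolation, so without sea salt the
  # recovery is good to a few 1e-5 AU
  mix <- simulate_spectrum(20, 5, 0, lib, cd, noise_sd = 0)
  pure <- simulate_spectrum(20, 5, 0, lib, NULL, noise_sd = 0)
  out <- subtract_cdom(mix, fit_cdom(mix), 200, 240)
  idx <- lib$wavelength >= 200 & lib$wavelength <= 240
  expect_lt(max(abs(out$absorbance[idx] - pure$absorbance[idx])), 1e-4)
  # the sea-salt tail reaching the 275-295 nm window biases the fit; the
  # extrapolated bias stays at the few-mAU level at full salinity
  mix2 <- simulate_spectrum(20, 5, 34, lib, cd, noise_sd = 0)
  pure2 <- simulate_spectrum(20, 5, 34, lib, NULL, noise_sd = 0)
  out2 <- subtract_cdom(mix2, fit_cdom(mix2), 200, 240)
  expect_lt(max(abs(out2$absorbance[idx] - pure2$absorbance[idx])), 0.02)
})

test_that("correction shrinks the CDOM residual several-fold under noise", {
  lib <- test_library()
  d <- random_design(12, 3)
  noisy <- simulate_dataset(d, lib, cdom_sampler(), noise_sd = 5e-4,
                            seed = 11)
  clean <- simulate_dataset(d, lib, cdom = NULL, noise_sd = 0)
  corr <- suppressWarnings(correct_cdom(noisy))
  idx <- lib$wavelength >= 215 & lib$wavelength <= 240
  rms_before <- sqrt(mean((noisy$absorbance[, idx] -
                             clean$absorbance[, idx])^2))
  rms_after <- sqrt(mean((corr$absorbance[, idx] -
                            clean$absorbance[, idx])^2))
  expect_lt(rms_after, rms_before / 5)
  expect_length(attr(corr, "cdom_fits"), 12L)
})

test_that("subtraction is linear in the spectra for a shared fit", {
  grid <- test_grid()
  lib <- test_library()
  fit <- fit_cdom(simulate_spectrum(0, 0, 0, lib,
                                    cdom_params(0.05, 0.02, 0.001), 0))
  set.seed(5)
  a1 <- runif(101); a2 <- runif(101)
  s1 <- absorbance_spectrum(grid, a1)
  s2 <- absorbance_spectrum(grid, a2)
  s12 <- absorbance_spectrum(grid, a1 + a2)
  lhs <- subtract_cdom(s12, fit)$absorbance
  expect_equal(lhs, subtract_cdom(s1, fit)$absorbance +
                 subtract_cdom(s2, fit)$absorbance +
                 cdom_absorbance(fit$params, grid),
               tolerance = 1e-12)
})
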