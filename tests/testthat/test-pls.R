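test_that("a single-component system is solved by one factor", {
  lib <- test_library()
  d <- data.frame(sample_id = paste0("s", 1:5),
                  no3_uM = c(2, 10, 25, 50, 80), no2_uM = 0,
                  salinity_psu = 0)
  x <- simulate_dataset(d, lib, cdom = NULL, noise_sd = 0)
  X <- x$absorbance
  Y <- as.matrix(d["no3_uM"])
  m <- fit_pls(X, Y, 1)
  expect_lt(max(abs(predict(m, X) - Y)), 1e-10)
})

test_that("full-rank PLS reproduces ordinary least squares", {
  set.seed(21)
  X <- matrix(rnorm(12 * 6), 12, 6)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  m <- fit_pls(X, Y, 6)
  expect_equal(unname(predict(m, X)), unname(ols_oracle_predict(X, Y, X)),
               tolerance = 1e-8)
  Xnew <- matrix(rnorm(4 * 6), 4, 6)
  expect_equal(unname(predict(m, Xnew)),
               unname(ols_oracle_predict(X, Y, Xnew)), tolerance = 1e-8)
})

test_that("X scores are mutually orthogonal", {
  set.seed(31)
  X <- matrix(rnorm(20 * 10), 20, 10)
  Y <- matrix(rnorm(20 * 3), 20, 3)
  m <- fit_pls(X, Y, 5)
  G <- crossprod(m$x_scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("permuting Y columns permutes coefficients identically in PLS2", {
  set.seed(41)
  X <- matrix(rnorm(15 * 8), 15, 8)
  Y <- matrix(rnorm(15 * 3), 15, 3)
  m1 <- fit_pls(X, Y, 4)
  m2 <- fit_pls(X, Y[, c(3, 1, 2)], 4)
  expect_equal(unname(m2$coefficients), unname(m1$coefficients[, c(3, 1, 2)]),
               tolerance = 1e-10)
})

test_that("predicting at the calibration mean returns the response mean", {
  set.seed(51)
  X <- matrix(rnorm(10 * 5), 10, 5)
  Y <- matrix(rnorm(10 * 2), 10, 2)
  m <- fit_pls(X, Y, 3)
  at_mean <- predict(m, matrix(m$x_mean, 3, 5, byrow = TRUE))
  expect_equal(unname(at_mean), matrix(m$y_mean, 3, 2, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("dimension mismatches and unattainable factor counts are errors", {
  lib <- test_library()
  x <- simulate_dataset(random_design(8, 2), lib, NULL, noise_sd = 0)
  xw <- window_spectra(x, 215, 240)
  m <- fit_pls(xw, n_factors = 3)
  expect_error(predict(m, window_spectra(x, 210, 240)),
               "wavelength|window")
  expect_error(fit_pls(xw, n_factors = 30), "min\\(n-1, m\\)")
  # noiseless three-component data has rank 3
  expect_error(fit_pls(xw$absorbance,
                       as.matrix(xw$compositions[, 2:4]), 5), "at most 3")
})

test_that("leave-one-out PRESS matches the explicit per-fold refit oracle", {
  lib <- test_library()
  d <- random_design(10, 6)
  x <- simulate_dataset(d, lib, cdom_sampler(), noise_sd = 5e-4, seed = 8)
  X <- x$absorbance[, test_grid() >= 215 & test_grid() <= 240]
  Y <- as.matrix(d[c("no3_uM", "no2_uM", "salinity_psu")])
  cv <- loo_cv(X, Y, h_max = 5)
  expect_equal(cv$press, press_loo_oracle(X, Y, 5), tolerance = 1e-10)
  # PLS2 pooled PRESS is the sum of the per-response PRESS in the same
  # latent space
  expect_equal(cv$press, rowSums(cv$press_per_response), tolerance = 1e-12)
})

test_that("a noiseless rank-3 system cross-validates to zero error at 3 factors", {
  lib <- test_library()
  x <- simulate_dataset(random_design(10, 13), lib, NULL, noise_sd = 0)
  cv <- suppressWarnings(loo_cv(x, h_max = 5))
  expect_equal(cv$h_max, 3L)
  expect_lt(cv$press[3], 1e-10)
})

test_that("Q2 satisfies its defining identity and is undefined at one factor", {
  lib <- test_library()
  x <- simulate_dataset(random_design(12, 17), lib, cdom_sampler(),
                        noise_sd = 5e-4, seed = 19)
  cv <- loo_cv(window_spectra(x, 215, 240), h_max = 6)
  expect_true(is.na(cv$q2[1]))
  for (h in 2:cv$h_max) {
    expect_identical(cv$q2[h], 1 - cv$press[h] / cv$ress[h - 1])
  }
  expect_true(all(cv$press >= 0) && all(cv$ress >= 0))
})

test_that("PLS1 mode runs one cross-validation per response", {
  lib <- test_library()
  x <- simulate_dataset(random_design(12, 23), lib, NULL, noise_sd = 5e-4,
                        seed = 29)
  cvs <- loo_cv(window_spectra(x, 215, 240), h_max = 5, mode = "PLS1")
  expect_named(cvs, c("no3_uM", "no2_uM", "salinity_psu"))
  m <- fit_pls(window_spectra(x, 215, 240), n_factors = 3, mode = "PLS1")
  expect_s3_class(m, "pls1_model")
  yh <- predict(m, window_spectra(x, 215, 240))
  expect_equal(dim(yh), c(12L, 3L))
})

test_that("the factor scan stops after the first failure following a success", {
  thr <- q2_threshold()
  expect_equal(thr, 0.0975)
  # steady passes run to the end of the scan
  expect_equal(select_factors(c(0.5, 0.5, 0.5)), 4L)
  # never significant: one factor
  expect_equal(select_factors(c(0.01, 0.02, 0.05)), 1L)
  # weak early factors are tolerated until the model has taken off
  expect_equal(select_factors(c(0.02, 0.48, 0.95, -1.30, -2.59, -2.35)), 4L)
  # failure after a success ends the scan despite later passes
  expect_equal(select_factors(c(0.5, 0.01, 0.8)), 2L)
})

test_that("cumulative contribution reaches 1 at full rank and is monotone", {
  set.seed(61)
  X <- matrix(rnorm(12 * 5), 12, 5)
  Y <- matrix(rnorm(12), 12, 1)
  m <- fit_pls(X, Y, 5)
  cc <- cumulative_contribution(m)
  expect_false(is.unsorted(cc))
  expect_equal(cc[5], 1, tolerance = 1e-10)
  # rank-1 predictors are fully explained by the first factor
  X1 <- outer(rnorm(8), rnorm(4))
  m1 <- fit_pls(X1, matrix(X1[, 1]), 1)
  expect_equal(cumulative_contribution(m1)[1], 1, tolerance = 1e-10)
})
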