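test_that("default library matches its stated closed forms", {
  lib <- test_library()
  g <- test_grid()
  expect_equal(lib$eps_no3[g == 205], 9600)
  expect_equal(lib$eps_no2[g == 210], 5400)
  expect_equal(lib$eps_salt[g == 240] / lib$eps_salt[g == 200], exp(-5))
  # all three absorbers are spent by 300 nm
  for (nm in c("eps_no3", "eps_no2", "eps_salt")) {
    expect_lt(lib[[nm]][g == 300], 0.01 * max(lib[[nm]]))
  }
  expect_error(default_library(220:300), "200-300")
})

test_that("component_library enforces deep-UV peaks and non-negativity", {
  g <- test_grid()
  expect_error(component_library(g, rep(1, 101), rep(1, 101),
                                 exp(-0.5 * ((g - 250) / 10)^2)),
               "below 230")
  expect_error(component_library(g, c(-1, rep(1, 100)), rep(1, 101),
                                 rep(1, 101)), "non-negative")
})

test_that("simulated spectra follow the forward model exactly at zero noise", {
  lib <- test_library()
  zero <- simulate_spectrum(0, 0, 0, lib, cdom = NULL, noise_sd = 0)
  expect_equal(zero$absorbance, rep(0, 101))
  cd <- cdom_params(0.05, 0.02, 0.002)
  mix <- simulate_spectrum(10, 2, 20, lib, cd, noise_sd = 0)
  parts <- list(simulate_spectrum(10, 0, 0, lib, NULL, 0),
                simulate_spectrum(0, 2, 0, lib, NULL, 0),
                simulate_spectrum(0, 0, 20, lib, NULL, 0))
  expect_equal(mix$absorbance,
               parts[[1]]$absorbance + parts[[2]]$absorbance +
                 parts[[3]]$absorbance + cdom_absorbance(cd, lib$wavelength),
               tolerance = 1e-12)
  expect_error(simulate_spectrum(-1, 0, 0, lib), ">= 0")
})

test_that("mixing is additive in composition at fixed CDOM", {
  lib <- test_library()
  cd <- cdom_params(0.03, 0.018, 0.001)
  f <- function(c3, c2, s) {
    simulate_spectrum(c3, c2, s, lib, cd, noise_sd = 0)$absorbance
  }
  for (i in 1:5) {
    set.seed(i)
    c1 <- runif(3, 0, c(80, 20, 34))
    c2 <- runif(3, 0, c(80, 20, 34))
    lhs <- f(c1[1] + c2[1], c1[2] + c2[2], c1[3] + c2[3])
    rhs <- f(c1[1], c1[2], c1[3]) + f(c2[1], c2[2], c2[3]) - f(0, 0, 0)
    expect_lt(max(abs(lhs - rhs)), 1e-12)
  }
})

test_that("pathlength scales the mixing term but not the CDOM background", {
  lib <- test_library()
  cd <- cdom_params(0.05, 0.02, 0.002)
  a3 <- simulate_spectrum(10, 2, 20, lib, cd, 0, pathlength = 3)$absorbance
  a6 <- simulate_spectrum(10, 2, 20, lib, cd, 0, pathlength = 6)$absorbance
  bg <- cdom_absorbance(cd, lib$wavelength)
  expect_equal(a6 - bg, 2 * (a3 - bg), tolerance = 1e-12)
})

test_that("seeding gives bit-identical spectra and datasets", {
  lib <- test_library()
  s1 <- simulate_spectrum(10, 2, 20, lib, NULL, noise_sd = 5e-4, seed = 9)
  s2 <- simulate_spectrum(10, 2, 20, lib, NULL, noise_sd = 5e-4, seed = 9)
  s3 <- simulate_spectrum(10, 2, 20, lib, NULL, noise_sd = 5e-4, seed = 10)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_false(identical(s1$absorbance, s3$absorbance))
  expect_lt(max(abs(s1$absorbance - s3$absorbance)), 6 * 5e-4)
  d <- random_design(5, 1)
  x1 <- simulate_dataset(d, lib, cdom_sampler(), noise_sd = 5e-4, seed = 3)
  x2 <- simulate_dataset(d, lib, cdom_sampler(), noise_sd = 5e-4, seed = 3)
  expect_identical(x1$absorbance, x2$absorbance)
  expect_identical(attr(x1, "cdom_log"), attr(x2, "cdom_log"))
})

test_that("published design tables are reproduced", {
  d <- table1_design()
  expect_equal(nrow(d$calibration), 34L)
  expect_equal(nrow(d$prediction), 20L)
  expect_equal(unlist(d$calibration[5, c("no3_uM", "no2_uM",
                                         "salinity_psu")], use.names = FALSE),
               c(49.61, 0, 0))
  expect_equal(unlist(d$prediction[11, c("no3_uM", "no2_uM",
                                         "salinity_psu")], use.names = FALSE),
               c(67.18, 11.04, 7.04))
  expect_true(all(d$calibration[-1, -1] >= 0))
})

test_that("noiseless CDOM-free dataset equals the matrix-product oracle", {
  lib <- test_library()
  d <- table1_design()$calibration
  x <- simulate_dataset(d, lib, cdom = NULL, noise_sd = 0)
  E <- rbind(lib$eps_no3 * 1e-6, lib$eps_no2 * 1e-6, lib$eps_salt)
  C <- as.matrix(d[c("no3_uM", "no2_uM", "salinity_psu")])
  expect_equal(unname(x$absorbance), unname(3 * C %*% E), tolerance = 1e-12)
  expect_error(simulate_dataset(d[0, ], lib), "empty")
})
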