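test_that("wide CSV round trip preserves structure and values exactly", {
  grid <- test_grid()
  set.seed(42)
  A <- matrix(runif(3 * length(grid), 0, 2), nrow = 3)
  s <- spectra_set(grid, A, c("a", "b", "c"), pathlength = 3)
  expect_equal(n_spectra(s), 3L)
  expect_length(s$wavelength, 101L)
  for (dialect in c("wide", "long")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_spectra(s, f, dialect)
    s2 <- read_spectra(f, dialect)
    expect_identical(s2$absorbance, s$absorbance)
    expect_identical(s2$wavelength, s$wavelength)
    expect_identical(s2$pathlength, s$pathlength)
    # second round trip is bit-exact too
    f2 <- withr::local_tempfile(fileext = ".csv")
    write_spectra(s2, f2, dialect)
    expect_identical(readLines(f), readLines(f2))
  }
})

test_that("descending wavelength files are re-sorted with a message", {
  grid <- test_grid()
  a <- seq_along(grid) / 100
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,s1",
               paste(rev(grid), rev(a), sep = ",")), f)
  expect_message(s <- read_spectra(f, "wide"), "re-sorted")
  expect_equal(s$wavelength, as.numeric(grid))
  expect_equal(unname(s$absorbance[1, ]), a)
})

test_that("parse errors name the offending sample and wavelength", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,s1,s2",
               "200,0.1,0.2", "201,,0.3", "202,0.3,0.4"), f)
  expect_error(read_spectra(f, "wide"), "s1.*201", ignore.case = TRUE)
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavelength_nm,s1,s1", "200,0.1,0.2", "201,0.2,0.3"), f2)
  expect_error(read_spectra(f2, "wide"), "duplicate")
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,wavelength_nm,absorbance",
               "a,200,0.1", "a,201,0.2", "b,200,0.1"), f3)
  expect_error(read_spectra(f3, "long"), "ragged|missing")
})

test_that("pathlength comment is honoured on read", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# pathlength_cm=1.0", "wavelength_nm,s1",
               paste(test_grid(), 0.5, sep = ",")), f)
  expect_equal(read_spectra(f, "wide")$pathlength, 1.0)
})

test_that("resample interpolates through shared nodes and refuses extrapolation", {
  grid <- test_grid()
  sp <- absorbance_spectrum(grid, sin(grid / 10) + 1)
  expect_equal(resample(sp, grid)$absorbance, sp$absorbance)
  fine <- seq(200, 300, by = 0.5)
  spf <- absorbance_spectrum(fine, approx(grid, sp$absorbance, fine)$y)
  back <- resample(spf, grid)
  expect_equal(back$absorbance, sp$absorbance)
  expect_error(resample(sp, 199:250), "beyond")
})

test_that("windowing is inclusive, strict about off-grid bounds, and nested", {
  set.seed(7)
  s <- spectra_set(test_grid(), matrix(runif(202), nrow = 2))
  w <- window_spectra(s, 215, 240)
  expect_length(w$wavelength, 26L)
  expect_error(window_spectra(s, 240, 215), "lo < hi")
  expect_error(window_spectra(s, 215.5, 240), "not on the wavelength grid")
  expect_identical(window_spectra(w, 215, 240), w)
  # nested windows commute with direct windowing
  expect_identical(window_spectra(window_spectra(s, 210, 260), 220, 240),
                   window_spectra(s, 220, 240))
})

test_that("pathlength rescaling scales absorbance linearly", {
  sp <- absorbance_spectrum(test_grid(), rep(0.3, 101), pathlength = 3)
  r <- rescale_pathlength(sp, 1)
  expect_equal(r$absorbance, rep(0.1, 101))
  expect_equal(r$pathlength, 1)
})

test_that("spectra_set validates grid, ids and composition alignment", {
  expect_error(spectra_set(c(200, 201, 203), matrix(0, 1, 3)), "uniform")
  expect_error(spectra_set(test_grid(), matrix(0, 2, 101), c("a", "a")),
               "duplicate")
  comp <- data.frame(sample_id = c("b", "a"), no3_uM = 1:2, no2_uM = 0,
                     salinity_psu = 0)
  s <- spectra_set(test_grid(), matrix(0, 2, 101), c("a", "b"),
                   compositions = comp)
  expect_equal(s$compositions$sample_id, c("a", "b"))
  expect_equal(s$compositions$no3_uM, c(2, 1))
})
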