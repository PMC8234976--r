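#' Component absorptivity library
#'
#' Molar absorptivity curves for the three UV-absorbing components of the
#' forward model: nitrate and nitrite in L mol^-1 cm^-1, sea salt as a
#' per-psu absorptivity in psu^-1 cm^-1. All three absorb in the deep UV;
#' each curve must peak below 230 nm, which is what makes the deconvolution
#' problem hard (strongly overlapping bands over 200--240 nm).
#'
#' @param wavelength Wavelength grid (nm).
#' @param eps_no3,eps_no2 Molar absorptivity curves (L mol^-1 cm^-1).
#' @param eps_salt Per-salinity absorptivity curve (psu^-1 cm^-1).
#' @return An object of class `"component_library"`.
#' @export
component_library <- function(wavelength, eps_no3, eps_no2, eps_salt) {
  wavelength <- unclass(wavelength_grid(wavelength))
  curves <- list(eps_no3 = as.numeric(eps_no3), eps_no2 = as.numeric(eps_no2),
                 eps_salt = as.numeric(eps_salt))
  for (nm in names(curves)) {
    v <- curves[[nm]]
    if (length(v) != length(wavelength)) {
      stop(nm, " length does not match grid", call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(nm, " must be non-negative and finite", call. = FALSE)
    }
    if (wavelength[which.max(v)] >= 230) {
      stop(nm, " must peak below 230 nm (deep-UV absorber)", call. = FALSE)
    }
  }
  structure(c(list(wavelength = wavelength), curves),
            class = "component_library")
}

#' Default surrogate absorptivity library
#'
#' Parametric surrogate curves emulating the qualitative shapes of the real
#' absorbers: nitrate and nitrite as Gaussian bands centred at 205 and
#' 210 nm, sea salt as an exponential edge decaying away from 200 nm. These
#' are generator plumbing for simulation studies, not calibrated physical
#' constants; all downstream validation is on recovery of known simulated
#' truth, never on these constants themselves.
#'
#' @param grid Wavelength grid (nm); must cover 200--300 nm.
#' @param no3_center,no3_sd,no3_peak Nitrate band centre (nm), width (nm)
#'   and peak absorptivity (L mol^-1 cm^-1).
#' @param no2_center,no2_sd,no2_peak Nitrite band parameters, same units.
#' @param salt_scale Sea-salt absorptivity at 200 nm (psu^-1 cm^-1).
#' @param salt_decay Sea-salt exponential decay length (nm).
#' @return A [component_library()].
#' @export
default_library <- function(grid,
                            no3_center = 205, no3_sd = 11, no3_peak = 9600,
                            no2_center = 210, no2_sd = 13, no2_peak = 5400,
                            salt_scale = 0.02, salt_decay = 8) {
  grid <- unclass(wavelength_grid(grid))
  if (grid[1L] > 200 || grid[length(grid)] < 300) {
    stop("default_library requires a grid covering 200-300 nm", call. = FALSE)
  }
  gauss <- function(center, sd, peak) peak * exp(-0.5 * ((grid - center) / sd)^2)
  component_library(
    grid,
    eps_no3 = gauss(no3_center, no3_sd, no3_peak),
    eps_no2 = gauss(no2_center, no2_sd, no2_peak),
    eps_salt = salt_scale * exp(-(grid - 200) / salt_decay)
  )
}

#' CDOM exponential background parameters
#'
#' The chromophoric dissolved organic matter background is modelled as
#' `A(lambda) = a0 * exp(s * (lambda0 - lambda)) + k`: an exponential decay
#' with spectral slope `s` (nm^-1) anchored at the absorbance `a0` at the
#' reference wavelength `lambda0` (300 nm by convention), plus a constant
#' offset `k` accounting for scattering and instrument drift.
#'
#' @param a0 Absorbance at `lambda0` (AU, >= 0).
#' @param s Spectral slope (nm^-1, > 0).
#' @param k Background offset (AU).
#' @param lambda0 Reference wavelength (nm).
#' @return An object of class `"cdom_params"`.
#' @export
cdom_params <- function(a0, s, k = 0, lambda0 = 300) {
  if (!is.numeric(a0) || a0 < 0) stop("a0 must be >= 0", call. = FALSE)
  if (!is.numeric(s) || s <= 0) stop("spectral slope s must be > 0",
                                     call. = FALSE)
  structure(list(a0 = as.numeric(a0), s = as.numeric(s), k = as.numeric(k),
                 lambda0 = as.numeric(lambda0)),
            class = "cdom_params")
}

#' Evaluate the CDOM exponential at given wavelengths
#'
#' @param params A [cdom_params()].
#' @param wavelength Wavelengths (nm).
#' @return Numeric vector of CDOM absorbance (AU).
#' @export
cdom_absorbance <- function(params, wavelength) {
  params$a0 * exp(params$s * (params$lambda0 - wavelength)) + params$k
}

#' Simulate one seawater absorbance spectrum
#'
#' Beer--Lambert forward model: the analyte mixing term (nitrate + nitrite +
#' sea salt, each absorptivity curve times its concentration) is scaled by
#' the pathlength; the CDOM background is added outside the pathlength
#' factor (it is an empirical absorbance, not a molar term), followed by
#' additive homoscedastic Gaussian instrument noise. Concentrations are
#' given in uM and converted to mol L^-1 internally so user-facing units
#' match routine nutrient reporting.
#'
#' @param no3,no2 Nitrate and nitrite concentrations (uM, >= 0).
#' @param salinity Salinity (psu, >= 0).
#' @param lib A [component_library()].
#' @param cdom A [cdom_params()], or `NULL` for no background.
#' @param noise_sd Instrument noise standard deviation (AU).
#' @param seed Optional integer seed; identical inputs and seed give a
#'   bit-identical spectrum.
#' @param pathlength Pathlength (cm).
#' @param cdom_in_pathlength If `TRUE`, place the CDOM term inside the
#'   pathlength factor instead (sensitivity-analysis alternative; default
#'   keeps it outside).
#' @param sample_id Sample identifier.
#' @return An [absorbance_spectrum()].
#' @export
simulate_spectrum <- function(no3, no2, salinity, lib, cdom = NULL,
                              noise_sd = 5e-4, seed = NULL, pathlength = 3,
                              cdom_in_pathlength = FALSE,
                              sample_id = "sim") {
  if (any(c(no3, no2, salinity) < 0)) {
    stop("generator concentrations must be >= 0", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  mix <- lib$eps_no3 * (no3 * 1e-6) + lib$eps_no2 * (no2 * 1e-6) +
    lib$eps_salt * salinity
  bg <- if (is.null(cdom)) 0 else cdom_absorbance(cdom, lib$wavelength)
  a <- if (cdom_in_pathlength) pathlength * (mix + bg) else
    pathlength * mix + bg
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    a <- a + stats::rnorm(length(a), sd = noise_sd)
  }
  absorbance_spectrum(lib$wavelength, a, pathlength, sample_id)
}

#' Per-sample CDOM parameter sampler
#'
#' Returns a function drawing independent uniform (a0, s, k) triples, used
#' by [simulate_dataset()] to emulate the sample-to-sample variation of
#' CDOM in estuarine and coastal water. Default ranges follow typical
#' coastal CDOM magnitudes and 275--295 nm spectral slopes.
#'
#' @param a0 Range of absorbance at the reference wavelength (AU).
#' @param s Range of spectral slopes (nm^-1).
#' @param k Range of background offsets (AU).
#' @param lambda0 Reference wavelength (nm).
#' @return A function `f(n)` returning a data frame with columns
#'   `a0`, `s`, `k`, `lambda0`.
#' @export
cdom_sampler <- function(a0 = c(0.01, 0.1), s = c(0.014, 0.03),
                         k = c(0, 0.005), lambda0 = 300) {
  force(a0); force(s); force(k); force(lambda0)
  function(n) {
    data.frame(a0 = stats::runif(n, a0[1L], a0[2L]),
               s = stats::runif(n, s[1L], s[2L]),
               k = stats::runif(n, k[1L], k[2L]),
               lambda0 = lambda0)
  }
}

#' Simulate a full spectra set from a composition design
#'
#' Applies [simulate_spectrum()] to every row of a composition design,
#' attaching the compositions and logging per-sample CDOM parameters in
#' the `"cdom_log"` attribute.
#'
#' @param design Data frame with columns `no3_uM`, `no2_uM`, `salinity_psu`
#'   (and optionally `sample_id`), e.g. one element of [table1_design()].
#' @param lib A [component_library()].
#' @param cdom A single [cdom_params()] shared by all samples, a sampler
#'   function as returned by [cdom_sampler()], or `NULL` for no CDOM.
#' @param noise_sd Instrument noise SD (AU).
#' @param seed Optional integer seed for the whole dataset (noise and CDOM
#'   draws).
#' @param pathlength Pathlength (cm).
#' @return A [spectra_set()] with compositions attached.
#' @export
simulate_dataset <- function(design, lib, cdom = cdom_sampler(),
                             noise_sd = 5e-4, seed = NULL, pathlength = 3) {
  design <- as.data.frame(design)
  if (nrow(design) == 0L) stop("empty design", call. = FALSE)
  if (is.null(design$sample_id)) {
    design$sample_id <- paste0("sim", seq_len(nrow(design)))
  }
  design <- validate_compositions(design)
  n <- nrow(design)
  if (!is.null(seed)) set.seed(seed)
  if (is.function(cdom)) {
    pars <- cdom(n)
    cdom_list <- lapply(seq_len(n), function(i) {
      cdom_params(pars$a0[i], pars$s[i], pars$k[i], pars$lambda0[i])
    })
  } else if (is.null(cdom)) {
    cdom_list <- rep(list(NULL), n)
  } else {
    cdom_list <- rep(list(cdom), n)
  }
  A <- matrix(NA_real_, nrow = n, ncol = length(lib$wavelength))
  for (i in seq_len(n)) {
    sp <- simulate_spectrum(design$no3_uM[i], design$no2_uM[i],
                            design$salinity_psu[i], lib, cdom_list[[i]],
                            noise_sd = noise_sd, seed = NULL,
                            pathlength = pathlength,
                            sample_id = design$sample_id[i])
    A[i, ] <- sp$absorbance
  }
  out <- spectra_set(lib$wavelength, A, design$sample_id, pathlength,
                     compositions = design)
  log_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- cdom_list[[i]]
    if (is.null(p)) data.frame(a0 = 0, s = NA_real_, k = 0, lambda0 = NA_real_)
    else data.frame(a0 = p$a0, s = p$s, k = p$k, lambda0 = p$lambda0)
  }))
  log_df <- cbind(sample_id = design$sample_id, log_df)
  attr(out, "cdom_log") <- log_df
  out
}

#' Published calibration / prediction composition design
#'
#' The 34-sample calibration design (single-, two- and three-component
#' mixtures of nitrate, nitrite and sea salt) and the 20-sample randomly
#' composed prediction design used for the spiked-estuary-seawater
#' calibration study, exactly as printed.
#'
#' @return A list with data frames `calibration` (34 rows) and `prediction`
#'   (20 rows), each with columns `sample_id`, `no3_uM`, `no2_uM`,
#'   `salinity_psu`.
#' @export
table1_design <- function() {
  cal <- data.frame(
    sample_id = paste0("cal", 1:34),
    no3_uM = c(0.00, 0.50, 1.98, 9.92, 49.61, 0.00, 0.00, 0.00, 0.00, 0.00,
               0.00, 0.00, 0.00, 4.75, 20.89, 55.12, 9.45, 0.97, 0.00, 0.00,
               0.00, 4.75, 20.89, 0.95, 5.25, 11.67, 8.27, 25.44, 4.75,
               11.81, 20.89, 52.22, 85.62, 26.85),
    no2_uM = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.50, 2.01, 10.06, 20.12, 0.00,
               0.00, 0.00, 0.00, 0.96, 5.30, 0.00, 0.00, 0.00, 9.15, 1.93,
               0.50, 0.96, 5.30, 0.97, 1.06, 2.96, 1.05, 10.32, 0.96, 2.40,
               5.30, 10.59, 2.22, 6.69),
    salinity_psu = c(0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00,
                     6.78, 16.95, 27.12, 33.90, 0.00, 0.00, 15.07, 25.83,
                     33.24, 12.33, 26.08, 33.56, 32.44, 26.76, 26.08, 17.94,
                     19.94, 14.13, 13.91, 8.11, 10.09, 8.92, 8.92, 1.51,
                     8.86)
  )
  pred <- data.frame(
    sample_id = paste0("pred", 1:20),
    no3_uM = c(9.23, 0.49, 4.61, 11.02, 27.54, 34.20, 43.52, 39.12, 23.24,
               9.68, 67.18, 71.87, 66.87, 18.66, 32.56, 12.35, 29.95, 56.71,
               18.11, 35.90),
    no2_uM = c(1.17, 0.49, 2.34, 2.79, 7.95, 6.65, 8.50, 14.60, 4.26, 4.05,
               11.04, 4.86, 5.07, 0.52, 15.97, 8.68, 3.76, 3.56, 2.83, 2.91),
    salinity_psu = c(12.61, 33.24, 25.23, 30.13, 9.32, 12.59, 10.06, 11.25,
                     29.32, 11.23, 7.04, 20.69, 20.54, 9.58, 3.56, 23.98,
                     32.00, 12.54, 23.65, 26.57)
  )
  list(calibration = cal, prediction = pred)
}

#' Published cross-validation reference values
#'
#' Per-factor PRESS, Q2 and cumulative-contribution sequences from the
#' published leave-one-out cross-validation of the 34-sample calibration set
#' on the 215--240 nm window, for the three single-response PLS1 models and
#' the joint PLS2 model. Q2 is undefined at one factor. These printed
#' sequences are reference inputs for checks of the factor-selection rule
#' and of the PRESS pooling convention.
#'
#' @return A list with elements `pls1_no3`, `pls1_no2`, `pls1_salinity`,
#'   `pls2`, each a list with numeric vectors `press` (h = 1..7), `q2`
#'   (h = 2..7) and `cumulative_contribution` (h = 1..4, percent).
#' @export
table2_cv <- function() {
  list(
    pls1_no3 = list(
      press = c(1962, 1391, 327.6, 2.39, 2.51, 2.53, 3.96),
      q2 = c(0.17, 0.77, 0.99, -0.36, -0.75, -2.13),
      cumulative_contribution = c(91.34, 99.50, 99.95, 99.99)
    ),
    pls1_no2 = list(
      press = c(614.3, 504.6, 191.7, 7.24, 8.11, 9.13, 5.81),
      q2 = c(0.02, 0.48, 0.95, -1.30, -2.59, -2.35),
      cumulative_contribution = c(90.52, 99.60, 99.95, 99.99)
    ),
    pls1_salinity = list(
      press = c(3552, 951.9, 61.34, 9.64, 11.67, 12.01, 11.67),
      q2 = c(0.72, 0.92, 0.77, -0.53, -0.78, -1.00),
      cumulative_contribution = c(76.89, 99.62, 99.96, 99.99)
    ),
    pls2 = list(
      press = c(7432, 3651, 543.4, 19.27, 21.89, 23.17, 18.79),
      q2 = c(0.47, 0.80, 0.95, -0.68, -0.95, -0.91),
      cumulative_contribution = c(91.30, 99.62, 99.95, 99.99)
    )
  )
}
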