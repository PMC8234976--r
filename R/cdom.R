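#' Fit the CDOM exponential background
#'
#' Fits `A(lambda) = a0 * exp(s * (lambda0 - lambda)) + k` to the spectrum
#' over the fit window by nonlinear least squares. CDOM dominates seawater
#' absorbance above ~270 nm where nitrate, nitrite and sea salt no longer
#' absorb, so the default window is 275--295 nm; the fitted curve can then
#' be extrapolated into the analytical window and subtracted
#' ([subtract_cdom()]).
#'
#' The additive offset `k` breaks log-linearity, so the fit is a true
#' nonlinear least squares (Levenberg--Marquardt) initialized from a
#' log-linear regression of `A - k0` against `lambda0 - lambda`, with
#' `k0` set just below the window minimum. The slope is box-bounded to
#' `[0.001, 0.1]` nm^-1 to prevent divergence on noise-only windows.
#'
#' The fit window is short relative to the decay length, so the three
#' parameters are nearly collinear and an unconstrained offset lets the fit
#' wander onto a ridge that matches the window but extrapolates wildly. The
#' offset is therefore box-bounded to `[-k_max, k_max]`: physically it is a
#' scattering/drift term of at most a few mAU, not a free baseline.
#'
#' @param s An [absorbance_spectrum()].
#' @param fit_lo,fit_hi Fit window bounds (nm).
#' @param lambda0 Reference wavelength (nm).
#' @param k_max Bound on the magnitude of the offset `k` (AU).
#' @return An object of class `"cdom_fit"`: list with `params`
#'   ([cdom_params()]), `fit_lo`, `fit_hi`, `rss`, `converged`.
#' @export
fit_cdom <- function(s, fit_lo = 275, fit_hi = 295, lambda0 = 300,
                     k_max = 0.01) {
  idx <- window_index(s$wavelength, fit_lo, fit_hi)
  if (length(idx) < 5L) {
    stop("CDOM fit window must contain at least 5 grid points",
         call. = FALSE)
  }
  wl <- s$wavelength[idx]
  a <- s$absorbance[idx]
  dr <- max(a) - min(a)
  if (dr <= 0 || max(a) <= 0) {
    stop("degenerate CDOM fit for sample '", s$sample_id,
         "': no positive dynamic range in [", fit_lo, ", ", fit_hi,
         "] nm; skip the correction for this spectrum", call. = FALSE)
  }
  # log-linear initializer with k taken as 0: the offset is a small drift
  # term, so log(A) ~ log(a0) + s (lambda0 - lambda) is close to linear
  ll <- stats::lm.fit(cbind(1, lambda0 - wl), log(pmax(a, 1e-8)))
  s0 <- min(max(ll$coefficients[2L], 0.001), 0.1)
  a00 <- max(exp(ll$coefficients[1L]), 1e-8)
  k0 <- 0
  dat <- data.frame(wl = wl, a = a)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      a ~ a0 * exp(ss * (lambda0 - wl)) + k,
      data = dat,
      start = list(a0 = a00, ss = s0, k = k0),
      lower = c(a0 = 0, ss = 0.001, k = -k_max),
      upper = c(a0 = Inf, ss = 0.1, k = k_max),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(list(params = cdom_params(a00, s0, k0, lambda0),
                          fit_lo = fit_lo, fit_hi = fit_hi,
                          rss = sum((a - (a00 * exp(s0 * (lambda0 - wl)) +
                                            k0))^2),
                          converged = FALSE),
                     class = "cdom_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(params = cdom_params(cf[["a0"]], cf[["ss"]], cf[["k"]],
                                      lambda0),
                 fit_lo = fit_lo, fit_hi = fit_hi,
                 rss = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv),
            class = "cdom_fit")
}

#' @export
print.cdom_fit <- function(x, ...) {
  cat("<cdom_fit> a0 =", signif(x$params$a0, 4),
      " s =", signif(x$params$s, 4), "nm^-1  k =", signif(x$params$k, 4),
      " (fit", x$fit_lo, "-", x$fit_hi, "nm, rss =", signif(x$rss, 3),
      if (x$converged) ", converged" else ", NOT converged", ")\n")
  invisible(x)
}

#' Subtract a fitted CDOM background
#'
#' Evaluates the fitted exponential (including the offset `k`) at every
#' wavelength of the target window and subtracts it; values outside the
#' window are left unchanged. Small negative corrected absorbances are
#' permitted (not clipped). By default the whole spectrum is corrected,
#' which is equivalent for any downstream regression restricted to a
#' sub-window.
#'
#' @param s An [absorbance_spectrum()].
#' @param fit A converged [fit_cdom()] result.
#' @param target_lo,target_hi Window to correct (nm); default full span.
#' @return Corrected [absorbance_spectrum()].
#' @export
subtract_cdom <- function(s, fit, target_lo = NULL, target_hi = NULL) {
  if (!inherits(fit, "cdom_fit")) stop("fit must be a cdom_fit",
                                       call. = FALSE)
  if (!isTRUE(fit$converged)) {
    stop("refusing to subtract an unconverged CDOM fit for sample '",
         s$sample_id, "'", call. = FALSE)
  }
  if (is.null(target_lo)) target_lo <- s$wavelength[1L]
  if (is.null(target_hi)) target_hi <- s$wavelength[length(s$wavelength)]
  idx <- window_index(s$wavelength, target_lo, target_hi)
  s$absorbance[idx] <- s$absorbance[idx] -
    cdom_absorbance(fit$params, s$wavelength[idx])
  s
}

#' Fit and subtract CDOM for every spectrum of a set
#'
#' Applies [fit_cdom()] then [subtract_cdom()] to each spectrum. The
#' correction is applied uniformly to calibration standards and unknowns
#' alike (standards prepared from natural seawater contain CDOM too).
#' Spectra with a degenerate or unconverged fit are left uncorrected with a
#' warning; per-sample fits are recorded in the `"cdom_fits"` attribute.
#'
#' @param x A [spectra_set()].
#' @param fit_lo,fit_hi CDOM fit window (nm).
#' @param lambda0 Reference wavelength (nm).
#' @param target_lo,target_hi Correction window (nm); default full span.
#' @return Corrected [spectra_set()] with attribute `"cdom_fits"` (a list
#'   of `cdom_fit` or `NULL` per sample).
#' @export
correct_cdom <- function(x, fit_lo = 275, fit_hi = 295, lambda0 = 300,
                         target_lo = NULL, target_hi = NULL) {
  fits <- vector("list", n_spectra(x))
  names(fits) <- x$sample_id
  for (i in seq_len(n_spectra(x))) {
    sp <- get_spectrum(x, i)
    fit <- tryCatch(fit_cdom(sp, fit_lo, fit_hi, lambda0),
                    error = function(e) {
                      warning("CDOM correction skipped for sample '",
                              sp$sample_id, "': ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (!is.null(fit) && isTRUE(fit$converged)) {
      sp2 <- subtract_cdom(sp, fit, target_lo, target_hi)
      x$absorbance[i, ] <- sp2$absorbance
      fits[[i]] <- fit
    } else if (!is.null(fit)) {
      warning("CDOM fit did not converge for sample '", sp$sample_id,
              "'; spectrum left uncorrected", call. = FALSE)
    }
  }
  attr(x, "cdom_fits") <- fits
  x
}
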