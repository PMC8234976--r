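#' Estimate component absorptivities from single-component standards
#'
#' For each component (nitrate, nitrite, sea salt) the absorptivity at each
#' wavelength is estimated by zero-intercept least squares of
#' `absorbance / pathlength` against concentration, using the standards in
#' which only that component is non-zero. Blanks are allowed and have no
#' effect on the zero-intercept fit.
#'
#' @param standards A [spectra_set()] with compositions in which every
#'   sample has at most one non-zero component.
#' @return A [component_library()] on the standards' grid.
#' @export
build_library_from_standards <- function(standards) {
  comp <- standards$compositions
  if (is.null(comp)) stop("standards need attached compositions",
                          call. = FALSE)
  conc <- as.matrix(comp[c("no3_uM", "no2_uM", "salinity_psu")])
  nz <- conc > 0
  if (any(rowSums(nz) > 1L)) {
    stop("standards must be single-component (sample '",
         comp$sample_id[which(rowSums(nz) > 1L)[1L]],
         "' has several non-zero components)", call. = FALSE)
  }
  A <- standards$absorbance / standards$pathlength
  curves <- lapply(1:3, function(j) {
    rows <- which(nz[, j])
    if (!length(rows)) {
      stop("no non-zero standard for component '",
           colnames(conc)[j], "'", call. = FALSE)
    }
    c_j <- conc[rows, j]
    if (j <= 2L) c_j <- c_j * 1e-6           # uM -> mol L^-1
    # zero-intercept LS per wavelength: eps = sum(c * A) / sum(c^2)
    drop(crossprod(c_j, A[rows, , drop = FALSE])) / sum(c_j^2)
  })
  component_library(standards$wavelength, eps_no3 = pmax(curves[[1L]], 0),
                    eps_no2 = pmax(curves[[2L]], 0),
                    eps_salt = pmax(curves[[3L]], 0))
}

#' Classical least squares fit of one spectrum
#'
#' Fits the full Beer--Lambert forward model — pathlength times the three
#' known absorptivity curves scaled by their concentrations, plus the CDOM
#' exponential with offset — jointly to a measured spectrum over the fit
#' window. The CDOM spectral slope is the only nonlinear parameter, so the
#' fit is solved by variable projection: for each candidate slope the
#' remaining five parameters (two concentrations, salinity, CDOM amplitude
#' and offset) are obtained exactly by linear least squares; the slope is
#' scanned on a grid over `[0.005, 0.05]` nm^-1 and polished by
#' golden-section search around the grid minimum. Deterministic, no
#' multistart. Concentrations are not constrained non-negative, matching
#' the unconstrained PLS side of the comparison.
#'
#' The default window is 200--240 nm rather than the 215--240 nm PLS
#' window: with five free parameters the narrow window is too
#' ill-conditioned (condition number above 1e5) and ordinary photometric
#' noise then dominates the solution, while 200--240 nm anchors both the
#' component bands and the CDOM exponential.
#'
#' @param s An [absorbance_spectrum()] (raw, not CDOM-corrected: the CDOM
#'   term is part of the model).
#' @param lib A [component_library()] on a grid containing the window.
#' @param window Fit window `c(lo, hi)` in nm.
#' @param slope_grid Candidate CDOM slopes (nm^-1).
#' @param lambda0 CDOM reference wavelength (nm).
#' @return An object of class `"cls_result"`: list with `composition`
#'   (named vector, uM / uM / psu), `cdom` ([cdom_params()]), `rss`,
#'   `converged` and the fitted `slope`.
#' @export
fit_cls <- function(s, lib, window = c(200, 240),
                    slope_grid = seq(0.005, 0.05, by = 0.001),
                    lambda0 = 300) {
  idx_s <- window_index(s$wavelength, window[1L], window[2L])
  idx_l <- window_index(lib$wavelength, window[1L], window[2L])
  wl <- s$wavelength[idx_s]
  if (length(idx_l) != length(idx_s) ||
      any(abs(lib$wavelength[idx_l] - wl) > 1e-8)) {
    stop("spectrum and library grids differ over the window", call. = FALSE)
  }
  a <- s$absorbance[idx_s]
  b <- s$pathlength
  Xfix <- cbind(no3 = b * lib$eps_no3[idx_l] * 1e-6,
                no2 = b * lib$eps_no2[idx_l] * 1e-6,
                sal = b * lib$eps_salt[idx_l])
  lin_fit <- function(slope) {
    M <- cbind(Xfix, cdom = exp(slope * (lambda0 - wl)), offset = 1)
    qr_m <- qr(M)
    if (qr_m$rank < ncol(M)) {
      stop("singular CLS subproblem over [", window[1L], ", ", window[2L],
           "] nm (condition number ", format(kappa(M), digits = 3),
           "); widen the window", call. = FALSE)
    }
    beta <- qr.coef(qr_m, a)
    list(beta = beta, rss = sum((a - M %*% beta)^2))
  }
  rss_of <- function(slope) lin_fit(slope)$rss
  rss_grid <- vapply(slope_grid, rss_of, numeric(1L))
  i0 <- which.min(rss_grid)
  lo <- slope_grid[max(1L, i0 - 1L)]
  hi <- slope_grid[min(length(slope_grid), i0 + 1L)]
  opt <- stats::optimize(rss_of, interval = c(lo, hi), tol = 1e-10)
  slope <- opt$minimum
  fin <- lin_fit(slope)
  comp <- c(no3_uM = unname(fin$beta["no3"]),
            no2_uM = unname(fin$beta["no2"]),
            salinity_psu = unname(fin$beta["sal"]))
  structure(
    list(composition = comp,
         cdom = cdom_params(max(fin$beta[["cdom"]], 0), slope,
                            fin$beta[["offset"]], lambda0),
         rss = fin$rss, converged = TRUE, slope = slope),
    class = "cls_result"
  )
}

#' @export
print.cls_result <- function(x, ...) {
  cat("<cls_result> NO3- =", signif(x$composition[["no3_uM"]], 4),
      "uM, NO2- =", signif(x$composition[["no2_uM"]], 4),
      "uM, salinity =", signif(x$composition[["salinity_psu"]], 4),
      "psu (rss =", signif(x$rss, 3), ")\n")
  invisible(x)
}

#' CLS predictions for every spectrum of a set
#'
#' @param x A [spectra_set()].
#' @param lib A [component_library()].
#' @param window Fit window (nm).
#' @param ... Passed to [fit_cls()].
#' @return Matrix of fitted compositions (samples x 3), with per-sample
#'   CDOM fits and residual sums of squares in attributes.
#' @export
predict_cls <- function(x, lib, window = c(200, 240), ...) {
  res <- lapply(seq_len(n_spectra(x)), function(i) {
    fit_cls(get_spectrum(x, i), lib, window, ...)
  })
  out <- do.call(rbind, lapply(res, function(r) r$composition))
  rownames(out) <- x$sample_id
  attr(out, "cdom") <- lapply(res, function(r) r$cdom)
  attr(out, "rss") <- vapply(res, function(r) r$rss, numeric(1L))
  out
}
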