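#' @keywords internal
#' NIPALS PLS decomposition of mean-centered X and Y.
#' Deterministic start from the Y column of largest (deflated) sum of
#' squares; inner loop converges on the weight vector to `tol`. Stops early
#' when the centered X (or Y) is exhausted, returning the achieved number
#' of factors.
nipals_pls <- function(Xc, Yc, h, tol = 1e-12, max_iter = 500L) {
  n <- nrow(Xc); m <- ncol(Xc); k <- ncol(Yc)
  W <- matrix(0, m, h); P <- matrix(0, m, h); C <- matrix(0, k, h)
  Tm <- matrix(0, n, h); U <- matrix(0, n, h)
  x_ss0 <- sum(Xc^2)
  achieved <- 0L
  for (a in seq_len(h)) {
    if (sum(Xc^2) <= x_ss0 * 1e-20) break       # X rank exhausted
    j0 <- which.max(colSums(Yc^2))
    u <- Yc[, j0]
    if (sum(u^2) <= .Machine$double.xmin) break # Y fully explained
    w_old <- rep(0, m)
    tt <- NULL; cc <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u))
      nw <- sqrt(sum(w^2))
      if (nw <= .Machine$double.xmin) break
      w <- w / nw
      tt <- drop(Xc %*% w)
      cc <- drop(crossprod(Yc, tt)) / sum(tt^2)
      if (k == 1L) break
      u <- drop(Yc %*% cc) / sum(cc^2)
      if (sum((w - w_old)^2) < tol^2) break
      w_old <- w
    }
    if (is.null(tt) || sum(tt^2) <= x_ss0 * 1e-24) break
    p <- drop(crossprod(Xc, tt)) / sum(tt^2)
    Xc <- Xc - tcrossprod(tt, p)
    Yc <- Yc - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- p; C[, a] <- cc; Tm[, a] <- tt; U[, a] <- u
    achieved <- a
  }
  list(W = W[, seq_len(achieved), drop = FALSE],
       P = P[, seq_len(achieved), drop = FALSE],
       C = C[, seq_len(achieved), drop = FALSE],
       T = Tm[, seq_len(achieved), drop = FALSE],
       U = U[, seq_len(achieved), drop = FALSE],
       achieved = achieved, x_ss0 = x_ss0)
}

pls_coefficients <- function(dec, h) {
  # B = W (P'W)^-1 C' using the first h factors; P'W is upper triangular
  W <- dec$W[, seq_len(h), drop = FALSE]
  P <- dec$P[, seq_len(h), drop = FALSE]
  C <- dec$C[, seq_len(h), drop = FALSE]
  R <- W %*% backsolve(crossprod(P, W), diag(h), upper.tri = TRUE)
  R %*% t(C)
}

#' Fit a PLS calibration model
#'
#' NIPALS partial least squares relating an `n x m` matrix of predictors
#' (absorbance at each wavelength) to an `n x k` matrix of responses
#' (nitrate, nitrite, salinity). Successive latent factors maximize the
#' covariance between X scores and Y scores. `"PLS2"` fits all responses
#' jointly with one common factor set; `"PLS1"` fits a separate
#' single-response model per response and returns them as a bundle. Both X
#' and Y are mean-centered internally (no variance scaling); the centering
#' vectors are stored with the model.
#'
#' @param X Numeric predictor matrix (samples x wavelengths), or a
#'   [spectra_set()] with compositions attached (then `Y` may be omitted).
#' @param Y Numeric response matrix (samples x responses).
#' @param n_factors Number of latent factors `h` (1 <= h <= min(n-1, m) and
#'   at most the rank of centered X).
#' @param mode `"PLS2"` or `"PLS1"`.
#' @param wavelength Optional wavelength grid labelling the predictor
#'   columns (stored for window checking at prediction time).
#' @return For `"PLS2"` (or a single response) an object of class
#'   `"pls_model"`; for `"PLS1"` with several responses an object of class
#'   `"pls1_model"` bundling one `pls_model` per response.
#' @export
fit_pls <- function(X, Y = NULL, n_factors, mode = c("PLS2", "PLS1"),
                    wavelength = NULL) {
  mode <- match.arg(mode)
  if (inherits(X, "spectra_set")) {
    if (is.null(Y)) {
      if (is.null(X$compositions)) {
        stop("spectra_set has no compositions; supply Y", call. = FALSE)
      }
      Y <- as.matrix(X$compositions[c("no3_uM", "no2_uM", "salinity_psu")])
    }
    wavelength <- X$wavelength
    X <- X$absorbance
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); k <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y row counts differ", call. = FALSE)
  h_cap <- min(n - 1L, m)
  if (n_factors < 1L || n_factors > h_cap) {
    stop("n_factors must be between 1 and min(n-1, m) = ", h_cap,
         call. = FALSE)
  }
  if (mode == "PLS1" && k > 1L) {
    models <- lapply(seq_len(k), function(j) {
      fit_pls(X, Y[, j, drop = FALSE], n_factors, mode = "PLS1",
              wavelength = wavelength)
    })
    names(models) <- colnames(Y)
    return(structure(list(models = models, mode = "PLS1",
                          n_factors = n_factors,
                          response_names = colnames(Y)),
                     class = "pls1_model"))
  }
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  if (any(colSums(Xc^2) == 0)) {
    warning("constant predictor column(s): zero weight after centering",
            call. = FALSE)
  }
  dec <- nipals_pls(Xc, Yc, n_factors)
  if (dec$achieved < n_factors) {
    stop("requested ", n_factors, " factors but centered X supports at ",
         "most ", dec$achieved, call. = FALSE)
  }
  structure(
    list(mode = mode, x_mean = xm, y_mean = ym,
         weights = dec$W, x_loadings = dec$P, y_loadings = dec$C,
         x_scores = dec$T, y_scores = dec$U,
         coefficients = pls_coefficients(dec, n_factors),
         n_factors = n_factors, x_ss0 = dec$x_ss0,
         wavelength = wavelength,
         window = if (!is.null(wavelength)) range(wavelength),
         response_names = colnames(Y)),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$mode, ", ", x$n_factors, " factor(s), ",
      length(x$x_mean), " wavelengths",
      if (!is.null(x$window)) paste0(" [", x$window[1L], "-", x$window[2L],
                                     " nm]"),
      ", ", ncol(x$coefficients), " response(s)\n", sep = "")
  invisible(x)
}

#' @export
print.pls1_model <- function(x, ...) {
  cat("<pls1_model> bundle of", length(x$models),
      "single-response models,", x$n_factors, "factor(s) each\n")
  invisible(x)
}

#' Predict responses from a PLS model
#'
#' `Yhat = (X - x_mean) B + y_mean`. Negative predictions are permitted
#' (near-zero true concentrations can legitimately predict slightly
#' negative).
#'
#' @param object A `pls_model` or `pls1_model`.
#' @param newdata Predictor matrix or [spectra_set()] on the model's
#'   wavelength window.
#' @param ... Unused.
#' @return Numeric matrix of predicted responses (samples x responses).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    if (!is.null(object$wavelength) &&
        (length(newdata$wavelength) != length(object$wavelength) ||
         any(abs(newdata$wavelength - object$wavelength) > 1e-8))) {
      stop("spectra are not on the model's wavelength window [",
           object$window[1L], ", ", object$window[2L], "] nm", call. = FALSE)
    }
    newdata <- newdata$absorbance
  }
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_mean)) {
    stop("model expects ", length(object$x_mean), " wavelengths",
         if (!is.null(object$window)) paste0(" (window [", object$window[1L],
                                             ", ", object$window[2L],
                                             "] nm)"),
         " but got ", ncol(X), call. = FALSE)
  }
  out <- sweep(X, 2L, object$x_mean) %*% object$coefficients
  out <- sweep(out, 2L, object$y_mean, "+")
  colnames(out) <- object$response_names
  out
}

#' @export
predict.pls1_model <- function(object, newdata, ...) {
  out <- do.call(cbind, lapply(object$models, predict, newdata = newdata))
  colnames(out) <- object$response_names
  out
}

#' Q-squared significance threshold
#'
#' The cross-validation significance cutoff used for factor selection: a
#' factor is retained while `Q2 = 1 - PRESS_h / RESS_(h-1)` stays at or
#' above `1 - press_ratio^2`. With the conventional `press_ratio = 0.95`
#' this is 0.0975, corresponding to approximately p <= 0.05 for the added
#' factor.
#'
#' @param press_ratio Maximum acceptable ratio of LOO prediction error to
#'   the previous fitted residual (on the RMS scale).
#' @return The Q2 cutoff (numeric scalar).
#' @export
q2_threshold <- function(press_ratio = 0.95) 1 - press_ratio^2

#' Leave-one-out cross-validation of a PLS calibration
#'
#' For each left-out sample the model is refit from scratch on the
#' remaining `n - 1` samples — including re-computing the centering means,
#' so no information leaks from the held-out sample — and the sample is
#' predicted at every factor count `h = 1..h_max`. Reports, per `h`:
#'
#' * `press[h]`: the prediction error sum of squares, i.e. squared LOO
#'   prediction errors summed over samples (and pooled over responses in
#'   PLS2, in original units);
#' * `ress[h]`: the *full-data* fitted residual sum of squares at `h`
#'   factors (not cross-validated);
#' * `q2[h] = 1 - press[h] / ress[h-1]`, undefined at `h = 1`.
#'
#' @param X Predictor matrix or [spectra_set()] with compositions.
#' @param Y Response matrix (omit when `X` is a spectra_set with
#'   compositions).
#' @param h_max Largest factor count to evaluate (clipped to `n - 2` and to
#'   the rank of X, with a warning).
#' @param mode `"PLS2"` (one pooled CV) or `"PLS1"` (one CV per response).
#' @param threshold Q2 cutoff for [select_factors()].
#' @return For `"PLS2"` an object of class `"cv_result"`; for `"PLS1"` a
#'   named list of `cv_result`, one per response.
#' @export
loo_cv <- function(X, Y = NULL, h_max, mode = c("PLS2", "PLS1"),
                   threshold = q2_threshold()) {
  mode <- match.arg(mode)
  if (inherits(X, "spectra_set")) {
    if (is.null(Y)) {
      Y <- as.matrix(X$compositions[c("no3_uM", "no2_uM", "salinity_psu")])
    }
    X <- X$absorbance
  }
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); k <- ncol(Y)
  if (n < 3L) stop("leave-one-out CV needs at least 3 samples",
                   call. = FALSE)
  if (h_max > n - 2L) {
    warning("h_max clipped from ", h_max, " to n - 2 = ", n - 2L,
            call. = FALSE)
    h_max <- n - 2L
  }
  if (mode == "PLS1" && k > 1L) {
    out <- lapply(seq_len(k), function(j) {
      loo_cv(X, Y[, j, drop = FALSE], h_max, mode = "PLS1",
             threshold = threshold)
    })
    names(out) <- colnames(Y)
    return(out)
  }

  xm <- colMeans(X); ym <- colMeans(Y)
  full <- nipals_pls(sweep(X, 2L, xm), sweep(Y, 2L, ym), h_max)
  if (full$achieved < h_max) {
    warning("h_max clipped from ", h_max, " to the attainable rank ",
            full$achieved, call. = FALSE)
    h_max <- full$achieved
  }
  if (h_max < 1L) stop("centered X has rank 0", call. = FALSE)

  # full-data residual SS at 0..h_max factors (ress[h] per Eq for RESS_h)
  Yc <- sweep(Y, 2L, ym)
  ress_pr <- matrix(NA_real_, h_max + 1L, k)   # row h+1 = h factors
  ress_pr[1L, ] <- colSums(Yc^2)
  resid <- Yc
  for (h in seq_len(h_max)) {
    resid <- resid - tcrossprod(full$T[, h], full$C[, h])
    ress_pr[h + 1L, ] <- colSums(resid^2)
  }

  press_pr <- matrix(0, h_max, k)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    xmi <- colMeans(Xi); ymi <- colMeans(Yi)
    di <- nipals_pls(sweep(Xi, 2L, xmi), sweep(Yi, 2L, ymi), h_max)
    xt <- X[i, ] - xmi
    yhat <- ymi
    err2_prev <- (Y[i, ] - yhat)^2
    for (h in seq_len(h_max)) {
      if (h <= di$achieved) {
        t_h <- sum(xt * di$W[, h])
        xt <- xt - t_h * di$P[, h]
        yhat <- yhat + t_h * di$C[, h]
        err2_prev <- (Y[i, ] - yhat)^2
      }
      press_pr[h, ] <- press_pr[h, ] + err2_prev
    }
  }

  press <- rowSums(press_pr)
  ress_all <- rowSums(ress_pr)
  ress <- ress_all[-1L]                 # ress[h], h = 1..h_max
  q2 <- c(NA_real_, 1 - press[-1L] / ress[seq_len(h_max - 1L)])
  tss_fac <- colSums(full$T^2) * colSums(full$P^2)
  cumcontrib <- cumsum(tss_fac) / full$x_ss0
  res <- structure(
    list(press = press, ress = ress, ress0 = ress_all[1L], q2 = q2,
         press_per_response = press_pr, ress_per_response = ress_pr[-1L, ,
                                                                    drop = FALSE],
         cumulative_contribution = cumcontrib,
         h_max = h_max, mode = mode, threshold = threshold,
         response_names = colnames(Y)),
    class = "cv_result"
  )
  res$selected_h <- select_factors(res, threshold)
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$mode, ", h = 1..", x$h_max, ", selected_h = ",
      x$selected_h, "\n", sep = "")
  print(data.frame(h = seq_len(x$h_max), PRESS = signif(x$press, 4),
                   RESS = signif(x$ress, 4), Q2 = round(x$q2, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Select the number of latent factors by the Q-squared rule
#'
#' Scans `h = 2, 3, ...` upward. A factor is significant when its
#' `Q2[h] >= threshold`. The scan tolerates sub-threshold values occurring
#' *before* the first significant factor (early factors can have weak
#' incremental Q2 while the model is still far from complete) and stops at
#' the first failure *after* a success — at that point adding another
#' factor no longer improves precision. Returns the largest significant
#' `h`, or 1 if no factor ever reaches the threshold.
#'
#' @param x A numeric vector of Q2 values for `h = 2, 3, ...`, or a
#'   `cv_result` from [loo_cv()].
#' @param threshold Significance cutoff (default [q2_threshold()]).
#' @return Selected factor count (integer >= 1).
#' @export
select_factors <- function(x, threshold = q2_threshold()) {
  UseMethod("select_factors")
}

#' @export
select_factors.cv_result <- function(x, threshold = q2_threshold()) {
  if (x$h_max < 2L) return(1L)
  select_factors(x$q2[2:x$h_max], threshold)
}

#' @export
select_factors.numeric <- function(x, threshold = q2_threshold()) {
  h_sel <- 1L
  any_pass <- FALSE
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && x[i] >= threshold) {
      h_sel <- i + 1L
      any_pass <- TRUE
    } else if (any_pass) {
      break
    }
  }
  h_sel
}

#' Cumulative X-variance contribution of the latent factors
#'
#' Fraction of the centered predictor variance explained by the first
#' `1..h` factors; non-decreasing, reaching 1 at full rank.
#'
#' @param model A `pls_model`.
#' @param X Optional predictor matrix to recompute the total centered sum
#'   of squares from (defaults to the calibration X the model stored).
#' @return Numeric vector of cumulative fractions, length `n_factors`.
#' @export
cumulative_contribution <- function(model, X = NULL) {
  if (inherits(model, "pls1_model")) {
    return(lapply(model$models, cumulative_contribution, X = X))
  }
  tot <- if (is.null(X)) model$x_ss0 else {
    X <- as.matrix(X)
    sum(sweep(X, 2L, colMeans(X))^2)
  }
  tss_fac <- colSums(model$x_scores^2) * colSums(model$x_loadings^2)
  cumsum(tss_fac) / tot
}
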