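#' Root mean square error of prediction
#'
#' `sqrt(mean((actual - predicted)^2))`, in the response's own units.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
rmsep <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted lengths differ", call. = FALSE)
  }
  if (length(actual) < 1L) stop("need at least one sample", call. = FALSE)
  sqrt(mean((actual - predicted)^2))
}

#' Squared correlation between predicted and actual values
#'
#' The squared sample Pearson correlation; affine-invariant, so a
#' perfectly linear (even biased or inverted) prediction scores 1.
#'
#' @param actual,predicted Numeric vectors, length >= 2, each with nonzero
#'   variance.
#' @return Scalar in `[0, 1]`.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted lengths differ", call. = FALSE)
  }
  if (length(actual) < 2L) stop("need at least two samples", call. = FALSE)
  if (stats::var(actual) == 0 || stats::var(predicted) == 0) {
    stop("r_squared undefined: zero variance", call. = FALSE)
  }
  stats::cor(actual, predicted)^2
}

#' Mean relative prediction error
#'
#' Mean of `(predicted - actual) / actual` over the samples, term-wise
#' absolute by default (the minimized form used in wavelength screening);
#' `mode = "signed"` retains the sign for bias analysis. Samples with
#' `actual == 0` are excluded (the division is undefined there); the
#' number excluded is reported in the `"n_excluded"` attribute.
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @param mode `"absolute"` (default) or `"signed"`.
#' @return Scalar (fraction, not percent) with attribute `"n_excluded"`.
#' @export
relative_error <- function(actual, predicted, mode = c("absolute",
                                                       "signed")) {
  mode <- match.arg(mode)
  if (length(actual) != length(predicted)) {
    stop("actual and predicted lengths differ", call. = FALSE)
  }
  keep <- actual != 0
  if (!any(keep)) {
    stop("relative error undefined: all actual values are zero",
         call. = FALSE)
  }
  terms <- (predicted[keep] - actual[keep]) / actual[keep]
  if (mode == "absolute") terms <- abs(terms)
  structure(mean(terms), n_excluded = sum(!keep))
}

#' Limit of detection from replicate analyses
#'
#' `k` times the sample standard deviation (n - 1 denominator, the
#' replicate-precision convention) of replicate determinations of a
#' low-concentration sample; `k = 3` gives the conventional detection
#' limit.
#'
#' @param replicates Numeric vector of replicate predictions (>= 2).
#' @param k SD multiplier.
#' @return Detection limit in the replicates' units.
#' @export
lod <- function(replicates, k = 3) {
  if (length(replicates) < 2L) {
    stop("limit of detection needs at least 2 replicates", call. = FALSE)
  }
  k * stats::sd(replicates)
}

#' Relative standard deviation of replicates (percent)
#'
#' @param replicates Numeric vector (>= 2) with nonzero mean.
#' @return RSD in percent.
#' @export
rsd <- function(replicates) {
  if (length(replicates) < 2L) {
    stop("RSD needs at least 2 replicates", call. = FALSE)
  }
  m <- mean(replicates)
  if (m == 0) stop("RSD undefined: zero mean", call. = FALSE)
  100 * stats::sd(replicates) / m
}

#' Spike recovery (percent)
#'
#' Found concentration as a percentage of the expected (spiked plus
#' background) concentration in a fortified sample.
#'
#' @param expected_total Expected concentration (> 0).
#' @param found Measured concentration.
#' @return Recovery in percent.
#' @export
recovery <- function(expected_total, found) {
  if (any(expected_total <= 0)) {
    stop("expected concentration must be > 0", call. = FALSE)
  }
  100 * found / expected_total
}

#' Per-response evaluation report
#'
#' RMSEP, squared correlation and mean relative error for each response of
#' a prediction set.
#'
#' @param actual,predicted Matrices (samples x responses) with matching
#'   dimensions.
#' @param response_names Optional column labels.
#' @return A data frame with one row per response: `response`, `rmsep`,
#'   `r2`, `re`, `n`, `n_re_excluded`.
#' @export
metrics_report <- function(actual, predicted, response_names = NULL) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  if (!all(dim(actual) == dim(predicted))) {
    stop("actual and predicted dimensions differ", call. = FALSE)
  }
  if (is.null(response_names)) {
    response_names <- colnames(actual)
    if (is.null(response_names)) {
      response_names <- paste0("y", seq_len(ncol(actual)))
    }
  }
  do.call(rbind, lapply(seq_len(ncol(actual)), function(j) {
    re_j <- tryCatch(relative_error(actual[, j], predicted[, j]),
                     error = function(e) structure(NA_real_,
                                                   n_excluded = NA_integer_))
    data.frame(response = response_names[j],
               rmsep = rmsep(actual[, j], predicted[, j]),
               r2 = tryCatch(r_squared(actual[, j], predicted[, j]),
                             error = function(e) NA_real_),
               re = as.numeric(re_j),
               n = nrow(actual),
               n_re_excluded = attr(re_j, "n_excluded"))
  }))
}
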