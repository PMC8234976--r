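#' Interval-PLS screening windows
#'
#' Sliding wavelength windows of `width_points` grid points (15 nm span at
#' 1 nm resolution) advancing by `step` nm over `[lo, hi]`. When the last
#' regular window falls short of `hi` it is replaced by one clipped to end
#' exactly at `hi`, reproducing the conventional irregular final interval
#' (..., 270--285, 285--300) rather than forcing arithmetic regularity.
#'
#' @param lo,hi Screening range bounds (nm).
#' @param width_points Window width in grid points.
#' @param step Window advance (nm).
#' @param spacing Grid spacing (nm).
#' @return A list of numeric `c(lo, hi)` windows.
#' @export
ipls_intervals <- function(lo = 200, hi = 300, width_points = 16L,
                           step = 10, spacing = 1) {
  span <- (width_points - 1L) * spacing
  if (lo + span > hi) {
    stop("window width (", span, " nm span) exceeds the screening range [",
         lo, ", ", hi, "] nm", call. = FALSE)
  }
  starts <- seq(lo, hi - span, by = step)
  wins <- lapply(starts, function(s) c(s, s + span))
  last <- wins[[length(wins)]]
  if (last[2L] < hi) wins[[length(wins)]] <- c(hi - span, hi)
  wins
}

#' Score one candidate window
#'
#' Fits a PLS model on the calibration set restricted to the window (factor
#' count chosen by the Q2 rule via leave-one-out CV within the window) and
#' evaluates RMSEP, R-squared and mean relative error per response on the
#' prediction set — or, with `use_cv = TRUE`, scores by the calibration
#' LOO error instead, which avoids reusing the prediction set during
#' selection. The pooled score averages RMSEP over responses after
#' normalizing each by its calibration range, since uM and psu are not
#' commensurable.
#'
#' @param cal Calibration [spectra_set()] with compositions (CDOM-corrected
#'   upstream if the workflow calls for it).
#' @param pred Prediction [spectra_set()] with compositions.
#' @param w Numeric `c(lo, hi)` window (nm).
#' @param mode `"PLS2"` or `"PLS1"`.
#' @param threshold Q2 cutoff for factor selection.
#' @param h_max Largest factor count tried.
#' @param use_cv Score by calibration LOO RMSE instead of the prediction
#'   set.
#' @return An object of class `"window_score"`: list with `lo`, `hi`,
#'   per-response `rmsep`, `r2`, `re`, the `pooled_score` and the selected
#'   factor count `n_factors`.
#' @export
score_window <- function(cal, pred, w, mode = c("PLS2", "PLS1"),
                         threshold = q2_threshold(), h_max = 7L,
                         use_cv = FALSE) {
  mode <- match.arg(mode)
  idx <- window_index(cal$wavelength, w[1L], w[2L])
  if (length(idx) < 2L) stop("window has fewer than 2 grid points",
                             call. = FALSE)
  cal_w <- window_spectra(cal, w[1L], w[2L])
  Ycal <- as.matrix(cal_w$compositions[c("no3_uM", "no2_uM",
                                         "salinity_psu")])
  rng <- apply(Ycal, 2L, function(y) diff(range(y)))
  rng[rng == 0] <- 1
  suppressWarnings(cv <- loo_cv(cal_w, h_max = h_max, mode = mode,
                                threshold = threshold))
  if (mode == "PLS1") {
    h <- vapply(cv, function(z) z$selected_h, integer(1L))
    n_factors <- max(h)
    fit <- fit_pls(cal_w, n_factors = n_factors, mode = "PLS1")
  } else {
    n_factors <- cv$selected_h
    fit <- fit_pls(cal_w, n_factors = n_factors, mode = "PLS2")
  }
  if (use_cv) {
    press_h <- if (mode == "PLS1") {
      vapply(seq_along(cv), function(j) cv[[j]]$press_per_response[h[j], 1L],
             numeric(1L))
    } else {
      cv$press_per_response[n_factors, ]
    }
    rmse_cv <- sqrt(press_h / n_spectra(cal_w))
    out <- list(lo = w[1L], hi = w[2L], rmsep = stats::setNames(rmse_cv,
                                                                colnames(Ycal)),
                r2 = rep(NA_real_, 3L), re = rep(NA_real_, 3L),
                pooled_score = mean(rmse_cv / rng), n_factors = n_factors)
    return(structure(out, class = "window_score"))
  }
  pred_w <- window_spectra(pred, w[1L], w[2L])
  Ypred <- as.matrix(pred_w$compositions[c("no3_uM", "no2_uM",
                                           "salinity_psu")])
  Yhat <- predict(fit, pred_w)
  rmsep_v <- vapply(seq_len(ncol(Ypred)),
                    function(j) rmsep(Ypred[, j], Yhat[, j]), numeric(1L))
  r2_v <- vapply(seq_len(ncol(Ypred)), function(j) {
    tryCatch(r_squared(Ypred[, j], Yhat[, j]), error = function(e) NA_real_)
  }, numeric(1L))
  re_v <- vapply(seq_len(ncol(Ypred)), function(j) {
    tryCatch(relative_error(Ypred[, j], Yhat[, j]), error = function(e)
      NA_real_)
  }, numeric(1L))
  names(rmsep_v) <- names(r2_v) <- names(re_v) <- colnames(Ypred)
  structure(list(lo = w[1L], hi = w[2L], rmsep = rmsep_v, r2 = r2_v,
                 re = re_v, pooled_score = mean(rmsep_v / rng),
                 n_factors = n_factors),
            class = "window_score")
}

#' @export
print.window_score <- function(x, ...) {
  cat("<window_score> [", x$lo, "-", x$hi, " nm] pooled_score = ",
      signif(x$pooled_score, 4), ", h = ", x$n_factors, "\n", sep = "")
  invisible(x)
}

#' Screen all iPLS intervals
#'
#' Scores every interval from [ipls_intervals()] and returns the per-window
#' metric table (the data behind an interval-screening plot).
#'
#' @inheritParams score_window
#' @param lo,hi,width_points,step Passed to [ipls_intervals()].
#' @return A data frame with one row per window: bounds, per-response
#'   RMSEP/R2/RE, pooled score and factor count, sorted as screened. The
#'   attribute `"best"` holds the `c(lo, hi)` of the lowest pooled score.
#' @export
ipls_screen <- function(cal, pred, lo = 200, hi = 300, width_points = 16L,
                        step = 10, mode = "PLS2",
                        threshold = q2_threshold(), h_max = 7L,
                        use_cv = FALSE) {
  wins <- ipls_intervals(lo, hi, width_points, step,
                         spacing = diff(cal$wavelength[1:2]))
  scores <- lapply(wins, function(w) {
    score_window(cal, pred, w, mode = mode, threshold = threshold,
                 h_max = h_max, use_cv = use_cv)
  })
  tab <- do.call(rbind, lapply(scores, function(s) {
    data.frame(lo = s$lo, hi = s$hi,
               rmsep_no3 = s$rmsep[[1L]], rmsep_no2 = s$rmsep[[2L]],
               rmsep_sal = s$rmsep[[3L]],
               r2_no3 = s$r2[[1L]], r2_no2 = s$r2[[2L]], r2_sal = s$r2[[3L]],
               re_no3 = s$re[[1L]], re_no2 = s$re[[2L]], re_sal = s$re[[3L]],
               pooled_score = s$pooled_score, n_factors = s$n_factors)
  }))
  best <- which.min(tab$pooled_score)
  attr(tab, "best") <- c(tab$lo[best], tab$hi[best])
  tab
}

#' Refine a window by greedy boundary moves
#'
#' One-sided boundary optimization of a screened window: alternately
#' proposes moving the low edge then the high edge by one step in either
#' direction, accepting a move only if the pooled score strictly
#' decreases, until neither edge can improve. Deterministic; the accepted
#' moves and their scores are recorded in the `"audit"` attribute. Windows
#' are never shrunk below `min_points` grid points.
#'
#' @inheritParams score_window
#' @param w0 Starting `c(lo, hi)` window (from screening).
#' @param step Edge step (nm).
#' @param min_points Minimum window size in grid points.
#' @param max_moves Safety cap on accepted moves.
#' @return The refined `c(lo, hi)` window with attributes `"audit"` (data
#'   frame of accepted states and scores) and `"score"` (final pooled
#'   score).
#' @export
refine_window <- function(cal, pred, w0, step = 1, min_points = 5L,
                          mode = "PLS2", threshold = q2_threshold(),
                          h_max = 7L, use_cv = FALSE, max_moves = 200L) {
  grid_lo <- cal$wavelength[1L]
  grid_hi <- cal$wavelength[length(cal$wavelength)]
  spacing <- diff(cal$wavelength[1:2])
  sc <- function(w) score_window(cal, pred, w, mode = mode,
                                 threshold = threshold, h_max = h_max,
                                 use_cv = use_cv)$pooled_score
  w <- as.numeric(w0)
  cur <- sc(w)
  audit <- data.frame(lo = w[1L], hi = w[2L], pooled_score = cur)
  valid <- function(w) {
    w[1L] >= grid_lo && w[2L] <= grid_hi &&
      (w[2L] - w[1L]) / spacing + 1 >= min_points
  }
  repeat {
    improved <- FALSE
    for (edge in 1:2) {
      best_w <- NULL; best_s <- cur
      for (d in c(-step, step)) {
        w_try <- w
        w_try[edge] <- w_try[edge] + d
        if (!valid(w_try)) next
        s_try <- sc(w_try)
        if (s_try < best_s) { best_s <- s_try; best_w <- w_try }
      }
      if (!is.null(best_w)) {
        w <- best_w; cur <- best_s; improved <- TRUE
        audit <- rbind(audit, data.frame(lo = w[1L], hi = w[2L],
                                         pooled_score = cur))
      }
    }
    if (!improved || nrow(audit) > max_moves) break
  }
  attr(w, "audit") <- audit
  attr(w, "score") <- cur
  w
}

#' Full wavelength selection: screening plus refinement
#'
#' Convenience wrapper: screens the iPLS intervals, takes the best one and
#' refines its boundaries.
#'
#' @inheritParams ipls_screen
#' @param refine Run boundary refinement on the best screened window.
#' @return A list with the screening table (`screen`), the screened best
#'   window (`screened`), and the refined window (`window`).
#' @export
select_wavelengths <- function(cal, pred, lo = 200, hi = 300,
                               width_points = 16L, step = 10,
                               mode = "PLS2", threshold = q2_threshold(),
                               h_max = 7L, use_cv = FALSE, refine = TRUE) {
  tab <- ipls_screen(cal, pred, lo, hi, width_points, step, mode,
                     threshold, h_max, use_cv)
  w0 <- attr(tab, "best")
  w <- if (refine) {
    refine_window(cal, pred, w0, mode = mode, threshold = threshold,
                  h_max = h_max, use_cv = use_cv)
  } else w0
  list(screen = tab, screened = w0, window = as.numeric(w),
       audit = attr(w, "audit"))
}
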