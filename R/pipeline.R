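#' Pipeline configuration
#'
#' Collects every tunable of the calibrate-and-predict workflow so a run is
#' fully reproducible from its logged config and seed.
#'
#' @param window Modeling window `c(lo, hi)` in nm.
#' @param mode `"PLS2"` (recommended: same accuracy as PLS1 here at lower
#'   cost) or `"PLS1"`.
#' @param q2_threshold Q2 significance cutoff for factor selection.
#' @param h_max Largest factor count evaluated in cross-validation.
#' @param cdom_apply Fit and subtract the CDOM background before PLS.
#' @param cdom_fit_range CDOM fit window `c(lo, hi)` in nm.
#' @param cdom_lambda0 CDOM reference wavelength (nm).
#' @param pathlength Expected cuvette pathlength (cm).
#' @param seed Optional integer seed logged with the run.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(window = c(215, 240), mode = c("PLS2", "PLS1"),
                       q2_threshold = 1 - 0.95^2, h_max = 7L,
                       cdom_apply = TRUE, cdom_fit_range = c(275, 295),
                       cdom_lambda0 = 300, pathlength = 3, seed = NULL) {
  mode <- match.arg(mode)
  structure(list(window = as.numeric(window), mode = mode,
                 q2_threshold = q2_threshold, h_max = as.integer(h_max),
                 cdom_apply = isTRUE(cdom_apply),
                 cdom_fit_range = as.numeric(cdom_fit_range),
                 cdom_lambda0 = cdom_lambda0,
                 pathlength = pathlength, seed = seed),
            class = "run_config")
}

#' Calibrate on one set and predict another
#'
#' The end-to-end workflow: optional per-spectrum CDOM correction of both
#' sets, restriction to the modeling window, leave-one-out cross-validated
#' factor selection, PLS fit, prediction of the unknowns, and — when
#' several unknown spectra share a `sample_id` (replicate scans) — a
#' replicate summary of mean and standard deviation per response. If the
#' unknowns carry compositions an evaluation report is added.
#'
#' @param cal Calibration [spectra_set()] with compositions.
#' @param unknowns [spectra_set()] to predict (compositions optional).
#' @param config A [run_config()].
#' @return A list of class `"uvnitro_run"`: `model`, `cv`, `predictions`
#'   (data frame), `replicates` (per-sample_id mean and sd), `metrics`
#'   (or `NULL`), `config`.
#' @export
run_pipeline <- function(cal, unknowns, config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  stage("validate", {
    if (!inherits(cal, "spectra_set") || is.null(cal$compositions)) {
      stop("calibration input must be a spectra_set with compositions")
    }
    if (!inherits(unknowns, "spectra_set")) {
      stop("unknowns must be a spectra_set")
    }
    if (abs(cal$pathlength - unknowns$pathlength) > 1e-9) {
      stop("calibration and unknown pathlengths differ (",
           cal$pathlength, " vs ", unknowns$pathlength,
           " cm); rescale_pathlength() first")
    }
  })
  if (config$cdom_apply) {
    cal <- stage("cdom", correct_cdom(cal, config$cdom_fit_range[1L],
                                      config$cdom_fit_range[2L],
                                      config$cdom_lambda0))
    unknowns <- stage("cdom", correct_cdom(unknowns,
                                           config$cdom_fit_range[1L],
                                           config$cdom_fit_range[2L],
                                           config$cdom_lambda0))
  }
  cal_w <- stage("window", window_spectra(cal, config$window[1L],
                                          config$window[2L]))
  unk_w <- stage("window", window_spectra(unknowns, config$window[1L],
                                          config$window[2L]))
  cv <- stage("cross-validation",
              suppressWarnings(loo_cv(cal_w, h_max = config$h_max,
                                      mode = config$mode,
                                      threshold = config$q2_threshold)))
  h <- if (config$mode == "PLS1") {
    max(vapply(cv, function(z) z$selected_h, integer(1L)))
  } else {
    cv$selected_h
  }
  model <- stage("fit", fit_pls(cal_w, n_factors = h, mode = config$mode))
  yhat <- stage("predict", predict(model, unk_w))
  predictions <- data.frame(sample_id = unk_w$sample_id,
                            no3_uM = yhat[, 1L], no2_uM = yhat[, 2L],
                            salinity_psu = yhat[, 3L], row.names = NULL)
  base_id <- sub("_rep[0-9]+$", "", predictions$sample_id)
  replicates <- do.call(rbind, lapply(split(seq_len(nrow(predictions)),
                                            base_id), function(rows) {
    data.frame(sample_id = base_id[rows[1L]], n = length(rows),
               no3_uM = mean(predictions$no3_uM[rows]),
               no3_sd = stats::sd(predictions$no3_uM[rows]),
               no2_uM = mean(predictions$no2_uM[rows]),
               no2_sd = stats::sd(predictions$no2_uM[rows]),
               salinity_psu = mean(predictions$salinity_psu[rows]),
               salinity_sd = stats::sd(predictions$salinity_psu[rows]))
  }))
  rownames(replicates) <- NULL
  metrics <- NULL
  if (!is.null(unk_w$compositions)) {
    actual <- as.matrix(unk_w$compositions[c("no3_uM", "no2_uM",
                                             "salinity_psu")])
    metrics <- metrics_report(actual, yhat,
                              c("no3_uM", "no2_uM", "salinity_psu"))
  }
  structure(list(model = model, cv = cv, predictions = predictions,
                 replicates = replicates, metrics = metrics,
                 config = config),
            class = "uvnitro_run")
}

#' @export
print.uvnitro_run <- function(x, ...) {
  h <- if (x$config$mode == "PLS1") {
    paste(vapply(x$cv, function(z) z$selected_h, integer(1L)),
          collapse = "/")
  } else {
    x$cv$selected_h
  }
  cat("<uvnitro_run> ", x$config$mode, " on [", x$config$window[1L], "-",
      x$config$window[2L], " nm], ", h, " factor(s), ",
      nrow(x$predictions), " prediction(s)\n", sep = "")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Serialize a PLS model to JSON
#'
#' Writes every matrix of the model (weights, loadings, scores,
#' coefficients), the centering vectors, factor count, wavelength window
#' and a schema version, as plain inspectable JSON.
#'
#' @param model A `pls_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pls_model <- function(model, path) {
  if (!inherits(model, "pls_model")) {
    stop("only single pls_model objects are serialized", call. = FALSE)
  }
  obj <- list(schema_version = 1L, mode = model$mode,
              x_mean = model$x_mean, y_mean = model$y_mean,
              weights = model$weights, x_loadings = model$x_loadings,
              y_loadings = model$y_loadings, x_scores = model$x_scores,
              y_scores = model$y_scores, coefficients = model$coefficients,
              n_factors = model$n_factors, x_ss0 = model$x_ss0,
              wavelength = model$wavelength, window = model$window,
              response_names = model$response_names)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' Read a PLS model from JSON
#'
#' @param path Path written by [write_pls_model()].
#' @return A `pls_model`.
#' @export
read_pls_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported model schema", call. = FALSE)
  }
  m <- obj[c("mode", "x_mean", "y_mean", "n_factors", "x_ss0",
             "wavelength", "window", "response_names")]
  as_mat <- function(z) if (is.matrix(z)) z else as.matrix(z)
  m$weights <- as_mat(obj$weights)
  m$x_loadings <- as_mat(obj$x_loadings)
  m$y_loadings <- as_mat(obj$y_loadings)
  m$x_scores <- as_mat(obj$x_scores)
  m$y_scores <- as_mat(obj$y_scores)
  m$coefficients <- as_mat(obj$coefficients)
  structure(m, class = "pls_model")
}
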