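#' Validate a wavelength grid
#'
#' A valid grid is a strictly increasing, uniformly spaced numeric vector of
#' wavelengths in nm, within the deep-UV range covered by the instrument
#' (190--400 nm). The default working resolution throughout the package is
#' 1 nm.
#'
#' @param values Numeric vector of wavelengths (nm).
#' @return The validated numeric vector, invisibly classed as
#'   `"wavelength_grid"`.
#' @export
wavelength_grid <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("wavelength grid needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("wavelength grid contains non-finite values", call. = FALSE)
  }
  if (is.unsorted(values, strictly = TRUE)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  sp <- diff(values)
  if ((max(sp) - min(sp)) > 1e-6 * mean(sp)) {
    stop("wavelength grid must be uniformly spaced", call. = FALSE)
  }
  if (values[1L] < 190 || values[length(values)] > 400) {
    stop("wavelength grid must lie within [190, 400] nm", call. = FALSE)
  }
  structure(values, class = "wavelength_grid")
}

#' Single absorbance spectrum
#'
#' One sample's absorbance spectrum on a validated wavelength grid, at a
#' stated cuvette pathlength. Absorbance is dimensionless (AU); the default
#' pathlength is the 3.0 cm cell used for low-absorbance seawater work.
#'
#' @param wavelength Numeric wavelength grid (nm).
#' @param absorbance Numeric vector of absorbance values, same length as
#'   `wavelength`.
#' @param pathlength Cuvette pathlength in cm (> 0).
#' @param sample_id Sample identifier.
#' @return An object of class `"absorbance_spectrum"`.
#' @export
absorbance_spectrum <- function(wavelength, absorbance, pathlength = 3,
                                sample_id = "sample") {
  wavelength <- unclass(wavelength_grid(wavelength))
  absorbance <- as.numeric(absorbance)
  if (length(absorbance) != length(wavelength)) {
    stop("absorbance length (", length(absorbance),
         ") does not match grid length (", length(wavelength), ")",
         call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance contains non-finite values for sample '", sample_id,
         "'", call. = FALSE)
  }
  if (!is.numeric(pathlength) || length(pathlength) != 1L || pathlength <= 0) {
    stop("pathlength must be a single positive number (cm)", call. = FALSE)
  }
  structure(
    list(wavelength = wavelength, absorbance = absorbance,
         pathlength = as.numeric(pathlength),
         sample_id = as.character(sample_id)),
    class = "absorbance_spectrum"
  )
}

#' Collection of spectra on a shared grid
#'
#' A set of absorbance spectra sharing one wavelength grid and one
#' pathlength, optionally paired with a composition table (nitrate uM,
#' nitrite uM, salinity psu) aligned by `sample_id`. Operations that would
#' mix pathlengths must rescale to a common pathlength first (see
#' [rescale_pathlength()]).
#'
#' @param wavelength Numeric wavelength grid (nm).
#' @param absorbance Numeric matrix, one row per sample, one column per
#'   wavelength.
#' @param sample_id Character vector of unique sample identifiers (defaults
#'   to the matrix rownames, then `"s1"`, `"s2"`, ...).
#' @param pathlength Common cuvette pathlength in cm.
#' @param compositions Optional data frame with columns `sample_id`,
#'   `no3_uM`, `no2_uM`, `salinity_psu`; reordered to match `sample_id`.
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(wavelength, absorbance, sample_id = NULL,
                        pathlength = 3, compositions = NULL) {
  wavelength <- unclass(wavelength_grid(wavelength))
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavelength)) {
    stop("absorbance matrix has ", ncol(absorbance),
         " columns but grid has ", length(wavelength), " wavelengths",
         call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- rownames(absorbance)
    if (is.null(sample_id)) sample_id <- paste0("s", seq_len(nrow(absorbance)))
  }
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(absorbance)) {
    stop("sample_id length does not match number of spectra", call. = FALSE)
  }
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    bad <- which(!is.finite(absorbance), arr.ind = TRUE)[1L, ]
    stop("non-finite absorbance for sample '", sample_id[bad[1L]],
         "' at ", wavelength[bad[2L]], " nm", call. = FALSE)
  }
  rownames(absorbance) <- sample_id
  colnames(absorbance) <- format(wavelength, trim = TRUE)
  if (!is.null(compositions)) {
    compositions <- validate_compositions(compositions)
    if (!setequal(compositions$sample_id, sample_id) ||
        nrow(compositions) != length(sample_id)) {
      stop("compositions must contain exactly one row per sample_id",
           call. = FALSE)
    }
    compositions <- compositions[match(sample_id, compositions$sample_id), ,
                                 drop = FALSE]
    rownames(compositions) <- NULL
  }
  structure(
    list(wavelength = wavelength, absorbance = absorbance,
         sample_id = sample_id, pathlength = as.numeric(pathlength),
         compositions = compositions),
    class = "spectra_set"
  )
}

validate_compositions <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "no3_uM", "no2_uM", "salinity_psu")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("composition table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  for (col in need[-1L]) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]))) {
      stop("non-finite value in composition column ", col, call. = FALSE)
    }
  }
  df[need]
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", nrow(x$absorbance), " spectra, ",
      length(x$wavelength), " wavelengths [",
      x$wavelength[1L], "-", x$wavelength[length(x$wavelength)],
      " nm], pathlength ", x$pathlength, " cm",
      if (!is.null(x$compositions)) ", compositions attached", "\n",
      sep = "")
  invisible(x)
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat("<absorbance_spectrum> '", x$sample_id, "', ",
      length(x$wavelength), " wavelengths [", x$wavelength[1L], "-",
      x$wavelength[length(x$wavelength)], " nm], pathlength ",
      x$pathlength, " cm\n", sep = "")
  invisible(x)
}

#' Number of spectra in a set
#' @param x A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(x) nrow(x$absorbance)

#' Extract one spectrum from a set
#' @param x A `spectra_set`.
#' @param i Index or sample_id.
#' @return An `absorbance_spectrum`.
#' @export
get_spectrum <- function(x, i) {
  if (is.character(i)) i <- match(i, x$sample_id)
  absorbance_spectrum(x$wavelength, x$absorbance[i, ], x$pathlength,
                      x$sample_id[i])
}

#' Read spectra from delimited text
#'
#' Two dialects are supported. *Wide*: first column `wavelength_nm`, one
#' column of absorbance per sample; an optional comment line
#' `# pathlength_cm=3.0` declares the pathlength. *Long*: columns
#' `sample_id, wavelength_nm, absorbance`. Files with a descending
#' wavelength column are re-sorted to ascending order (with a message);
#' non-numeric cells, missing values, ragged samples and duplicate sample
#' ids are parse errors naming the offending row.
#'
#' @param path Path to a CSV file.
#' @param dialect `"wide"` or `"long"`.
#' @param pathlength Pathlength (cm) to use when the file does not declare
#'   one.
#' @return A [spectra_set()].
#' @export
read_spectra <- function(path, dialect = c("wide", "long"), pathlength = 3) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  comments <- grep("^\\s*#", lines, value = TRUE)
  pl <- pathlength
  m <- regmatches(comments,
                  regexpr("pathlength_cm\\s*=\\s*[0-9.eE+-]+", comments))
  if (length(m)) pl <- as.numeric(sub(".*=\\s*", "", m[[1L]]))
  body <- lines[!grepl("^\\s*#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (names(df)[1L] != "wavelength_nm") {
      stop("wide spectra file must start with a 'wavelength_nm' column",
           call. = FALSE)
    }
    ids <- names(df)[-1L]
    if (anyDuplicated(ids)) {
      stop("duplicate sample_id column(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
    wl <- suppressWarnings(as.numeric(df[[1L]]))
    if (any(is.na(wl))) {
      stop("non-numeric wavelength in row ", which(is.na(wl))[1L],
           call. = FALSE)
    }
    A <- matrix(NA_real_, nrow = length(ids), ncol = length(wl),
                dimnames = list(ids, NULL))
    for (j in seq_along(ids)) {
      v <- suppressWarnings(as.numeric(df[[j + 1L]]))
      if (any(is.na(v))) {
        k <- which(is.na(v))[1L]
        stop("missing or non-numeric absorbance for sample '", ids[j],
             "' at ", wl[k], " nm", call. = FALSE)
      }
      A[j, ] <- v
    }
    if (is.unsorted(wl, strictly = TRUE)) {
      if (is.unsorted(rev(wl), strictly = TRUE)) {
        stop("wavelength column is neither ascending nor descending",
             call. = FALSE)
      }
      message("descending wavelength column in '", path,
              "': re-sorted to ascending order")
      ord <- order(wl)
      wl <- wl[ord]
      A <- A[, ord, drop = FALSE]
    }
    spectra_set(wl, A, ids, pathlength = pl)
  } else {
    need <- c("sample_id", "wavelength_nm", "absorbance")
    if (!all(need %in% names(df))) {
      stop("long spectra file must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    df$sample_id <- as.character(df$sample_id)
    wl_num <- suppressWarnings(as.numeric(df$wavelength_nm))
    ab_num <- suppressWarnings(as.numeric(df$absorbance))
    if (any(is.na(wl_num)) || any(is.na(ab_num))) {
      k <- which(is.na(wl_num) | is.na(ab_num))[1L]
      stop("missing or non-numeric value for sample '", df$sample_id[k],
           "' in data row ", k, call. = FALSE)
    }
    ids <- unique(df$sample_id)
    wl <- sort(unique(wl_num))
    A <- matrix(NA_real_, nrow = length(ids), ncol = length(wl),
                dimnames = list(ids, NULL))
    idx <- cbind(match(df$sample_id, ids), match(wl_num, wl))
    if (anyDuplicated(idx)) {
      k <- which(duplicated(idx))[1L]
      stop("duplicate (sample_id, wavelength) pair for sample '",
           df$sample_id[k], "' at ", wl_num[k], " nm", call. = FALSE)
    }
    A[idx] <- ab_num
    if (any(is.na(A))) {
      bad <- which(is.na(A), arr.ind = TRUE)[1L, ]
      stop("missing absorbance for sample '", ids[bad[1L]], "' at ",
           wl[bad[2L]], " nm (ragged long file)", call. = FALSE)
    }
    spectra_set(wl, A, ids, pathlength = pl)
  }
}

#' Write spectra to delimited text
#'
#' Inverse of [read_spectra()]; values are written with 17 significant
#' digits so a read/write/read round trip is bit-exact.
#'
#' @param x A `spectra_set`.
#' @param path Output path.
#' @param dialect `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) sprintf("%.17g", v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pathlength_cm=%.17g", x$pathlength), con)
  if (dialect == "wide") {
    writeLines(paste(c("wavelength_nm", x$sample_id), collapse = ","), con)
    for (j in seq_along(x$wavelength)) {
      writeLines(paste(c(fmt(x$wavelength[j]), fmt(x$absorbance[, j])),
                       collapse = ","), con)
    }
  } else {
    writeLines("sample_id,wavelength_nm,absorbance", con)
    for (i in seq_along(x$sample_id)) {
      writeLines(paste(x$sample_id[i], fmt(x$wavelength),
                       fmt(x$absorbance[i, ]), sep = ","), con)
    }
  }
  invisible(path)
}

#' Read a composition table
#'
#' @param path CSV with columns `sample_id, no3_uM, no2_uM, salinity_psu`.
#' @return A data frame.
#' @export
read_compositions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_compositions(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a composition table
#' @param df Composition data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compositions <- function(df, path) {
  utils::write.csv(validate_compositions(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation onto `grid`; no extrapolation is performed, so the
#' new grid must lie within the wavelength span of the spectrum.
#'
#' @param s An `absorbance_spectrum` or `spectra_set`.
#' @param grid Target wavelength grid (nm).
#' @return Object of the same class as `s` on the new grid.
#' @export
resample <- function(s, grid) UseMethod("resample")

#' @export
resample.absorbance_spectrum <- function(s, grid) {
  grid <- unclass(wavelength_grid(grid))
  rng <- range(s$wavelength)
  if (grid[1L] < rng[1L] || grid[length(grid)] > rng[2L]) {
    stop("target grid [", grid[1L], ", ", grid[length(grid)],
         "] extends beyond the spectrum span [", rng[1L], ", ", rng[2L],
         "] nm", call. = FALSE)
  }
  a <- stats::approx(s$wavelength, s$absorbance, xout = grid,
                     method = "linear", rule = 1)$y
  absorbance_spectrum(grid, a, s$pathlength, s$sample_id)
}

#' @export
resample.spectra_set <- function(s, grid) {
  grid <- unclass(wavelength_grid(grid))
  rng <- range(s$wavelength)
  if (grid[1L] < rng[1L] || grid[length(grid)] > rng[2L]) {
    stop("target grid extends beyond the spectrum span [", rng[1L], ", ",
         rng[2L], "] nm", call. = FALSE)
  }
  A <- t(apply(s$absorbance, 1L, function(a) {
    stats::approx(s$wavelength, a, xout = grid, method = "linear",
                  rule = 1)$y
  }))
  spectra_set(grid, A, s$sample_id, s$pathlength, s$compositions)
}

#' Restrict spectra to a wavelength window
#'
#' Returns the spectra restricted to `[lo, hi]` inclusive. Both bounds must
#' fall exactly on the grid; off-grid bounds are an error rather than being
#' silently snapped.
#'
#' @param x An `absorbance_spectrum` or `spectra_set`.
#' @param lo,hi Window bounds in nm, `lo < hi`, both on the grid.
#' @return Object of the same class restricted to the window.
#' @export
window_spectra <- function(x, lo, hi) UseMethod("window_spectra")

window_index <- function(wavelength, lo, hi) {
  if (!(lo < hi)) stop("window requires lo < hi (got ", lo, ", ", hi, ")",
                       call. = FALSE)
  tol <- 1e-8
  i_lo <- which(abs(wavelength - lo) < tol)
  i_hi <- which(abs(wavelength - hi) < tol)
  if (!length(i_lo) || !length(i_hi)) {
    stop("window bound ", if (!length(i_lo)) lo else hi,
         " nm is not on the wavelength grid", call. = FALSE)
  }
  seq.int(i_lo, i_hi)
}

#' @export
window_spectra.absorbance_spectrum <- function(x, lo, hi) {
  idx <- window_index(x$wavelength, lo, hi)
  absorbance_spectrum(x$wavelength[idx], x$absorbance[idx], x$pathlength,
                      x$sample_id)
}

#' @export
window_spectra.spectra_set <- function(x, lo, hi) {
  idx <- window_index(x$wavelength, lo, hi)
  spectra_set(x$wavelength[idx], x$absorbance[, idx, drop = FALSE],
              x$sample_id, x$pathlength, x$compositions)
}

#' Rescale a spectrum to a different pathlength
#'
#' Multiplies absorbance by `to / from`. Valid for Beer--Lambert absorbance;
#' note that additive backgrounds that do not scale with the cell (e.g. an
#' instrument offset) are rescaled too, so apply background correction
#' first when that matters.
#'
#' @param x An `absorbance_spectrum` or `spectra_set`.
#' @param to Target pathlength (cm).
#' @return Rescaled object with `pathlength = to`.
#' @export
rescale_pathlength <- function(x, to) {
  if (!is.numeric(to) || length(to) != 1L || to <= 0) {
    stop("target pathlength must be a single positive number", call. = FALSE)
  }
  f <- to / x$pathlength
  x$absorbance <- x$absorbance * f
  x$pathlength <- to
  x
}
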