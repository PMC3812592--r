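#' Wavelength ranges retained after removing the noisy detector bands
#'
#' The ASD FieldSpec-type instrument emulated here is noisy around the
#' 1,400 nm and 1,900 nm atmospheric water vapour bands and at the far end of
#' the SWIR2 detector.  The retained ranges (inclusive at both ends, in nm)
#' are \code{[350, 1359]}, \code{[1386, 1799]} and \code{[1931, 2399]}.
#'
#' @return A list of length-2 numeric vectors \code{c(lower, upper)}.
#' @export
retained_ranges <- function() {
  list(c(350, 1359), c(1386, 1799), c(1931, 2399))
}

#' Wavelength ranges defining the three spectral subsets
#'
#' \describe{
#'   \item{VNIR}{350--1,000 nm}
#'   \item{VNIR_SWIR1}{350--1,359 and 1,386--1,799 nm}
#'   \item{VNIR_SWIR1_SWIR2}{adds 1,931--2,399 nm}
#' }
#'
#' @param name Subset name.
#' @return A list of length-2 numeric vectors \code{c(lower, upper)}.
#' @export
subset_ranges <- function(name = c("VNIR", "VNIR_SWIR1", "VNIR_SWIR1_SWIR2")) {
  name <- match.arg(name)
  switch(name,
    VNIR             = list(c(350, 1000)),
    VNIR_SWIR1       = list(c(350, 1359), c(1386, 1799)),
    VNIR_SWIR1_SWIR2 = retained_ranges()
  )
}

#' Construct a single spectrum
#'
#' A spectrum is a wavelength-indexed vector of reflectance (or transformed)
#' values.  Reflectance values must lie in \code{[0, 1.2]}; values slightly
#' above 1 are tolerated because reference-panel calibration can push bright
#' targets past unity.
#'
#' @param wavelength Strictly increasing numeric vector of wavelengths (nm).
#' @param value Numeric vector, same length as \code{wavelength}.
#' @param kind \code{"reflectance"} or \code{"transformed"}.
#' @return An object of class \code{"spectrum"}.
#' @export
spectrum <- function(wavelength, value, kind = c("reflectance", "transformed")) {
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  value <- as.numeric(value)
  if (length(wavelength) == 0L)
    stop("spectrum needs at least one band")
  if (length(wavelength) != length(value))
    stop("wavelength and value lengths differ")
  if (anyNA(wavelength) || anyNA(value))
    stop("NA values are not allowed in a spectrum")
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  if (kind == "reflectance" && (any(value < 0) || any(value > 1.2)))
    stop("reflectance values must lie in [0, 1.2]")
  structure(list(wavelength = wavelength, value = value, kind = kind),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d bands, %.0f-%.0f nm, kind=%s>\n",
              length(x$wavelength), min(x$wavelength), max(x$wavelength),
              x$kind))
  invisible(x)
}

#' Construct a set of repeated readings for one plot
#'
#' @param plot_id Plot identifier (scalar).
#' @param readings List of \code{\link{spectrum}} objects on an identical
#'   wavelength grid.
#' @return An object of class \code{"reading_set"}.
#' @export
reading_set <- function(plot_id, readings) {
  if (length(readings) < 1L) stop("a reading set needs at least one reading")
  if (!all(vapply(readings, inherits, logical(1), "spectrum")))
    stop("all readings must be 'spectrum' objects")
  grid <- readings[[1L]]$wavelength
  for (r in readings) {
    if (!identical(r$wavelength, grid))
      stop("all readings of plot '", plot_id,
           "' must share an identical wavelength grid")
  }
  structure(list(plot_id = as.character(plot_id), readings = readings),
            class = "reading_set")
}

#' Construct a samples-by-bands spectral dataset
#'
#' @param wavelength Shared wavelength grid (strictly increasing, nm).
#' @param values Numeric matrix, one row per sample, one column per band.
#' @param sample_ids Unique sample identifiers (one per row).
#' @param averaging How per-plot readings were averaged (\code{"mean"} or
#'   \code{"median"}); \code{"none"} for raw or simulated matrices.
#' @param kind \code{"reflectance"} or \code{"transformed"}.
#' @return An object of class \code{"spectral_dataset"}.
#' @export
spectral_dataset <- function(wavelength, values, sample_ids,
                             averaging = c("none", "mean", "median"),
                             kind = c("reflectance", "transformed")) {
  averaging <- match.arg(averaging)
  kind <- match.arg(kind)
  wavelength <- as.numeric(wavelength)
  values <- as.matrix(values)
  if (ncol(values) != length(wavelength))
    stop("column count must equal grid length")
  if (nrow(values) != length(sample_ids))
    stop("row count must equal number of sample ids")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(diff(wavelength) <= 0))
    stop("wavelengths must be strictly increasing")
  dimnames(values) <- list(as.character(sample_ids), NULL)
  structure(list(wavelength = wavelength, values = values,
                 sample_ids = as.character(sample_ids),
                 averaging = averaging, kind = kind),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf(
    "<spectral_dataset: %d samples x %d bands, %.0f-%.0f nm, averaging=%s>\n",
    nrow(x$values), ncol(x$values), min(x$wavelength), max(x$wavelength),
    x$averaging))
  invisible(x)
}

#' Extract one sample of a dataset as a spectrum
#'
#' @param ds A \code{\link{spectral_dataset}}.
#' @param i Row index or sample id.
#' @return A \code{\link{spectrum}}.
#' @export
dataset_spectrum <- function(ds, i) {
  spectrum(ds$wavelength, ds$values[i, ], kind = ds$kind)
}

#' Average the repeated readings of a plot
#'
#' Each plot's repeated canopy readings are collapsed into a single spectrum,
#' per band, using either the mean or the median.
#'
#' @param rs A \code{\link{reading_set}}.
#' @param method \code{"mean"} or \code{"median"}.
#' @return A \code{\link{spectrum}} of the same kind as the readings.
#' @export
average_readings <- function(rs, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(rs, "reading_set"))
  m <- do.call(rbind, lapply(rs$readings, function(s) s$value))
  v <- if (method == "mean") colMeans(m) else apply(m, 2L, stats::median)
  spectrum(rs$readings[[1L]]$wavelength, v, kind = rs$readings[[1L]]$kind)
}

#' Collapse a list of reading sets into a per-plot dataset
#'
#' @param reading_sets List of \code{\link{reading_set}} objects on a shared
#'   grid.
#' @param method Averaging statistic, \code{"mean"} or \code{"median"}.
#' @return A \code{\link{spectral_dataset}} with one row per plot.
#' @export
average_plots <- function(reading_sets, method = c("mean", "median")) {
  method <- match.arg(method)
  specs <- lapply(reading_sets, average_readings, method = method)
  ids <- vapply(reading_sets, function(r) r$plot_id, character(1))
  spectral_dataset(specs[[1L]]$wavelength,
                   do.call(rbind, lapply(specs, function(s) s$value)),
                   ids, averaging = method, kind = specs[[1L]]$kind)
}

keep_in_ranges <- function(wavelength, ranges) {
  keep <- rep(FALSE, length(wavelength))
  for (r in ranges) keep <- keep | (wavelength >= r[1] & wavelength <= r[2])
  keep
}

#' Remove the noisy detector bands
#'
#' Drops the bands outside \code{\link{retained_ranges}} (water-vapour windows
#' around 1,360--1,385 nm and 1,800--1,930 nm, and beyond 2,399 nm).
#' Idempotent; membership is decided by wavelength value, not index, so any
#' monotone grid is supported.
#'
#' @param ds A \code{\link{spectral_dataset}} within 350--2,500 nm.
#' @return The dataset restricted to the retained wavelengths.
#' @export
exclude_noisy_bands <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (min(ds$wavelength) < 350 || max(ds$wavelength) > 2500)
    stop("grid must lie within 350-2,500 nm")
  keep <- keep_in_ranges(ds$wavelength, retained_ranges())
  if (!any(keep)) warning("no bands remain after noisy-band exclusion")
  spectral_dataset(ds$wavelength[keep], ds$values[, keep, drop = FALSE],
                   ds$sample_ids, averaging = ds$averaging, kind = ds$kind)
}

#' Restrict a dataset to a named spectral subset
#'
#' @param ds A \code{\link{spectral_dataset}}; noisy bands should already be
#'   excluded.
#' @param name One of \code{"VNIR"}, \code{"VNIR_SWIR1"},
#'   \code{"VNIR_SWIR1_SWIR2"}.
#' @return The restricted \code{\link{spectral_dataset}}.
#' @export
spectral_subset <- function(ds, name) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!name %in% c("VNIR", "VNIR_SWIR1", "VNIR_SWIR1_SWIR2"))
    stop("unknown spectral subset: ", name)
  keep <- keep_in_ranges(ds$wavelength, subset_ranges(name))
  spectral_dataset(ds$wavelength[keep], ds$values[, keep, drop = FALSE],
                   ds$sample_ids, averaging = ds$averaging, kind = ds$kind)
}

#' Validate a table of biomass records
#'
#' Checks the structural invariants of the response table: total dry
#' aboveground biomass (TAGB, g/m^2), its green fraction (GAGB, g/m^2) and
#' the percent green fraction (pctGAGB, %).  \code{pctGAGB} must agree with
#' \code{100 * GAGB / TAGB} within 0.5 percentage points.
#'
#' @param df Data frame with columns \code{plot_id}, \code{TAGB},
#'   \code{GAGB}, \code{pctGAGB}.
#' @return The validated data frame (invisibly usable in pipes).
#' @export
validate_biomass <- function(df) {
  need <- c("plot_id", "TAGB", "GAGB", "pctGAGB")
  if (!all(need %in% names(df)))
    stop("biomass table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$plot_id))
    stop("duplicate plot_id in biomass table")
  if (any(df$TAGB < 0) || any(df$GAGB < 0))
    stop("biomass values must be non-negative")
  if (any(df$GAGB > df$TAGB + 1e-9))
    stop("GAGB cannot exceed TAGB")
  if (any(df$pctGAGB < 0 | df$pctGAGB > 100))
    stop("pctGAGB must lie in [0, 100]")
  ok <- df$TAGB > 0
  if (any(abs(df$pctGAGB[ok] - 100 * df$GAGB[ok] / df$TAGB[ok]) > 0.5))
    stop("pctGAGB inconsistent with 100*GAGB/TAGB (tolerance 0.5)")
  df
}
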