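#' Codes of the pre-processing transformations
#'
#' The 18 single-shot transformations applied to spectra before modelling
#' (continuum removal is handled separately by the \code{continuum} tools):
#' baseline offset (BLO), de-trending of order 1--3 (DE-TREN1..3), the three
#' multiplicative scatter corrections (MSCA, MSCF, MSCO), five normalisations
#' (NAR, NMX, NME, NRA, NUV), Norris gap first derivatives with gaps 3, 5, 7,
#' 9 (NGD-3..NGD-9), reflectance to absorbance (RAB) and the standard normal
#' variate (SNV).
#'
#' @return Character vector of the 18 codes.
#' @export
transform_codes <- function() {
  c("BLO", "DE-TREN1", "DE-TREN2", "DE-TREN3",
    "MSCA", "MSCF", "MSCO",
    "NAR", "NMX", "NME", "NRA", "NUV",
    "NGD-3", "NGD-5", "NGD-7", "NGD-9",
    "RAB", "SNV")
}

as_transformed <- function(x, value, wavelength = x$wavelength) {
  spectrum(wavelength, value, kind = "transformed")
}

#' Baseline offset correction
#'
#' Subtracts the per-spectrum minimum so the corrected spectrum touches zero.
#'
#' @param x A \code{\link{spectrum}}.
#' @return A transformed \code{\link{spectrum}}.
#' @export
baseline_offset <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  as_transformed(x, x$value - min(x$value))
}

#' De-trending by polynomial subtraction
#'
#' Fits a least-squares polynomial of degree \code{k} in wavelength to the
#' whole spectrum (baseline and signal alike) and returns the residuals.
#' Internally the grid is centred and scaled to \code{[-1, 1]} for
#' conditioning; the residuals are unchanged by that reparameterisation.
#'
#' @param x A \code{\link{spectrum}} with more than \code{k + 1} bands.
#' @param k Polynomial order, 1, 2 or 3.
#' @return A transformed \code{\link{spectrum}} of residuals.
#' @export
detrend <- function(x, k) {
  stopifnot(inherits(x, "spectrum"))
  if (!k %in% 1:3) stop("polynomial order k must be 1, 2 or 3")
  n <- length(x$wavelength)
  if (n <= k + 1) stop("too few bands to de-trend with order ", k)
  u <- 2 * (x$wavelength - min(x$wavelength)) /
    (max(x$wavelength) - min(x$wavelength)) - 1
  basis <- cbind(1, stats::poly(u, degree = k, raw = FALSE, simple = TRUE))
  fit <- stats::lm.fit(basis, x$value)
  as_transformed(x, unname(fit$residuals))
}

#' Multiplicative scatter correction
#'
#' Each spectrum is regressed by ordinary least squares on the dataset mean
#' spectrum \eqn{r}: \eqn{x = a + b r + e}.  The named correction is then
#' applied: \code{offset} gives \eqn{x - a}, \code{amplification} gives
#' \eqn{x / b} and \code{full} gives \eqn{(x - a)/b}.  The reference is the
#' mean spectrum of the dataset passed in, so it must be recomputed whenever
#' observations change (and inside every cross-validation fold).
#'
#' @param ds A \code{\link{spectral_dataset}} with at least 2 samples.
#' @param mode \code{"offset"}, \code{"amplification"} or \code{"full"}.
#' @param reference Optional reference spectrum values (defaults to the
#'   column means of \code{ds}); pass the training-set reference to correct
#'   held-out samples without leakage.
#' @return A transformed \code{\link{spectral_dataset}}.
#' @export
msc <- function(ds, mode = c("offset", "amplification", "full"),
                reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "spectral_dataset"))
  if (is.null(reference)) {
    if (nrow(ds$values) < 2L)
      stop("MSC needs at least 2 samples to form a reference")
    reference <- colMeans(ds$values)
  }
  if (length(reference) != ncol(ds$values))
    stop("reference length must match band count")
  out <- msc_correct_matrix(ds$values, reference, mode)
  spectral_dataset(ds$wavelength, out, ds$sample_ids,
                   averaging = ds$averaging, kind = "transformed")
}

# row-wise MSC against a fixed reference; shared by msc() and the
# fold-internal pre-processing used during cross-validation
msc_correct_matrix <- function(values, reference, mode) {
  out <- values
  rc <- reference - mean(reference)
  denom <- sum(rc * rc)
  if (denom < 1e-24) stop("degenerate (constant) MSC reference")
  for (i in seq_len(nrow(out))) {
    xi <- values[i, ]
    b <- sum(rc * (xi - mean(xi))) / denom
    a <- mean(xi) - b * mean(reference)
    if (abs(b) < 1e-12) stop("degenerate MSC slope for sample ", i)
    out[i, ] <- switch(mode,
      offset        = xi - a,
      amplification = xi / b,
      full          = (xi - a) / b)
  }
  out
}

#' Spectrum normalisations
#'
#' Divides the spectrum by one per-spectrum scalar: its trapezoidal area over
#' wavelength (\code{area}), maximum (\code{max}), mean (\code{mean}), range
#' \code{max - min} (\code{range}) or Euclidean norm (\code{unit_vector}).
#'
#' @param x A \code{\link{spectrum}}.
#' @param mode One of \code{"area"}, \code{"max"}, \code{"mean"},
#'   \code{"range"}, \code{"unit_vector"}.
#' @return A transformed \code{\link{spectrum}}.
#' @export
normalize_spectrum <- function(x, mode = c("area", "max", "mean", "range",
                                           "unit_vector")) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "spectrum"))
  v <- x$value
  denom <- switch(mode,
    area        = trapz(x$wavelength, v),
    max         = max(v),
    mean        = mean(v),
    range       = max(v) - min(v),
    unit_vector = sqrt(sum(v * v)))
  if (abs(denom) < 1e-15)
    stop("zero denominator in '", mode, "' normalisation")
  as_transformed(x, v / denom)
}

trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Norris gap first derivative
#'
#' Symmetric gap difference
#' \deqn{D(\lambda_i) = \frac{x(\lambda_{i+g}) - x(\lambda_{i-g})}
#'                           {\lambda_{i+g} - \lambda_{i-g}},}
#' exact for quadratics; \code{g} bands are dropped at each edge of the grid.
#'
#' @param x A \code{\link{spectrum}} with more than \code{2 g} bands.
#' @param g Gap size, one of 3, 5, 7, 9.
#' @return A transformed \code{\link{spectrum}} on the trimmed grid.
#' @export
norris_gap_derivative <- function(x, g) {
  stopifnot(inherits(x, "spectrum"))
  if (!g %in% c(3, 5, 7, 9)) stop("gap size g must be 3, 5, 7 or 9")
  n <- length(x$wavelength)
  if (n <= 2 * g) stop("grid too short for gap size ", g)
  i <- (g + 1L):(n - g)
  d <- (x$value[i + g] - x$value[i - g]) /
       (x$wavelength[i + g] - x$wavelength[i - g])
  as_transformed(x, d, wavelength = x$wavelength[i])
}

#' Reflectance to absorbance
#'
#' \eqn{A(\lambda) = \log_{10}(1 / R(\lambda))}; requires strictly positive
#' reflectance.
#'
#' @param x A \code{\link{spectrum}} with all values > 0.
#' @return A transformed \code{\link{spectrum}}.
#' @export
reflectance_to_absorbance <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  if (any(x$value <= 0))
    stop("reflectance must be strictly positive for absorbance")
  as_transformed(x, log10(1 / x$value))
}

#' Standard normal variate
#'
#' Centres each spectrum to zero mean and scales it to unit standard
#' deviation (n - 1 denominator).
#'
#' @param x A \code{\link{spectrum}} with at least 2 bands and non-constant
#'   values.
#' @return A transformed \code{\link{spectrum}}.
#' @export
snv <- function(x) {
  stopifnot(inherits(x, "spectrum"))
  if (length(x$value) < 2L) stop("SNV needs at least 2 bands")
  s <- stats::sd(x$value)
  if (s < 1e-15) stop("SNV undefined for a constant spectrum")
  as_transformed(x, (x$value - mean(x$value)) / s)
}

msc_mode_of <- function(code) {
  switch(code, MSCA = "amplification", MSCF = "full", MSCO = "offset",
         stop("not an MSC code: ", code))
}

is_msc_code <- function(code) code %in% c("MSCA", "MSCF", "MSCO")

apply_spectrum_transform <- function(x, code) {
  switch(code,
    "BLO"      = baseline_offset(x),
    "DE-TREN1" = detrend(x, 1L),
    "DE-TREN2" = detrend(x, 2L),
    "DE-TREN3" = detrend(x, 3L),
    "NAR"      = normalize_spectrum(x, "area"),
    "NMX"      = normalize_spectrum(x, "max"),
    "NME"      = normalize_spectrum(x, "mean"),
    "NRA"      = normalize_spectrum(x, "range"),
    "NUV"      = normalize_spectrum(x, "unit_vector"),
    "NGD-3"    = norris_gap_derivative(x, 3L),
    "NGD-5"    = norris_gap_derivative(x, 5L),
    "NGD-7"    = norris_gap_derivative(x, 7L),
    "NGD-9"    = norris_gap_derivative(x, 9L),
    "RAB"      = reflectance_to_absorbance(x),
    "SNV"      = snv(x),
    stop("unknown transformation code: ", code))
}

#' Apply a coded transformation to a whole dataset
#'
#' Per-spectrum transforms are applied row by row; the MSC family uses the
#' dataset mean spectrum as reference (recomputed from \code{ds} itself).
#' The Norris derivatives shorten the wavelength grid.
#'
#' @param ds A \code{\link{spectral_dataset}}.
#' @param code One of \code{\link{transform_codes}()}.
#' @return A transformed \code{\link{spectral_dataset}}.
#' @export
apply_transform <- function(ds, code) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!code %in% transform_codes())
    stop("unknown transformation code: ", code)
  if (is_msc_code(code)) return(msc(ds, msc_mode_of(code)))
  specs <- lapply(seq_len(nrow(ds$values)), function(i)
    apply_spectrum_transform(dataset_spectrum(ds, i), code))
  spectral_dataset(specs[[1L]]$wavelength,
                   do.call(rbind, lapply(specs, function(s) s$value)),
                   ds$sample_ids, averaging = ds$averaging,
                   kind = "transformed")
}
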