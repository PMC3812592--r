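detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read canopy spectra as per-plot reading sets
#'
#' The file format is delimited text (comma or tab, auto-detected): first
#' column \code{wavelength_nm}, then one column per reading named
#' \code{<plot_id>__r<k>}.
#'
#' @param path File path.
#' @return A named list of \code{\link{reading_set}} objects.
#' @export
read_spectra <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "wavelength_nm")
    stop("malformed header: first column must be 'wavelength_nm'")
  wl <- df[[1L]]
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  cols <- names(df)[-1L]
  if (!all(grepl("^.+__r[0-9]+$", cols)))
    stop("reading columns must be named <plot_id>__r<k>")
  plot_of <- sub("__r[0-9]+$", "", cols)
  out <- list()
  for (pid in unique(plot_of)) {
    specs <- lapply(which(plot_of == pid) + 1L, function(j)
      spectrum(wl, df[[j]], kind = "reflectance"))
    out[[pid]] <- reading_set(pid, specs)
  }
  out
}

#' Write reading sets to a delimited spectra file
#'
#' @param reading_sets Named list of \code{\link{reading_set}} objects on a
#'   shared grid.
#' @param path Output path.
#' @param sep Field separator, comma by default.
#' @return \code{path}, invisibly.
#' @export
write_spectra <- function(reading_sets, path, sep = ",") {
  wl <- reading_sets[[1L]]$readings[[1L]]$wavelength
  cols <- list(wavelength_nm = wl)
  for (rs in reading_sets) {
    for (k in seq_along(rs$readings)) {
      if (!identical(rs$readings[[k]]$wavelength, wl))
        stop("all reading sets must share one wavelength grid")
      cols[[sprintf("%s__r%d", rs$plot_id, k)]] <- rs$readings[[k]]$value
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a biomass table
#'
#' Expects columns \code{plot_id, TAGB, GAGB, pctGAGB} (comma or tab
#' separated) and validates the record invariants.
#'
#' @param path File path.
#' @return A validated data frame.
#' @export
read_biomass <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  df$plot_id <- as.character(df$plot_id)
  validate_biomass(df)
}

#' Write a biomass table
#'
#' @param df Biomass data frame (validated on the way out).
#' @param path Output path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
write_biomass <- function(df, path, sep = ",") {
  validate_biomass(df)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a spectral dataset (samples in columns)
#'
#' Layout mirrors the spectra file: first column \code{wavelength_nm}, one
#' column per sample.  Full double precision is kept so that a write/read
#' round trip is lossless to 1e-12.
#'
#' @param ds A \code{\link{spectral_dataset}}.
#' @param path Output path.
#' @param sep Field separator.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path, sep = ",") {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(wavelength_nm = ds$wavelength, check.names = FALSE)
  for (i in seq_along(ds$sample_ids))
    df[[ds$sample_ids[i]]] <- ds$values[i, ]
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectral dataset written by [write_dataset()]
#'
#' @param path File path.
#' @param averaging Averaging flag to record on the dataset.
#' @param kind Value kind flag.
#' @return A \code{\link{spectral_dataset}}.
#' @export
read_dataset <- function(path, averaging = "none", kind = "reflectance") {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "wavelength_nm")
    stop("malformed header: first column must be 'wavelength_nm'")
  ids <- names(df)[-1L]
  spectral_dataset(df[[1L]], t(as.matrix(df[, -1L, drop = FALSE])), ids,
                   averaging = averaging, kind = kind)
}
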