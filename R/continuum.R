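#' Default absorption zones for continuum removal
#'
#' Five wavelength windows, each containing one absorption feature of a
#' grass/clover canopy: two pigment features in the visible (Z1, Z2) and
#' three water features in the NIR/SWIR1 (Z3--Z5).  Bounds in nm, inclusive.
#'
#' @return Data frame with columns \code{zone}, \code{lambda_start},
#'   \code{lambda_end}.
#' @export
absorption_zones <- function() {
  data.frame(
    zone = c("Z1", "Z2", "Z3", "Z4", "Z5"),
    lambda_start = c(440, 554, 916, 1079, 1265),
    lambda_end   = c(567, 762, 1120, 1297, 1676),
    stringsAsFactors = FALSE
  )
}

zone_bounds <- function(zone) {
  z <- absorption_zones()
  i <- match(zone, z$zone)
  if (is.na(i)) stop("unknown absorption zone: ", zone)
  c(z$lambda_start[i], z$lambda_end[i])
}

zone_index <- function(x, bounds) {
  idx <- which(x$wavelength >= bounds[1] & x$wavelength <= bounds[2])
  if (length(idx) < 3L)
    stop("zone [", bounds[1], ", ", bounds[2],
         "] covers fewer than 3 grid wavelengths")
  idx
}

#' Continuum line over an absorption zone
#'
#' The continuum is the straight chord joining the spectrum's reflectance at
#' the two zone endpoints (the grid wavelengths nearest inside the printed
#' bounds), evaluated at every grid wavelength in the zone.
#'
#' @param x A reflectance \code{\link{spectrum}} covering the zone.
#' @param zone Zone name (\code{"Z1"}..\code{"Z5"}) or numeric
#'   \code{c(start, end)} in nm.
#' @return Numeric vector of continuum values on the in-zone grid.
#' @export
continuum_line <- function(x, zone) {
  stopifnot(inherits(x, "spectrum"))
  bounds <- if (is.character(zone)) zone_bounds(zone) else as.numeric(zone)
  idx <- zone_index(x, bounds)
  wl <- x$wavelength[idx]
  v <- x$value[idx]
  n <- length(wl)
  if (v[1] <= 0 || v[n] <= 0)
    stop("endpoint reflectance must be positive for continuum removal")
  v[1] + (v[n] - v[1]) * (wl - wl[1]) / (wl[n] - wl[1])
}

#' Continuum-removed reflectance over a zone
#'
#' Divides the reflectance by the chord continuum; the continuum-removed
#' reflectance (CRR) equals 1 exactly at the zone endpoints and dips below 1
#' inside an absorption feature.
#'
#' @inheritParams continuum_line
#' @return An object of class \code{"continuum_removed"} with fields
#'   \code{zone}, \code{wavelength}, \code{reflectance}, \code{continuum},
#'   \code{crr}.
#' @export
continuum_removed <- function(x, zone) {
  stopifnot(inherits(x, "spectrum"))
  bounds <- if (is.character(zone)) zone_bounds(zone) else as.numeric(zone)
  idx <- zone_index(x, bounds)
  cont <- continuum_line(x, bounds)
  structure(list(
    zone = if (is.character(zone)) zone else sprintf("[%g,%g]", bounds[1], bounds[2]),
    bounds = bounds,
    wavelength = x$wavelength[idx],
    reflectance = x$value[idx],
    continuum = cont,
    crr = x$value[idx] / cont
  ), class = "continuum_removed")
}

#' @export
print.continuum_removed <- function(x, ...) {
  cat(sprintf("<continuum_removed %s: %d bands, min CRR %.4f>\n",
              x$zone, length(x$crr), min(x$crr)))
  invisible(x)
}

#' Maximum band depth
#'
#' The band depth at a wavelength is \eqn{1 - CRR(\lambda)}; the maximum band
#' depth (MBD) is its maximum over the zone, clamped at 0.  A feature-less
#' zone (CRR never below 1) is flagged degenerate.  Because MBD is computed
#' on the continuum-removed scale it is invariant under positive scaling of
#' the spectrum.
#'
#' @param cr A \code{\link{continuum_removed}} object.
#' @return Numeric MBD with attribute \code{degenerate} (logical).
#' @export
max_band_depth <- function(cr) {
  stopifnot(inherits(cr, "continuum_removed"))
  m <- min(cr$crr)
  mbd <- max(0, 1 - m)
  attr(mbd, "degenerate") <- m >= 1
  mbd
}

# Solve crr(lambda) = level between in-zone grid points, walking outward from
# the argmin.  Between two grid wavelengths both the reflectance and the
# chord are linear, so the crossing solves the *linear* equation
# R(lambda) - level * C(lambda) = 0 exactly (the CRR itself is a ratio of
# linear functions, monotone on each interval).
crossing_from <- function(cr, i_min, level, direction) {
  wl <- cr$wavelength; R <- cr$reflectance; C <- cr$continuum
  g <- R - level * C                      # <=0 where depth >= half depth
  n <- length(wl)
  i <- i_min
  repeat {
    j <- i + direction
    if (j < 1L || j > n) return(wl[i])    # truncated at the zone edge
    if (g[j] >= 0) {                      # crossing inside (i, j]
      if (g[j] == g[i]) return(wl[j])
      return(wl[i] + (0 - g[i]) * (wl[j] - wl[i]) / (g[j] - g[i]))
    }
    i <- j
  }
}

#' Area over the minimum
#'
#' \eqn{AOM = MBD \times W} where \eqn{W} is the feature width measured where
#' the band depth equals half of the MBD.  The half-depth crossings are the
#' ones nearest to the deepest point on each side, located exactly by solving
#' the linear (in reflectance/chord space) crossing equation between grid
#' points; a side whose depth never falls to half within the zone is
#' truncated at the zone edge.  \eqn{AOM = 0} when \eqn{MBD = 0}.
#'
#' @param cr A \code{\link{continuum_removed}} object.
#' @return Numeric AOM (nm x depth).
#' @export
area_over_minimum <- function(cr) {
  stopifnot(inherits(cr, "continuum_removed"))
  mbd <- as.numeric(max_band_depth(cr))
  if (mbd <= 0) return(0)
  i_min <- which.min(cr$crr)[1L]          # smallest wavelength among ties
  level <- 1 - mbd / 2                    # CRR value at half depth
  left  <- crossing_from(cr, i_min, level, -1L)
  right <- crossing_from(cr, i_min, level, +1L)
  mbd * (right - left)
}

#' Absorption-feature index table
#'
#' Computes MBD and AOM for every sample and every requested zone.
#'
#' @param ds A reflectance \code{\link{spectral_dataset}} covering the zones.
#' @param zones Character vector of zone names (default all five).
#' @return Data frame with columns \code{sample_id}, \code{zone}, \code{MBD},
#'   \code{AOM}, \code{degenerate}; one row per sample x zone.
#' @export
extract_feature_table <- function(ds, zones = absorption_zones()$zone) {
  stopifnot(inherits(ds, "spectral_dataset"))
  rows <- vector("list", nrow(ds$values) * length(zones))
  k <- 0L
  for (i in seq_len(nrow(ds$values))) {
    x <- dataset_spectrum(ds, i)
    for (z in zones) {
      cr <- continuum_removed(x, z)
      mbd <- max_band_depth(cr)
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = ds$sample_ids[i], zone = z,
        MBD = as.numeric(mbd), AOM = area_over_minimum(cr),
        degenerate = attr(mbd, "degenerate"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Reshape a feature table into a predictor matrix
#'
#' @param features Output of \code{\link{extract_feature_table}}.
#' @param index \code{"MBD"} or \code{"AOM"}.
#' @param zones Zones to keep as columns, in order.
#' @return Numeric matrix, samples x zones, with dimnames.
#' @export
feature_matrix <- function(features, index = c("MBD", "AOM"),
                           zones = absorption_zones()$zone) {
  index <- match.arg(index)
  missing_z <- setdiff(zones, unique(features$zone))
  if (length(missing_z))
    stop("zones absent from feature table: ", paste(missing_z, collapse = ", "))
  ids <- unique(features$sample_id)
  m <- matrix(NA_real_, length(ids), length(zones),
              dimnames = list(ids, zones))
  for (z in zones) {
    sub <- features[features$zone == z, ]
    m[sub$sample_id, z] <- sub[[index]]
  }
  m
}
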