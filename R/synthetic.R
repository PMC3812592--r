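#' Configuration of the synthetic canopy simulator
#'
#' The generator emulates the sampling design of a grass/clover field
#' campaign: 30 plots, 15 repeated canopy readings per plot on a 1 nm grid
#' from 350 to 2,500 nm.  Total dry aboveground biomass (TAGB) is drawn from
#' a truncated Normal(45.05, 15.40) g/m^2 and the percent green fraction from
#' a truncated Normal(68.34, 13.57) %, matching the field campaign's sample
#' moments; GAGB is derived exactly as \code{TAGB * pctGAGB / 100}.
#' Absorption-feature depths are linked linearly to biomass
#' (\code{d = d0 + d1 * driver}) per zone, with Gaussian depth jitter, and
#' each reading receives per-detector noise (inflated tenfold inside the
#' noisy excluded wavelength windows) plus per-plot multiplicative scatter.
#'
#' @param n_plots Number of plots.
#' @param readings_per_plot Repeated readings per plot.
#' @param seed Root seed; per-plot substreams are derived from it so earlier
#'   plots are unchanged when \code{n_plots} grows.
#' @param grid Wavelength grid (nm).
#' @param tagb Mean, sd and truncation bounds of the TAGB distribution.
#' @param pct_green Mean, sd and truncation bounds of the percent green
#'   fraction.
#' @param links Per-zone linear depth links: list of
#'   \code{list(d0 =, d1 =, driver = "TAGB"|"pctGAGB")}.
#' @param depth_jitter_sd Gaussian jitter added to each true depth.
#' @param noise_sd Reading noise sd by detector: VNIR (< 1,000 nm), SWIR1
#'   (1,000--1,800 nm), SWIR2 (> 1,800 nm).
#' @param noisy_factor Multiplier on the noise sd inside the excluded
#'   windows (1,360--1,385, 1,800--1,930, >= 2,400 nm).
#' @param scatter_slope_sd,scatter_offset_sd Per-plot multiplicative scatter:
#'   slope ~ Normal(1, slope_sd), offset ~ Normal(0, offset_sd).
#' @return Object of class \code{"sim_config"}.
#' @export
simulation_config <- function(n_plots = 30L, readings_per_plot = 15L,
                              seed = 1L, grid = 350:2500,
                              tagb = c(mean = 45.05, sd = 15.40,
                                       lower = 5, upper = 80),
                              pct_green = c(mean = 68.34, sd = 13.57,
                                            lower = 25, upper = 95),
                              links = default_depth_links(),
                              depth_jitter_sd = 0.01,
                              noise_sd = c(VNIR = 0.004, SWIR1 = 0.008,
                                           SWIR2 = 0.012),
                              noisy_factor = 10,
                              scatter_slope_sd = 0.05,
                              scatter_offset_sd = 0.01) {
  if (any(noise_sd < 0) || depth_jitter_sd < 0)
    stop("noise standard deviations must be non-negative")
  if (min(grid) < 350 || max(grid) > 2500)
    stop("grid must lie within 350-2,500 nm")
  structure(list(n_plots = as.integer(n_plots),
                 readings_per_plot = as.integer(readings_per_plot),
                 seed = as.integer(seed), grid = as.numeric(grid),
                 tagb = tagb, pct_green = pct_green, links = links,
                 depth_jitter_sd = depth_jitter_sd, noise_sd = noise_sd,
                 noisy_factor = noisy_factor,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd),
            class = "sim_config")
}

#' Default biomass-to-depth links
#'
#' Pigment features (Z1, Z2) deepen with the percent green fraction; water
#' features (Z3--Z5) deepen with total biomass.  Depths are on the
#' continuum-removed scale and are clipped to \code{[0, 0.95]}.
#'
#' @return Named list of per-zone links.
#' @export
default_depth_links <- function() {
  list(Z1 = list(d0 = 0.10, d1 = 0.003,  driver = "pctGAGB"),
       Z2 = list(d0 = 0.10, d1 = 0.003,  driver = "pctGAGB"),
       Z3 = list(d0 = 0.03, d1 = 0.003,  driver = "TAGB"),
       Z4 = list(d0 = 0.05, d1 = 0.004,  driver = "TAGB"),
       Z5 = list(d0 = 0.04, d1 = 0.0035, driver = "TAGB"))
}

# dip centres/widths (nm): one Gaussian per zone Z1..Z5 plus the fixed
# 1,940 nm atmospheric water feature outside the modelled zones
dip_table <- function() {
  data.frame(zone = c("Z1", "Z2", "Z3", "Z4", "Z5", "W1940"),
             center = c(490, 670, 980, 1200, 1450, 1940),
             sd = c(25, 35, 30, 40, 45, 50),
             stringsAsFactors = FALSE)
}

#' Smooth canopy reflectance template with multiplicative absorption dips
#'
#' A deterministic grass-like template: visible floor 0.05 with a green-peak
#' bump at 550 nm, a sigmoid red edge centred at 715 nm rising to a NIR
#' plateau of 0.45, and a gentle linear SWIR decline beyond 1,500 nm.
#' Gaussian absorption dips (centres 490, 670, 980, 1,200, 1,450, 1,940 nm)
#' are applied multiplicatively, so a dip of amplitude \eqn{a} produces a
#' continuum-removed band depth close to \eqn{a}.
#'
#' @param grid Wavelength grid in nm (within 350--2,500).
#' @param depths Named numeric vector of dip amplitudes on the
#'   continuum-removed scale, names among \code{Z1..Z5, W1940}; missing dips
#'   default to 0.
#' @return A reflectance \code{\link{spectrum}} with all values in (0, 1).
#' @export
base_curve <- function(grid, depths = numeric(0)) {
  grid <- as.numeric(grid)
  if (min(grid) < 350 || max(grid) > 2500)
    stop("grid must lie within 350-2,500 nm")
  smooth <- 0.05 +
    0.06 * exp(-(grid - 550)^2 / (2 * 30^2)) +
    0.40 / (1 + exp(-(grid - 715) / 25)) -
    0.00022 * pmax(0, grid - 1500)
  dips <- dip_table()
  mult <- rep(1, length(grid))
  for (k in seq_len(nrow(dips))) {
    a <- if (dips$zone[k] %in% names(depths)) depths[[dips$zone[k]]] else 0
    a <- max(0, min(0.95, a))
    if (a > 0)
      mult <- mult * (1 - a * exp(-(grid - dips$center[k])^2 /
                                    (2 * dips$sd[k]^2)))
  }
  spectrum(grid, pmin(0.999, pmax(1e-4, smooth * mult)),
           kind = "reflectance")
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

noise_sd_vector <- function(grid, noise_sd, noisy_factor) {
  sdv <- ifelse(grid < 1000, noise_sd[["VNIR"]],
                ifelse(grid <= 1800, noise_sd[["SWIR1"]],
                       noise_sd[["SWIR2"]]))
  noisy <- (grid >= 1360 & grid <= 1385) |
    (grid >= 1800 & grid <= 1930) | (grid >= 2400)
  sdv[noisy] <- sdv[noisy] * noisy_factor
  sdv
}

plot_seed <- function(root, plot) as.integer((root * 10000 + 7919 * plot) %% 2147483647)

#' Simulate a full synthetic campaign
#'
#' Per plot: draw biomass, derive the per-zone true feature depths through
#' the configured links (with jitter, clipped to \code{[0, 0.95]}), build the
#' plot spectrum from \code{\link{base_curve}}, apply the plot's
#' multiplicative scatter (\code{slope * curve + offset}) and emit the
#' configured number of noisy readings (values clamped to the physical
#' \code{[0, 1.2]} range).  Fully reproducible for a fixed seed; per-plot
#' substreams keep earlier plots stable when \code{n_plots} changes.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{readings} (named list of
#'   \code{\link{reading_set}}s), \code{biomass} (validated data frame) and
#'   \code{truth} (per-plot true depths and scatter parameters).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  sdv <- noise_sd_vector(grid, config$noise_sd, config$noisy_factor)
  readings <- list()
  bio <- truth <- vector("list", config$n_plots)
  for (p in seq_len(config$n_plots)) {
    set.seed(plot_seed(config$seed, p))
    tagb <- rtruncnorm1(config$tagb[["mean"]], config$tagb[["sd"]],
                        config$tagb[["lower"]], config$tagb[["upper"]])
    pct <- rtruncnorm1(config$pct_green[["mean"]], config$pct_green[["sd"]],
                       config$pct_green[["lower"]], config$pct_green[["upper"]])
    gagb <- tagb * pct / 100
    drivers <- c(TAGB = tagb, GAGB = gagb, pctGAGB = pct)
    depths <- vapply(config$links, function(lk) {
      d <- lk$d0 + lk$d1 * drivers[[lk$driver]] +
        stats::rnorm(1L, 0, config$depth_jitter_sd)
      max(0, min(0.95, d))
    }, numeric(1))
    depths <- c(depths, W1940 = 0.30)
    slope <- stats::rnorm(1L, 1, config$scatter_slope_sd)
    offset <- stats::rnorm(1L, 0, config$scatter_offset_sd)
    curve <- slope * base_curve(grid, depths)$value + offset
    pid <- sprintf("plot%02d", p)
    specs <- lapply(seq_len(config$readings_per_plot), function(k) {
      v <- curve + stats::rnorm(length(grid), 0, sdv)
      spectrum(grid, pmin(1.2, pmax(0, v)), kind = "reflectance")
    })
    readings[[pid]] <- reading_set(pid, specs)
    bio[[p]] <- data.frame(plot_id = pid, TAGB = tagb, GAGB = gagb,
                           pctGAGB = pct, stringsAsFactors = FALSE)
    truth[[p]] <- data.frame(plot_id = pid, t(depths), slope = slope,
                             offset = offset, stringsAsFactors = FALSE)
  }
  list(readings = readings,
       biomass = validate_biomass(do.call(rbind, bio)),
       truth = do.call(rbind, truth))
}

#' End-to-end parameter-recovery benchmark
#'
#' Runs the complete pipeline on a simulated campaign: average the readings
#' (mean), exclude the noisy bands, extract the continuum-removal indices,
#' and fit factor-selected PLSR under leave-one-out cross-validation for
#' TAGB on MBD(Z3, Z4) and for GAGB on AOM(Z1, Z3, Z4).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with the simulated data, both \code{\link{cv_result}}s and
#'   the feature table.
#' @export
recovery_benchmark <- function(config = simulation_config()) {
  sim <- simulate_dataset(config)
  ds <- exclude_noisy_bands(average_plots(sim$readings, "mean"))
  feats <- extract_feature_table(ds)
  mbd <- feature_matrix(feats, "MBD")
  aom <- feature_matrix(feats, "AOM")
  bio <- sim$biomass[match(rownames(mbd), sim$biomass$plot_id), ]
  tagb <- select_plsr_factors(mbd[, c("Z3", "Z4")], bio$TAGB)
  gagb <- select_plsr_factors(aom[, c("Z1", "Z3", "Z4")], bio$GAGB)
  list(sim = sim, features = feats,
       tagb_mbd_z3z4 = tagb$cv, gagb_aom_z1z3z4 = gagb$cv)
}
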