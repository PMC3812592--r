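#' Default configuration of the model grid
#'
#' With these defaults the grid enumerates 140 model specifications per
#' response variable (420 over TAGB, GAGB and pctGAGB): per response, 12
#' untransformed models (PLSR and SVM on each of the three spectral subsets,
#' mean and median spectra), 124 PLSR models involving transformations or
#' continuum-removal products (18 transformations x 3 subsets x 2 averagings
#' = 108, continuum-removed reflectance for 5 zones x 2 = 10, the all-zone
#' MBD and AOM index sets x 2 = 4, and the full noisy-band-excluded spectrum
#' x 2 = 2) and 4 OLSR index models (MBD and AOM x 2 averagings, each
#' internally scanning the five zones and reporting the best one).
#'
#' @param responses Response variables to model.
#' @param transforms Transformation codes (see \code{\link{transform_codes}}).
#' @param subsets Spectral subset names.
#' @param zones Continuum-removal zones.
#' @param averagings Averaging statistics for the plot spectra.
#' @param C_grid SVR cost grid.
#' @param f_max Largest PLS factor count profiled.
#' @param center Percent-RMSE denominator statistic.
#' @param epsilon SVR tube half-width.
#' @return Object of class \code{"grid_config"}.
#' @export
grid_config <- function(responses = c("TAGB", "GAGB", "pctGAGB"),
                        transforms = transform_codes(),
                        subsets = c("VNIR", "VNIR_SWIR1", "VNIR_SWIR1_SWIR2"),
                        zones = absorption_zones()$zone,
                        averagings = c("mean", "median"),
                        C_grid = default_C_grid(),
                        f_max = 10L,
                        center = "mean",
                        epsilon = 0.1) {
  bad <- setdiff(transforms, transform_codes())
  if (length(bad)) stop("unknown transform codes: ", paste(bad, collapse = ", "))
  structure(list(responses = responses, transforms = transforms,
                 subsets = subsets, zones = zones, averagings = averagings,
                 C_grid = C_grid, f_max = as.integer(f_max), center = center,
                 epsilon = epsilon),
            class = "grid_config")
}

spec_row <- function(response, method, transform, input, averaging) {
  data.frame(response = response, method = method, transform = transform,
             input = input, averaging = averaging, stringsAsFactors = FALSE)
}

#' Enumerate the model grid
#'
#' Pure function of the configuration: no data needed.  SVM is only paired
#' with untransformed subsets and OLSR only with index inputs; requesting
#' anything else through a hand-built specification table is rejected by
#' \code{\link{run_grid}}.
#'
#' @param config A \code{\link{grid_config}}.
#' @return Data frame of model specifications, one row each, with columns
#'   \code{response, method, transform, input, averaging}.
#' @export
build_model_grid <- function(config = grid_config()) {
  stopifnot(inherits(config, "grid_config"))
  rows <- list()
  for (resp in config$responses) {
    for (avg in config$averagings) {
      for (sub in config$subsets) {
        rows[[length(rows) + 1L]] <- spec_row(resp, "PLSR", "none", sub, avg)
        rows[[length(rows) + 1L]] <- spec_row(resp, "SVM", "none", sub, avg)
        for (tr in config$transforms)
          rows[[length(rows) + 1L]] <- spec_row(resp, "PLSR", tr, sub, avg)
      }
      for (z in config$zones)
        rows[[length(rows) + 1L]] <- spec_row(resp, "PLSR", "CRR", z, avg)
      for (idx in c("MBD", "AOM")) {
        rows[[length(rows) + 1L]] <-
          spec_row(resp, "PLSR", idx, paste(config$zones, collapse = "-"), avg)
        rows[[length(rows) + 1L]] <-
          spec_row(resp, "OLSR", idx, "best-zone", avg)
      }
      rows[[length(rows) + 1L]] <- spec_row(resp, "PLSR", "none", "FULL", avg)
    }
  }
  out <- do.call(rbind, rows)
  key <- do.call(paste, c(out, sep = "|"))
  if (anyDuplicated(key)) stop("duplicate model specifications in grid")
  out
}

#' Precompute the shared inputs of a grid run
#'
#' Averages the per-plot readings with each requested statistic, removes the
#' noisy bands, and extracts the continuum-removal feature table per
#' averaging.
#'
#' @param reading_sets Named list of \code{\link{reading_set}}s.
#' @param config A \code{\link{grid_config}}.
#' @return List with per-averaging datasets and feature tables.
#' @export
prepare_grid_inputs <- function(reading_sets, config = grid_config()) {
  out <- list()
  for (avg in config$averagings) {
    ds <- exclude_noisy_bands(average_plots(reading_sets, avg))
    out[[avg]] <- list(dataset = ds,
                       features = extract_feature_table(ds, config$zones))
  }
  out
}

z4_pattern <- function() "Z4|VNIR_SWIR1|FULL"

#' Does a model specification's input cover the Z4 water feature?
#'
#' True for index or continuum inputs naming Z4 and for wavelength subsets
#' covering 1,079--1,297 nm (VNIR_SWIR1, VNIR_SWIR1_SWIR2, FULL).
#'
#' @param input Input descriptor string(s) from a grid row.
#' @return Logical vector.
#' @export
is_z4_bearing <- function(input) grepl(z4_pattern(), input)

run_one_spec <- function(spec, inputs, biomass, config) {
  ctx <- inputs[[spec$averaging]]
  ds <- ctx$dataset
  y <- biomass[match(ds$sample_ids, biomass$plot_id), spec$response]
  if (anyNA(y)) stop("missing '", spec$response, "' for some plots")
  center <- config$center
  if (spec$method == "SVM") {
    if (spec$transform != "none")
      stop("SVM is only run on untransformed subsets")
    X <- spectral_subset(ds, spec$input)$values
    fit <- fit_svr(X, y, C_grid = config$C_grid, epsilon = config$epsilon,
                   center = center)
    return(list(cv = fit$cv, complexity = fit$C, input = spec$input))
  }
  if (spec$method == "OLSR") {
    idx <- feature_matrix(ctx$features, spec$transform, config$zones)
    best <- NULL
    for (z in config$zones) {
      cv <- loocv(idx[, z, drop = FALSE], y,
                  fit_olsr, center = center, complexity = 1)
      if (is.null(best) || cv$R2 > best$cv$R2 ||
          (cv$R2 == best$cv$R2 && cv$RMSE < best$cv$RMSE))
        best <- list(cv = cv, complexity = 1, input = z)
    }
    return(best)
  }
  # PLSR family
  preprocess <- NULL
  if (spec$transform %in% c("none", "CRR", "MBD", "AOM")) {
    X <- switch(spec$transform,
      none = if (spec$input == "FULL") ds$values
             else spectral_subset(ds, spec$input)$values,
      CRR = t(vapply(seq_len(nrow(ds$values)), function(i)
        continuum_removed(dataset_spectrum(ds, i), spec$input)$crr,
        numeric(length(continuum_removed(dataset_spectrum(ds, 1L),
                                         spec$input)$crr)))),
      feature_matrix(ctx$features, spec$transform,
                     strsplit(spec$input, "-", fixed = TRUE)[[1L]]))
  } else if (is_msc_code(spec$transform)) {
    X <- spectral_subset(ds, spec$input)$values
    mode <- msc_mode_of(spec$transform)
    preprocess <- function(X_train, X_test) {
      ref <- colMeans(X_train)
      list(train = msc_correct_matrix(X_train, ref, mode),
           test = msc_correct_matrix(X_test, ref, mode))
    }
  } else {
    X <- apply_transform(spectral_subset(ds, spec$input),
                         spec$transform)$values
  }
  sel <- select_plsr_factors(X, y, f_max = config$f_max, center = center,
                             preprocess = preprocess)
  list(cv = sel$cv, complexity = sel$nfactors, input = spec$input)
}

#' Run a grid of model specifications
#'
#' Executes every row with the modelling tools; a failing row is recorded
#' (with its error message) rather than aborting the run.  Deterministic
#' given the data.
#'
#' @param specs Specification table from \code{\link{build_model_grid}}.
#' @param reading_sets Named list of \code{\link{reading_set}}s, or the
#'   output of \code{\link{prepare_grid_inputs}}.
#' @param biomass Validated biomass data frame.
#' @param config A \code{\link{grid_config}}.
#' @return Data frame, one row per specification, with the cross-validation
#'   statistics (\code{complexity, R2, RMSE, pct_RMSE}) and an \code{error}
#'   column (\code{NA} on success).
#' @export
run_grid <- function(specs, reading_sets, biomass, config = grid_config()) {
  validate_biomass(biomass)
  inputs <- if (!is.null(reading_sets[[1]]$dataset)) reading_sets
            else prepare_grid_inputs(reading_sets, config)
  out <- specs
  out$input_used <- out$input
  out$complexity <- NA_real_
  out$R2 <- NA_real_; out$RMSE <- NA_real_; out$pct_RMSE <- NA_real_
  out$overfit_flag <- NA
  out$error <- NA_character_
  for (i in seq_len(nrow(specs))) {
    res <- tryCatch(run_one_spec(specs[i, ], inputs, biomass, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$input_used[i] <- res$input
      out$complexity[i] <- res$complexity
      out$R2[i] <- res$cv$R2
      out$RMSE[i] <- res$cv$RMSE
      out$pct_RMSE[i] <- res$cv$pct_RMSE
      out$overfit_flag[i] <- res$cv$overfit_flag
    }
  }
  out
}

#' Is model A more accurate than model B?
#'
#' A model is flagged strictly more accurate than another only if it reduces
#' the cross-validation RMSE by at least 2 percent.
#'
#' @param rmse_a,rmse_b Cross-validation RMSEs.
#' @return Logical.
#' @export
more_accurate <- function(rmse_a, rmse_b) rmse_a <= 0.98 * rmse_b

#' Rank grid results
#'
#' Orders rows by cross-validated R^2 (descending), breaking ties by RMSE
#' (ascending) and then by the specification columns for a stable,
#' reproducible order.  Adds a \code{rank} column and a \code{beats_next}
#' flag: whether the row is more accurate (>= 2 percent RMSE reduction,
#' \code{\link{more_accurate}}) than the next-ranked row.
#'
#' @param results Output of \code{\link{run_grid}} (failed rows are dropped
#'   from the ranking).
#' @return The ranked data frame.
#' @export
rank_models <- function(results) {
  ok <- results[is.na(results$error), , drop = FALSE]
  if (nrow(ok) == 0L) stop("no successful rows to rank")
  key <- do.call(paste, c(ok[c("response", "method", "transform", "input",
                               "averaging")], sep = "|"))
  ord <- order(-ok$R2, ok$RMSE, key)
  ok <- ok[ord, , drop = FALSE]
  ok$rank <- seq_len(nrow(ok))
  ok$beats_next <- c(more_accurate(ok$RMSE[-nrow(ok)], ok$RMSE[-1L]), NA)
  ok
}

#' Explore zone combinations around a mandatory zone
#'
#' Runs factor-selected PLSR on the chosen continuum-removal index for every
#' subset of the optional zones unioned with the mandatory zone (15
#' combinations of sizes 2--5 with the default five zones).
#'
#' @param features Feature table from \code{\link{extract_feature_table}}.
#' @param y Response vector aligned with the feature table's samples.
#' @param index \code{"MBD"} or \code{"AOM"}.
#' @param mandatory Zone that every combination must contain.
#' @param zones All candidate zones.
#' @param f_max,center Passed to \code{\link{select_plsr_factors}}.
#' @return Data frame with one row per combination: \code{input}, \code{F},
#'   \code{R2}, \code{RMSE}, \code{pct_RMSE}.
#' @export
explore_zone_combinations <- function(features, y, index = c("MBD", "AOM"),
                                      mandatory = "Z4",
                                      zones = absorption_zones()$zone,
                                      f_max = 10L, center = "mean") {
  index <- match.arg(index)
  if (!mandatory %in% unique(features$zone))
    stop("mandatory zone '", mandatory, "' absent from feature table")
  optional <- setdiff(zones, mandatory)
  m <- feature_matrix(features, index, zones)
  rows <- list()
  for (k in seq_along(optional)) {
    for (combo in utils::combn(optional, k, simplify = FALSE)) {
      zs <- zones[zones %in% c(combo, mandatory)]   # canonical order
      sel <- select_plsr_factors(m[, zs, drop = FALSE], y,
                                 f_max = f_max, center = center)
      rows[[length(rows) + 1L]] <- data.frame(
        input = paste(zs, collapse = "-"), F = sel$nfactors,
        R2 = sel$cv$R2, RMSE = sel$cv$RMSE, pct_RMSE = sel$cv$pct_RMSE,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
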