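test_that("average_readings matches per-band mean/median and the identity case", {
  wl <- 400:410
  s <- spectrum(wl, seq(0.2, 0.4, length.out = length(wl)))
  rs <- reading_set("p1", rep(list(s), 15))
  expect_equal(average_readings(rs, "mean")$value, s$value)
  expect_equal(average_readings(rs, "median")$value, s$value)

  vals <- c(1, 2, 10) / 10      # one band, three readings
  rs2 <- reading_set("p2", lapply(vals, function(v) spectrum(400, v)))
  expect_equal(average_readings(rs2, "median")$value, 0.2)
  expect_equal(average_readings(rs2, "mean")$value, 1.3 / 3)
})

test_that("the 15-reading mean is within 4*sigma/sqrt(15) of truth at every band", {
  set.seed(11)
  wl <- 400:500
  truth <- 0.3 + 0.2 * sin(wl / 30)
  sigma <- 0.01
  rs <- reading_set("p", lapply(1:15, function(k)
    spectrum(wl, truth + rnorm(length(wl), 0, sigma))))
  avg <- average_readings(rs, "mean")
  expect_true(all(abs(avg$value - truth) < 4 * sigma / sqrt(15)))
})

test_that("mean averaging is linear in the readings, median is permutation-invariant", {
  set.seed(3)
  wl <- 400:420
  a <- lapply(1:5, function(k) spectrum(wl, runif(length(wl), 0.2, 0.4)))
  b <- lapply(1:5, function(k) spectrum(wl, runif(length(wl), 0.1, 0.3)))
  half <- lapply(1:5, function(k)
    spectrum(wl, (a[[k]]$value + b[[k]]$value) / 2))
  expect_equal(average_readings(reading_set("p", half), "mean")$value,
               (average_readings(reading_set("p", a), "mean")$value +
                average_readings(reading_set("p", b), "mean")$value) / 2)
  perm <- sample(5)
  expect_equal(
    average_readings(reading_set("p", a[perm]), "median")$value,
    average_readings(reading_set("p", a), "median")$value)
})

test_that("reading sets reject mismatched grids and empty sets", {
  s1 <- spectrum(400:410, rep(0.5, 11))
  s2 <- spectrum(401:411, rep(0.5, 11))
  expect_error(reading_set("p", list(s1, s2)), "identical wavelength grid")
  expect_error(reading_set("p", list()), "at least one")
})

test_that("noisy-band exclusion retains exactly the three printed ranges", {
  ds <- spectral_dataset(350:2500, matrix(0.5, 1, 2151), "a")
  e <- exclude_noisy_bands(ds)
  expect_identical(ncol(e$values), 1893L)
  # boundary behaviour at the 1,360-1,385 nm water window
  expect_false(1385 %in% e$wavelength)
  expect_true(1386 %in% e$wavelength)
  expect_true(1359 %in% e$wavelength)
  expect_false(1360 %in% e$wavelength)
  expect_false(2400 %in% e$wavelength)
  expect_true(2399 %in% e$wavelength)
  # idempotent, and a no-op on an already-clean grid
  expect_identical(exclude_noisy_bands(e)$wavelength, e$wavelength)
  clean <- spectral_dataset(400:500, matrix(0.5, 1, 101), "a")
  expect_identical(exclude_noisy_bands(clean)$wavelength, clean$wavelength)
})

test_that("spectral subsets have the derived band counts and are nested", {
  ds <- exclude_noisy_bands(
    spectral_dataset(350:2500, matrix(0.5, 1, 2151), "a"))
  vnir <- spectral_subset(ds, "VNIR")
  vs1 <- spectral_subset(ds, "VNIR_SWIR1")
  vs12 <- spectral_subset(ds, "VNIR_SWIR1_SWIR2")
  expect_identical(ncol(vnir$values), 651L)
  expect_identical(ncol(vs1$values), 1424L)
  expect_identical(vs12$wavelength, ds$wavelength)
  expect_true(all(vnir$wavelength %in% vs1$wavelength))
  expect_true(all(vs1$wavelength %in% vs12$wavelength))
  expect_error(spectral_subset(ds, "SWIR3"), "unknown spectral subset")
})

test_that("spectrum and dataset constructors enforce their invariants", {
  expect_error(spectrum(c(400, 400, 401), c(1, 2, 3) / 10), "increasing")
  expect_error(spectrum(400:402, c(0.5, 1.3, 0.5)), "\\[0, 1.2\\]")
  expect_silent(spectrum(400:402, c(0.5, 1.15, 0.5)))  # panel artifact ok
  expect_error(spectral_dataset(400:401, matrix(0.5, 2, 2), c("a", "a")),
               "duplicate")
})

test_that("biomass validation enforces the record invariants", {
  ok <- data.frame(plot_id = "p1", TAGB = 50, GAGB = 30, pctGAGB = 60)
  expect_identical(validate_biomass(ok), ok)
  bad1 <- transform(ok, GAGB = 60)
  expect_error(validate_biomass(bad1), "GAGB cannot exceed TAGB")
  bad2 <- transform(ok, pctGAGB = 65)   # inconsistent with 100*GAGB/TAGB
  expect_error(validate_biomass(bad2), "inconsistent")
})

test_that("spectra and dataset files round-trip losslessly", {
  set.seed(21)
  wl <- seq(400, 900, by = 5)
  rs <- lapply(c("pA", "pB", "pC"), function(p)
    reading_set(p, lapply(1:3, function(k)
      spectrum(wl, runif(length(wl), 0.1, 0.9)))))
  names(rs) <- c("pA", "pB", "pC")
  f <- withr::local_tempfile(fileext = ".csv")
  write_spectra(rs, f)
  back <- read_spectra(f)
  expect_identical(names(back), names(rs))
  expect_equal(back$pB$readings[[2]]$value, rs$pB$readings[[2]]$value,
               tolerance = 1e-12)

  ds <- average_plots(rs, "mean")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, f2)
  back2 <- read_dataset(f2, averaging = "mean")
  expect_equal(back2$values, ds$values, tolerance = 1e-12)
  expect_equal(back2$wavelength, ds$wavelength)

  # duplicated sample ids and malformed headers are rejected
  writeLines(c("wavelength_nm,p1,p1", "400,0.5,0.5"), f)
  expect_error(read_dataset(f), "duplicate")
  writeLines(c("lambda,p1", "400,0.5"), f)
  expect_error(read_dataset(f), "malformed header")
  writeLines(c("wavelength_nm,p1__r1", "401,0.5", "400,0.6"), f)
  expect_error(read_spectra(f), "increasing")
})
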