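test_that("baseline offset subtracts the per-spectrum minimum", {
  expect_equal(baseline_offset(flat_spectrum(0.7))$value, rep(0, 101))
  x <- spectrum(400:402, c(1, 3, 2) / 10)
  expect_equal(baseline_offset(x)$value, c(0, 2, 1) / 10)
  set.seed(5)
  for (k in 1:100)
    expect_equal(min(baseline_offset(random_pw_spectrum())$value), 0)
})

test_that("detrend annihilates polynomials up to its order and is orthogonal to them", {
  wl <- seq(400, 900, by = 2)
  for (k in 1:3) {
    poly_vals <- 0.5 + 1e-4 * (wl - 650) + 1e-7 * (wl - 650)^2 * (k >= 2) +
      1e-10 * (wl - 650)^3 * (k >= 3)
    x <- spectrum(wl, poly_vals / max(poly_vals))
    expect_lt(max(abs(detrend(x, k)$value)), 1e-9)
  }
  # residuals orthogonal to the monomial basis
  set.seed(9)
  x <- random_pw_spectrum(wl = 400:700, n_knots = 8)
  r <- detrend(x, 2)$value
  for (deg in 0:2)
    expect_lt(abs(sum(r * (x$wavelength / 700)^deg)), 1e-6 * length(r))
  expect_error(detrend(spectrum(400:402, c(0.1, 0.2, 0.3)), 2), "few bands")
})

test_that("MSC recovers the reference and is the identity on identical spectra", {
  wl <- seq(400, 900, by = 10)
  ref <- 0.2 + 0.3 * exp(-(wl - 650)^2 / 2e4)
  same <- spectral_dataset(wl, rbind(ref, ref, ref), c("a", "b", "c"))
  expect_equal(msc(same, "full")$values, same$values, ignore_attr = TRUE)
  # x = 2*ref + 0.1: full MSC against an explicit reference recovers ref
  ds <- spectral_dataset(wl, rbind(2 * ref + 0.1, ref), c("a", "b"),
                         kind = "transformed")
  out <- msc(ds, "full", reference = ref)
  expect_equal(out$values[1, ], ref, ignore_attr = TRUE, tolerance = 1e-12)
  # offset/amplification apply only the named part of the fit
  expect_equal(msc(ds, "offset", reference = ref)$values[1, ],
               2 * ref, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(msc(ds, "amplification", reference = ref)$values[1, ],
               ref + 0.05, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("full-MSC output means reproduce the reference on random data", {
  set.seed(31)
  wl <- seq(400, 900, by = 10)
  ref <- 0.2 + 0.3 * exp(-(wl - 650)^2 / 2e4)
  m <- t(sapply(1:8, function(i)
    runif(1, 0.5, 2) * ref + runif(1, -0.05, 0.05) +
      rnorm(length(wl), 0, 0.002)))
  ds <- spectral_dataset(wl, m, sprintf("s%d", 1:8), kind = "transformed")
  out <- msc(ds, "full")
  # corrected spectra all collapse onto the reference shape
  expect_lt(max(abs(sweep(out$values, 2, colMeans(ds$values)))), 0.05)
})

test_that("normalisations divide by the advertised scalar", {
  x <- spectrum(seq(0, 10, by = 0.5) + 350, rep(0.2, 21))
  # constant 2 over a width-10 interval: area 20 (values scaled to reflectance)
  area <- normalize_spectrum(spectrum(350 + seq(0, 10, 0.5), rep(1, 21)), "area")
  expect_equal(area$value, rep(1 / 10, 21))
  set.seed(13)
  y <- random_pw_spectrum()
  expect_equal(sqrt(sum(normalize_spectrum(y, "unit_vector")$value^2)), 1)
  expect_equal(max(normalize_spectrum(y, "max")$value), 1)
  expect_equal(mean(normalize_spectrum(y, "mean")$value), 1)
  rng <- normalize_spectrum(y, "range")$value
  expect_equal(max(rng) - min(rng), 1)
  expect_error(normalize_spectrum(flat_spectrum(0.5), "range"),
               "zero denominator")
})

test_that("Norris gap derivative is exact on lines and quadratics", {
  wl <- 400:500
  for (g in c(3, 5, 7, 9)) {
    lin <- norris_gap_derivative(spectrum(wl, (2e-3) * (wl - 400)), g)
    expect_equal(lin$value, rep(2e-3, length(lin$value)))
    expect_identical(length(lin$wavelength), length(wl) - 2L * as.integer(g))
    flat <- norris_gap_derivative(flat_spectrum(0.4, wl), g)
    expect_equal(flat$value, rep(0, length(flat$value)))
  }
  # central gap difference of lambda^2 is exactly 2*lambda
  u <- 0:60
  quad <- spectrum(350 + u, (u / 60)^2, kind = "transformed")
  d <- norris_gap_derivative(quad, 5)
  expect_equal(d$value, 2 * (d$wavelength - 350) / 60^2, tolerance = 1e-12)
  expect_error(norris_gap_derivative(spectrum(400:405, runif(6)), 3),
               "too short")
})

test_that("reflectance-absorbance conversion round-trips", {
  expect_equal(reflectance_to_absorbance(flat_spectrum(1))$value, rep(0, 101))
  expect_equal(reflectance_to_absorbance(flat_spectrum(0.1))$value,
               rep(1, 101))
  set.seed(17)
  x <- random_pw_spectrum()
  a <- reflectance_to_absorbance(x)
  expect_equal(10^(-a$value), x$value, tolerance = 1e-12)
  expect_error(
    reflectance_to_absorbance(spectrum(1:3 + 400, c(0, 0.5, 0.5))),
    "positive")
})

test_that("SNV standardises each spectrum and is affine-invariant", {
  set.seed(19)
  x <- random_pw_spectrum()
  z <- snv(x)
  expect_equal(mean(z$value), 0, tolerance = 1e-12)
  expect_equal(sd(z$value), 1, tolerance = 1e-12)
  shifted <- spectrum(x$wavelength, 0.05 + 0.5 * x$value)
  expect_equal(snv(shifted)$value, z$value, tolerance = 1e-10)
  expect_equal(snv(spectrum(400:402, c(0, 1, 2) / 10))$value, c(-1, 0, 1))
  expect_error(snv(flat_spectrum(0.3)), "constant")
})

test_that("every coded transformation runs, deterministically, on a dataset", {
  ds <- small_dataset(n = 5)
  for (code in transform_codes()) {
    out1 <- apply_transform(ds, code)
    out2 <- apply_transform(ds, code)
    expect_identical(out1$values, out2$values)
    expect_s3_class(out1, "spectral_dataset")
    expect_identical(out1$kind, "transformed")
  }
  expect_error(apply_transform(ds, "SAVGOL"), "unknown transformation")
  # MSC reference is recomputed per dataset: permuting samples permutes rows
  perm <- c(3, 1, 5, 2, 4)
  dsp <- spectral_dataset(ds$wavelength, ds$values[perm, ],
                          ds$sample_ids[perm])
  expect_equal(apply_transform(dsp, "MSCF")$values,
               apply_transform(ds, "MSCF")$values[perm, ],
               ignore_attr = TRUE)
})
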