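test_that("reader skips headers, detects pitch, and flags bad input", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Sample: lysozyme", "wavelength CD", "# pitch 1 nm",
               paste(250:235, seq(0, 1.5, by = 0.1))), f)
  s <- read_cd_spectrum(f)
  expect_equal(nrow(s), 16)
  expect_equal(s$wavelength, 235:250)          # stored ascending
  expect_equal(s$value, rev(seq(0, 1.5, by = 0.1)))
  expect_equal(spectrum_pitch(s$wavelength), 1)

  # descending 0.5 nm pitch, comma-delimited
  f2 <- withr::local_tempfile(fileext = ".txt")
  w <- seq(250, 240, by = -0.5)
  writeLines(paste(w, rnorm(length(w)), sep = ","), f2)
  expect_equal(spectrum_pitch(read_cd_spectrum(f2)$wavelength), 0.5)

  # corrupt cell inside the data block names its line
  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(paste(250:241, 0.1), "240 oops", paste(239:230, 0.2)), f3)
  expect_error(read_cd_spectrum(f3), "line 11")

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(250:245, 0.1), f4)
  expect_error(read_cd_spectrum(f4), "insufficient")

  expect_error(cd_spectrum(c(200, 200.3, 200.6), c(1, 2, 3)),
               "pitch")
})

test_that("written spectra round-trip bit-identically", {
  set.seed(7)
  s <- cd_spectrum(seq(180, 260, by = 0.2), rnorm(401))
  f <- withr::local_tempfile(fileext = ".txt")
  write_cd_spectrum(s, f)
  r <- read_cd_spectrum(f)
  expect_identical(r$wavelength, s$wavelength)
  expect_identical(r$value, s$value)
})

test_that("unit conversions use the fixed constants and round-trip", {
  s <- cd_spectrum(200:250, rep(1, 51), unit = "delta_epsilon")
  expect_equal(convert_cd_units(s, "mre")$value, rep(3298, 51))

  m <- cd_spectrum(200:250, rep(32980, 51), unit = "mdeg",
                   concentration = 1, pathlength = 1, n_residues = 1)
  expect_equal(convert_cd_units(m, "delta_epsilon")$value, rep(1, 51))

  set.seed(11)
  s2 <- cd_spectrum(200:250, rnorm(51), unit = "delta_epsilon",
                    concentration = 2e-5, pathlength = 0.1,
                    n_residues = 120)
  for (via in c("mre", "mdeg")) {
    back <- convert_cd_units(convert_cd_units(s2, via), "delta_epsilon")
    expect_equal(back$value, s2$value, tolerance = 1e-12)
  }
  bad <- cd_spectrum(200:250, rnorm(51), unit = "mdeg")
  expect_error(convert_cd_units(bad, "delta_epsilon"), "concentration")
})

test_that("smoothing is a truncated-window mean and linear", {
  w <- seq(190, 250, by = 0.5)
  const <- cd_spectrum(w, rep(2.5, length(w)))
  expect_equal(cd_smooth(const)$value, rep(2.5, length(w)))

  lin <- cd_spectrum(w, 3 * w - 100)
  sm <- cd_smooth(lin)
  interior <- w >= 192 & w <= 248
  expect_equal(sm$value[interior], lin$value[interior])

  set.seed(3)
  r <- cd_spectrum(w, rnorm(length(w)))
  expect_equal(cd_smooth(r, 2)$value,
               oracle_window_mean(w, r$value, w, 1, strict = TRUE))

  # linear operator
  set.seed(4)
  a <- cd_spectrum(w, rnorm(length(w))); b <- cd_spectrum(w, rnorm(length(w)))
  combo <- cd_spectrum(w, 2 * a$value - 3 * b$value)
  expect_equal(cd_smooth(combo)$value,
               2 * cd_smooth(a)$value - 3 * cd_smooth(b)$value)
})

test_that("regridding bin-averages onto integer nodes", {
  w <- seq(190.05, 250, by = 0.1)
  ramp <- cd_spectrum(w, 5 * w)
  rg <- cd_regrid(ramp, 1)
  expect_equal(rg$wavelength, 191:249)
  expect_equal(rg$value, 5 * rg$wavelength, tolerance = 1e-9)

  set.seed(8)
  w2 <- seq(200, 240, by = 0.2)
  r <- cd_spectrum(w2, rnorm(length(w2)))
  rg2 <- cd_regrid(r, 1)
  expect_equal(rg2$value,
               oracle_window_mean(w2, r$value, rg2$wavelength, 0.5))

  already <- cd_spectrum(200:240, rnorm(41))
  expect_equal(cd_regrid(already, 1)$value, already$value)
  expect_error(cd_regrid(already, 0.5), "upsampling")
})

test_that("RMSD uses the raw spectrum while NRMSD uses the smoothed one", {
  w <- 200:240
  set.seed(5)
  smoothed <- cd_spectrum(w, sin(w / 5) * 4)
  raw <- cd_spectrum(w, smoothed$value + rnorm(41, 0, 0.3))
  fitted <- smoothed                       # fitted == smoothed != raw
  q <- fit_quality(raw, smoothed, fitted)
  expect_equal(q$nrmsd, 0)
  expect_gt(q$rmsd, 0)
  expect_equal(q$rmsd, sqrt(mean((raw$value - fitted$value)^2)))

  q2 <- fit_quality(raw, raw, raw)
  expect_equal(q2$rmsd, 0); expect_equal(q2$nrmsd, 0)

  # scale invariance of NRMSD
  sc <- cd_spectrum(w, smoothed$value * 7.3)
  fit_sc <- cd_spectrum(w, fitted$value * 7.3)
  expect_equal(fit_quality(raw, sc, fit_sc)$nrmsd,
               fit_quality(raw, smoothed, fitted)$nrmsd)
  zero <- cd_spectrum(w, rep(0, 41))
  expect_error(fit_quality(raw, zero, zero), "NRMSD undefined")
})

test_that("scale scan recovers inverse amplitude errors", {
  truth <- truth_small()
  ss0 <- ss_vector(c(0.3, 0.1, 0.1, 0.1, 0.05, 0.05, 0.1, 0.2))
  clean <- evaluate_model(truth, ss0)
  dec <- function(s) {
    fit <- fit_secondary_structure(s, truth, n_starts = 6)
    fit$quality$nrmsd
  }
  pre <- clean
  pre$value <- clean$value * 1.3
  scan <- scale_scan(pre, dec, center = 1, n_steps = 31)
  expect_equal(attr(scan, "best_factor"), 1 / 1.3,
               tolerance = exp(log(4) / 30) - 1)

  scan1 <- scale_scan(clean, dec, center = 1, n_steps = 31)
  expect_equal(attr(scan1, "best_factor"), 1,
               tolerance = exp(log(4) / 30) - 1)

  single <- scale_scan(clean, dec, center = 1, n_steps = 1)
  expect_equal(nrow(single), 1)
  expect_equal(single$factor, 1)

  # callback failures are flagged, scan continues
  flaky <- function(s) if (max(abs(s$value)) > max(abs(clean$value)) * 1.2)
    stop("boom") else dec(s)
  scan2 <- scale_scan(clean, flaky, center = 1, n_steps = 11)
  expect_true(any(!scan2$ok) && any(scan2$ok))
})

test_that("amplitude plausibility warning fires outside the band", {
  ok <- cd_spectrum(200:250, rep(5, 51))
  expect_silent(check_cd_amplitude(ok))
  loud <- cd_spectrum(200:250, rep(500, 51))
  expect_warning(check_cd_amplitude(loud), "abnormal")
})
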