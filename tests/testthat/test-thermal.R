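rand_params <- function(seed) {
  set.seed(seed)
  list(A_N = rnorm(1, -10, 3), m_N = rnorm(1, 0.01, 0.005),
       A_D = rnorm(1, -2, 1), m_D = rnorm(1, 0.002, 0.002),
       T_m = runif(1, 310, 350), dH_m = runif(1, 2e5, 6e5),
       dCp = runif(1, 0, 1e4))
}

test_that("the melting model matches an independent transliteration", {
  T <- seq(275, 380, length.out = 50)
  for (s in 1:10) {
    p <- rand_params(s)
    expect_equal(model_cd(T, p), oracle_model_cd(T, p), tolerance = 1e-12)
  }
  # algebraic checkpoints
  p <- rand_params(99)
  mid <- ((p$A_N + p$m_N * p$T_m) + (p$A_D + p$m_D * p$T_m)) / 2
  expect_equal(model_cd(p$T_m, p), mid, tolerance = 1e-12)
  p0 <- p; p0$dCp <- 0
  expect_equal(model_cd(200 + 73, p0), p0$A_N + p0$m_N * 273,
               tolerance = 1e-6)
  # overflow safety far from T_m
  p$dH_m <- 5e6
  expect_true(all(is.finite(model_cd(c(260, 400), p))))
})

test_that("free energy follows the Gibbs-Helmholtz form", {
  for (s in 1:10) {
    p <- rand_params(s + 20)
    expect_equal(delta_g(p$T_m, p), 0, tolerance = 1e-9)
    expect_equal(delta_g(298.15, p), oracle_delta_g(298.15, p),
                 tolerance = 1e-12)
    p0 <- p; p0$dCp <- 0
    T <- seq(280, 360, 10)
    expect_equal(delta_g(T, p0), p0$dH_m * (1 - T / p0$T_m),
                 tolerance = 1e-12)
    # consistency with -RT log K of the model's equilibrium factor
    R <- 8.314
    y <- (1 / R) * ((p$T_m * p$dCp - p$dH_m) / T + p$dH_m / p$T_m - p$dCp)
    lnK <- y + (p$dCp / R) * log(T / p$T_m)
    expect_equal(delta_g(T, p), -R * T * lnK,
                 tolerance = 1e-9 * max(abs(delta_g(T, p))))
  }
})

test_that("dCp estimation applies the per-residue rule", {
  expect_equal(estimate_dcp(100), 5000)
  expect_equal(estimate_dcp(1), 50)
  expect_error(estimate_dcp(0), "argument error")
})

test_that("noise-free curves are recovered to high precision", {
  p <- list(A_N = -11, m_N = 0.004, A_D = -2, m_D = 0.0015,
            T_m = 330, dH_m = 4e5, dCp = 8000)
  curve <- gen_melting_curve(p, sigma = 0, seed = 1)
  fit <- fit_melting(curve, dCp = 8000)
  expect_true(fit$converged)
  for (nm in c("A_N", "m_N", "A_D", "m_D", "T_m", "dH_m")) {
    expect_equal(fit$params[[nm]], p[[nm]],
                 tolerance = 1e-6 * max(1, abs(p[[nm]])))
  }
  expect_equal(fit$params$dCp, 8000)      # fixed, not fitted
  g <- glance(fit)
  expect_equal(g$dG_25C, delta_g(298.15, p), tolerance = 1e-4 * abs(g$dG_25C))
  expect_equal(delta_g(fit$params$T_m, fit$params), 0, tolerance = 1e-9)
})

test_that("noisy recovery is accurate and manual inits are honoured", {
  p <- list(A_N = -11, m_N = 0.004, A_D = -2, m_D = 0.0015,
            T_m = 330, dH_m = 4e5, dCp = 8000)
  errs <- vapply(1:25, function(s) {
    f <- fit_melting(gen_melting_curve(p, sigma = 0.01, seed = s),
                     dCp = 8000)
    c(f$params$T_m - p$T_m, f$params$dH_m / p$dH_m - 1)
  }, numeric(2))
  expect_lt(sqrt(mean(errs[1, ]^2)), 0.3)
  expect_lt(sqrt(mean(errs[2, ]^2)), 0.03)

  curve <- gen_melting_curve(p, sigma = 0.01, seed = 3)
  f2 <- fit_melting(curve, dCp = 8000, init = list(T_m = 320, dH_m = 3e5))
  expect_equal(f2$params$T_m, p$T_m, tolerance = 1e-3)
  td <- tidy(f2)
  expect_equal(td$term[7], "dCp")
  expect_true(all(is.finite(td$std_error[1:6])))
  expect_s3_class(autoplot(f2), "ggplot")
})

test_that("transition-free data are flagged as non-converged", {
  T <- seq(290, 360, by = 1)
  set.seed(12)
  curve <- melting_curve(T, -5 + 0.01 * T + rnorm(length(T), 0, 0.02))
  fit <- fit_melting(curve, dCp = 0)
  expect_false(fit$converged)
  expect_true(fit$no_transition)
})

test_that("fits are equivariant under affine rescaling of the CD axis", {
  p <- list(A_N = -11, m_N = 0.004, A_D = -2, m_D = 0.0015,
            T_m = 330, dH_m = 4e5, dCp = 5000)
  curve <- gen_melting_curve(p, sigma = 0.005, seed = 8)
  f1 <- fit_melting(curve, dCp = 5000)
  scaled <- curve; scaled$value <- 3 * curve$value + 10
  f2 <- fit_melting(scaled, dCp = 5000)
  expect_equal(f2$params$T_m, f1$params$T_m, tolerance = 1e-6)
  expect_equal(f2$params$dH_m, f1$params$dH_m, tolerance = 1e-5 * p$dH_m)
  expect_equal(f2$rmsd, 3 * f1$rmsd, tolerance = 1e-6)
})

test_that("melting curves read from text with Celsius conversion", {
  p <- list(A_N = -11, m_N = 0.004, A_D = -2, m_D = 0.0015,
            T_m = 330, dH_m = 4e5, dCp = 5000)
  curve <- gen_melting_curve(p, sigma = 0, seed = 1)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("temp_C CD", paste(curve$temperature - 273.15, curve$value)),
             f)
  back <- read_melting_curve(f, unit = "C")
  expect_equal(back$temperature, curve$temperature, tolerance = 1e-9)
  expect_error(melting_curve(seq(300, 305, 0.5), rnorm(11)), ">= 20 K")
})
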