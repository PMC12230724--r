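#' @rdname model_cd
#' @export
GAS_CONSTANT <- 8.314  # J/(mol K)

#' Two-state thermal denaturation model
#'
#' Evaluates the Gibbs-Helmholtz two-state melting model.  The native and
#' denatured baselines are linear in temperature, `A_N + m_N T` and
#' `A_D + m_D T` (amplitudes are intercepts at 0 K), and the population of
#' the denatured state follows the unfolding equilibrium factor
#' `K(T) = exp(y) * (T/T_m)^(dCp/R)` with
#' `y = (1/R) * ((T_m dCp - dH_m)/T + dH_m/T_m - dCp)`.
#' The curve is computed in log space so large `|y|` cannot overflow.
#'
#' @param temperature Absolute temperature(s), K.
#' @param params Named list or vector with `A_N`, `m_N`, `A_D`, `m_D`,
#'   `T_m` (K), `dH_m` (J/mol) and `dCp` (J/(mol K), fixed).
#' @return CD value(s) of the model at `temperature`.
#' @export
model_cd <- function(temperature, params) {
  p <- as.list(params)
  T <- as.numeric(temperature)
  if (any(T <= 0)) abort("temperature must be positive (Kelvin)")
  R <- GAS_CONSTANT
  y <- (1 / R) * ((p$T_m * p$dCp - p$dH_m) / T + p$dH_m / p$T_m - p$dCp)
  logK <- y + (p$dCp / R) * log(T / p$T_m)
  fd <- stats::plogis(logK)                 # K/(1+K), overflow-safe
  (p$A_N + p$m_N * T) * (1 - fd) + (p$A_D + p$m_D * T) * fd
}

#' Unfolding free energy from the Gibbs-Helmholtz relation
#'
#' `dG(T) = dH_m (1 - T/T_m) - dCp ((T_m - T) + T ln(T/T_m))`, in J/mol.
#' `dG(T_m) = 0` exactly.
#'
#' @param temperature Absolute temperature(s), K.
#' @param params As in [model_cd()] (only `T_m`, `dH_m`, `dCp` used).
#' @return Free energy change of unfolding in J/mol.
#' @export
delta_g <- function(temperature, params) {
  p <- as.list(params)
  T <- as.numeric(temperature)
  if (any(T <= 0) || p$T_m <= 0) abort("temperatures must be positive")
  p$dH_m * (1 - T / p$T_m) - p$dCp * ((p$T_m - T) + T * log(T / p$T_m))
}

#' Rough heat-capacity estimate for globular proteins
#'
#' Uses the per-residue rule of thumb of about 50 J/(mol K) per residue
#' for the unfolding heat-capacity change of small globular proteins.
#'
#' @param n_residues Number of residues (positive integer).
#' @return Estimated `dCp` in J/(mol K).
#' @export
estimate_dcp <- function(n_residues) {
  if (!is.numeric(n_residues) || length(n_residues) != 1 || n_residues <= 0)
    abort("argument error: n_residues must be a positive integer")
  50 * n_residues
}

#' Construct a melting curve
#'
#' @param temperature Temperatures, strictly increasing; Kelvin, or
#'   Celsius with `unit = "C"` (converted to Kelvin on input).
#' @param value CD values in any single consistent unit.
#' @param unit `"K"` or `"C"`.
#' @return A `melting_curve` tibble (temperatures in K).
#' @export
melting_curve <- function(temperature, value, unit = c("K", "C")) {
  unit <- match.arg(unit)
  if (unit == "C") temperature <- temperature + 273.15
  if (any(diff(temperature) <= 0))
    abort("temperatures must be strictly increasing")
  if (length(temperature) < 10 ||
      max(temperature) - min(temperature) < 20)
    abort("a melting curve needs >= 10 points spanning >= 20 K")
  out <- tibble(temperature = as.numeric(temperature),
                value = as.numeric(value))
  class(out) <- c("melting_curve", class(out))
  out
}

#' Read a two-column temperature/CD melting profile
#'
#' @param file Path; same header-skipping rules as [read_cd_spectrum()].
#' @param unit `"C"` (default) or `"K"` for the temperature column.
#' @return A `melting_curve`.
#' @export
read_melting_curve <- function(file, unit = c("C", "K")) {
  unit <- match.arg(unit)
  s <- read_cd_spectrum(file)              # reuse the 2-column text reader
  melting_curve(s$wavelength, s$value, unit = unit)
}

# automatic initialization: baselines from the curve extremes, T_m from
# the half-transition crossing, dH_m from a van't Hoff slope
init_thermal <- function(curve, dCp) {
  T <- curve$temperature; v <- curve$value
  n <- length(T)
  k <- max(3L, floor(0.2 * n))
  lo <- seq_len(k); hi <- seq(n - k + 1L, n)
  cN <- stats::coef(stats::lm(v[lo] ~ T[lo]))
  cD <- stats::coef(stats::lm(v[hi] ~ T[hi]))
  base_n <- cN[1] + cN[2] * T
  base_d <- cD[1] + cD[2] * T
  frac <- (v - base_n) / ifelse(abs(base_d - base_n) < 1e-12, 1e-12,
                                base_d - base_n)
  cross <- which(diff(sign(frac - 0.5)) != 0)
  T_m <- if (length(cross) > 0) {
    i <- cross[1]
    T[i] + (0.5 - frac[i]) * (T[i + 1] - T[i]) / (frac[i + 1] - frac[i])
  } else stats::median(T)
  mid <- frac > 0.15 & frac < 0.85 & is.finite(frac)
  dH_m <- 4e5
  if (sum(mid) >= 3) {
    fr <- pmin(pmax(frac[mid], 0.02), 0.98)
    lnK <- log(fr / (1 - fr))
    sl <- stats::coef(stats::lm(lnK ~ I(1 / T[mid])))[2]
    if (is.finite(sl) && sl < 0) dH_m <- -GAS_CONSTANT * sl
  }
  list(A_N = unname(cN[1]), m_N = unname(cN[2]),
       A_D = unname(cD[1]), m_D = unname(cD[2]),
       T_m = unname(T_m), dH_m = unname(max(dH_m, 1e4)), dCp = dCp)
}

#' Fit the two-state thermal denaturation model
#'
#' Nonlinear least squares over `A_N, m_N, A_D, m_D, T_m, dH_m` with the
#' heat-capacity change `dCp` held fixed.  Initial values are derived from
#' the data (linear baselines through the coolest and hottest 20% of
#' points, half-transition crossing for `T_m`, van't Hoff slope for
#' `dH_m`) and can be overridden for manual re-fits.  Standard errors come
#' from the linearized covariance at the optimum.
#'
#' @param curve A `melting_curve` (or tibble with `temperature` in K and
#'   `value`).
#' @param dCp Fixed heat-capacity change, J/(mol K).
#' @param range Optional temperature interval `c(min, max)` in K.
#' @param init Optional named list overriding any of the automatic
#'   initial values.
#' @return A `thermal_fit` object; see [tidy.thermal_fit()],
#'   [glance.thermal_fit()], [autoplot.thermal_fit()].
#' @export
fit_melting <- function(curve, dCp, range = NULL, init = NULL) {
  if (!is.numeric(dCp) || length(dCp) != 1 || !is.finite(dCp) || dCp < 0)
    abort("dCp must be a single nonnegative number (J/(mol K))")
  if (!is.null(range)) {
    keep <- curve$temperature >= range[1] & curve$temperature <= range[2]
    curve <- curve[keep, , drop = FALSE]
  }
  T <- curve$temperature; v <- curve$value
  if (length(T) < 10) abort("fewer than 10 points on the fit range")
  p0 <- init_thermal(curve, dCp)
  for (nm in names(init)) p0[[nm]] <- init[[nm]]

  # transition detection: a single straight line explaining the data to
  # within the point-to-point noise level means there is no sigmoid to fit
  noise <- stats::sd(diff(v)) / sqrt(2)
  line_resid <- stats::sd(stats::residuals(stats::lm(v ~ T)))
  no_transition <- line_resid < 3 * noise

  par0 <- c(A_N = p0$A_N, m_N = p0$m_N, A_D = p0$A_D, m_D = p0$m_D,
            T_m = p0$T_m, dH_m = p0$dH_m)
  resid_fn <- function(par) {
    pp <- as.list(par); pp$dCp <- dCp
    model_cd(T, pp) - v
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  converged <- !is.null(fit) && fit$info %in% 1:4 && !no_transition
  par <- if (is.null(fit)) par0 else setNames(as.numeric(fit$par), names(par0))
  params <- as.list(par); params$dCp <- dCp
  fitted_v <- model_cd(T, params)
  rmsd <- sqrt(mean((fitted_v - v)^2))

  se <- rep(NA_real_, 6)
  if (!is.null(fit)) {
    # linearized covariance s^2 (J'J)^-1, inverted on a scaled system so
    # the huge spread in parameter magnitudes cannot break the solve
    JtJ <- fit$hessian
    s2 <- sum(fit$fvec^2) / max(1, length(T) - 6)
    d <- sqrt(pmax(diag(JtJ), 1e-300))
    Js <- JtJ / tcrossprod(d)
    inv <- tryCatch(solve(Js), error = function(e) {
      sv <- svd(Js)
      keep <- sv$d > 1e-12 * max(sv$d)
      sv$v %*% (ifelse(keep, 1 / sv$d, 0) * t(sv$u))
    })
    se <- sqrt(pmax(diag(inv) / d^2 * s2, 0))
  }
  dg <- function(TC) delta_g(TC + 273.15, params)
  structure(list(
    params = params, std_errors = setNames(se, names(par0)),
    curve = curve, fitted = fitted_v, rmsd = rmsd,
    dG_25C = dg(25), dG_37C = dg(37),
    converged = converged, no_transition = no_transition,
    init = p0), class = "thermal_fit")
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat(sprintf(paste0("<thermal_fit> T_m = %.2f K (%.2f C), dH_m = %.3g ",
                     "kJ/mol, dCp = %.3g kJ/(mol K)%s\n"),
              x$params$T_m, x$params$T_m - 273.15, x$params$dH_m / 1000,
              x$params$dCp / 1000,
              if (x$converged) "" else " [not converged]"))
  cat(sprintf("  dG(25C) = %.3g kJ/mol, dG(37C) = %.3g kJ/mol, RMSD = %.4g\n",
              x$dG_25C / 1000, x$dG_37C / 1000, x$rmsd))
  invisible(x)
}

#' Tidy the fitted thermal parameters
#'
#' @param x A `thermal_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error` (the fixed `dCp`
#'   appears with `NA` standard error).
#' @export
tidy.thermal_fit <- function(x, ...) {
  terms <- c("A_N", "m_N", "A_D", "m_D", "T_m", "dH_m", "dCp")
  tibble(term = terms,
         estimate = vapply(terms, function(t) x$params[[t]], 0.0),
         std_error = c(x$std_errors, dCp = NA_real_))
}

#' One-row summary of a thermal fit
#'
#' @param x A `thermal_fit`.
#' @param ... Unused.
#' @return Tibble with `T_m`, `dH_m`, `dG_25C`, `dG_37C`, `rmsd`,
#'   `converged`.
#' @export
glance.thermal_fit <- function(x, ...) {
  tibble(T_m = x$params$T_m, dH_m = x$params$dH_m, dG_25C = x$dG_25C,
         dG_37C = x$dG_37C, rmsd = x$rmsd, converged = x$converged)
}

#' Plot a thermal denaturation fit
#'
#' @param object A `thermal_fit`.
#' @param ... Unused.
#' @return A ggplot of the data and fitted curve.
#' @export
autoplot.thermal_fit <- function(object, ...) {
  d <- tibble(temperature = object$curve$temperature,
              value = object$curve$value, fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(.data$temperature - 273.15)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.8,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red3") +
    ggplot2::labs(x = "temperature (°C)", y = "CD signal") +
    ggplot2::theme_minimal()
}
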