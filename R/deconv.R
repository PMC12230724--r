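#' Simplex-constrained linear least squares
#'
#' Solves `min ||A x - y||^2` subject to `x >= 0` and `sum(x) = 1` with an
#' exact active-set method (the equality constraint is kept inside every
#' KKT subproblem).  Rank-deficient systems are solved minimum-norm and
#' flagged.
#'
#' @param A Design matrix (rows = observations).
#' @param y Response vector.
#' @return List with `x` (the solution), `objective`
#'   (`0.5 * ||A x - y||^2`) and `rank_deficient`.
#' @export
simplex_lsq <- function(A, y) {
  A <- as.matrix(A)
  if (nrow(A) != length(y)) abort("nrow(A) must equal length(y)")
  cpp_simplex_ls(A, as.numeric(y))
}

#' Fit eight fractions against fixed basis spectra
#'
#' The linear special case of the deconvolution: `min ||B ss - cd||` over
#' the probability simplex, where `B` holds one basis spectrum per
#' component.
#'
#' @param exp A `cd_spectrum` in delta-epsilon units.
#' @param basis Either a tibble as returned by [basis_spectra()]
#'   (`wavelength` plus the eight component columns) or a
#'   constant-column `basis_matrix_set`.
#' @param range Optional wavelength interval `c(min, max)`.
#' @return An [ss_vector()] with attributes `objective` and
#'   `rank_deficient`.
#' @export
linear_fit <- function(exp, basis, range = NULL) {
  if (inherits(basis, "basis_matrix_set")) basis <- basis_spectra(basis)
  comps <- ss_components()
  if (!all(c("wavelength", comps) %in% names(basis)))
    abort("basis must have columns wavelength and the 8 component names")
  if (is.null(range))
    range <- c(max(min(exp$wavelength), min(basis$wavelength)),
               min(max(exp$wavelength), max(basis$wavelength)))
  keep_e <- exp$wavelength >= range[1] - 1e-9 & exp$wavelength <= range[2] + 1e-9
  e <- exp[keep_e, ]
  b <- basis[basis$wavelength >= range[1] - 1e-9 &
               basis$wavelength <= range[2] + 1e-9, ]
  if (nrow(e) != nrow(b) || max(abs(e$wavelength - b$wavelength)) > 1e-6)
    abort("experimental spectrum and basis must share the fit grid")
  A <- as.matrix(b[, comps])
  sol <- cpp_simplex_ls(A, e$value)
  out <- ss_vector(setNames(as.numeric(sol$x), comps), normalize = TRUE)
  attr(out, "objective") <- sol$objective
  attr(out, "rank_deficient") <- sol$rank_deficient
  out
}

# starts for the multi-start scheme: the 8 simplex vertices plus seeded
# flat-Dirichlet draws
deconv_starts <- function(n_starts, seed) {
  n_vertex <- min(8L, n_starts)
  S <- diag(8)[, seq_len(n_vertex), drop = FALSE]
  n_rand <- n_starts - n_vertex
  if (n_rand > 0) {
    R <- with_seed(seed, t(rdirichlet(n_rand, rep(1, 8))))
    S <- cbind(S, R)
  }
  S
}

#' Deconvolve a CD spectrum into eight secondary-structure fractions
#'
#' Solves the simplex-constrained inverse problem
#' `min 0.5 ||q(ss) - CD_exp||^2` with `q(ss)_lambda = ss' M_lambda ss`,
#' i.e. the model is quadratic in the composition, making the objective
#' quartic.  The solver alternates (a) forming the effective basis
#' `B[lambda, i] = (M_lambda ss)_i` at the current composition with (b) a
#' simplex-constrained linear solve, taking an exact line search along the
#' simplex segment so the true objective never increases; it is restarted
#' from the 8 simplex vertices plus seeded Dirichlet(1) draws and the best
#' start is kept (ties broken by lowest start index).
#'
#' @param exp A `cd_spectrum` in delta-epsilon units, already smoothed and
#'   regridded to the model's 1 nm grid.
#' @param m A `basis_matrix_set`.
#' @param range Optional wavelength interval `c(min, max)`; defaults to
#'   the overlap of spectrum and model.  Fit ranges of 175-250, 190-250
#'   and 200-250 nm are conventional; the lower limit is typically moved
#'   in 5 nm steps.
#' @param n_starts Number of optimizer starts (default 20).
#' @param seed Seed for the random starts (default 1; fixed so repeated
#'   calls are reproducible).
#' @param max_iter,tol Iteration cap and relative objective tolerance of
#'   the alternating scheme.
#' @param raw Optional un-smoothed spectrum used for the RMSD part of the
#'   fit quality (defaults to `exp`).
#' @return A `cd_deconv` object; see [tidy.cd_deconv()],
#'   [glance.cd_deconv()] and [autoplot.cd_deconv()].
#' @export
fit_secondary_structure <- function(exp, m, range = NULL, n_starts = 20,
                                    seed = 1, max_iter = 200, tol = 1e-10,
                                    raw = NULL) {
  if (cd_unit(exp) != "delta_epsilon")
    abort("spectrum must be in delta-epsilon units (see convert_cd_units)")
  wl <- m$wavelength
  if (is.null(range))
    range <- c(max(min(exp$wavelength), min(wl)),
               min(max(exp$wavelength), max(wl)))
  keep <- exp$wavelength >= range[1] - 1e-9 & exp$wavelength <= range[2] + 1e-9
  e <- exp[keep, ]
  idx <- match(round(e$wavelength), round(wl))
  if (any(is.na(idx)))
    abort("coverage error: spectrum wavelengths missing from the model grid")
  if (any(!is.finite(e$value)))
    abort("data error: non-finite CD values on the fit range")
  Msym <- m$M[, , idx, drop = FALSE]
  for (l in seq_along(idx)) Msym[, , l] <- (Msym[, , l] + t(Msym[, , l])) / 2
  starts <- deconv_starts(n_starts, seed)
  fit <- cpp_quadratic_fit(Msym, e$value, starts, as.integer(max_iter), tol)
  ss <- ss_vector(setNames(as.numeric(fit$x), ss_components()),
                  normalize = TRUE)
  fitted <- evaluate_model(m, ss, range = c(min(e$wavelength),
                                            max(e$wavelength)))
  raw <- raw %||% exp
  quality <- fit_quality(raw, exp, fitted,
                         range = c(min(e$wavelength), max(e$wavelength)))
  structure(list(ss = ss, fitted = fitted, exp = e, raw = raw,
                 quality = quality, range = range,
                 converged = isTRUE(fit$converged),
                 n_starts_used = ncol(starts), objective = fit$objective,
                 best_start = fit$start),
            class = "cd_deconv")
}

#' @export
print.cd_deconv <- function(x, ...) {
  cat(sprintf("<cd_deconv> fit on %g-%g nm, RMSD %.4g, NRMSD %.4g%s\n",
              x$range[1], x$range[2], x$quality$rmsd, x$quality$nrmsd,
              if (x$converged) "" else " (not converged)"))
  print(round(unclass(x$ss), 4))
  invisible(x)
}

#' Tidy the fractions of a deconvolution
#'
#' @param x A `cd_deconv`.
#' @param ... Unused.
#' @return Tibble with columns `component` and `fraction` (eight rows).
#' @export
tidy.cd_deconv <- function(x, ...) {
  tibble(component = ss_components(), fraction = as.numeric(x$ss))
}

#' One-row summary of a deconvolution
#'
#' @param x A `cd_deconv`.
#' @param ... Unused.
#' @return Tibble with fit-quality metrics and convergence info.
#' @export
glance.cd_deconv <- function(x, ...) {
  tibble(rmsd = x$quality$rmsd, nrmsd = x$quality$nrmsd,
         objective = x$objective, converged = x$converged,
         n_starts = x$n_starts_used)
}

#' Plot a deconvolution fit
#'
#' @param object A `cd_deconv`.
#' @param ... Unused.
#' @return A ggplot of the experimental and fitted spectra.
#' @export
autoplot.cd_deconv <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble(wavelength = object$exp$wavelength, value = object$exp$value,
           which = "experimental"),
    tibble(wavelength = object$fitted$wavelength, value = object$fitted$value,
           which = "fitted"))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavelength, .data$value,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)",
                  y = expression(Delta * epsilon ~ (M^-1 ~ cm^-1)),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
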