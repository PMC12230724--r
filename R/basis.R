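#' Construct a basis-matrix set
#'
#' The spectral model is quadratic in the secondary-structure composition:
#' at each wavelength the CD signal is `ss' M ss`, where `M` is an 8 x 8
#' basis matrix.  A constant-column set, in which every column `i` of `M`
#' equals a constant `b_i` times the ones vector, collapses to the classic
#' linear model `CD = sum_i b_i ss_i` (because the fractions sum to one).
#'
#' @param wavelength Integer-valued wavelength grid (nm) at 1 nm pitch,
#'   contiguous.
#' @param M Numeric array of dimension `c(8, 8, length(wavelength))`.
#' @param provenance One of `"trained"`, `"loaded"`, `"constant-column"`,
#'   `"synthetic"`.
#' @return A `basis_matrix_set`.
#' @export
basis_matrix_set <- function(wavelength, M,
                             provenance = c("trained", "loaded",
                                            "constant-column", "synthetic")) {
  provenance <- match.arg(provenance)
  wavelength <- as.numeric(wavelength)
  if (length(wavelength) < 2 || any(abs(diff(wavelength) - 1) > 1e-9))
    abort("basis-matrix wavelength grid must be contiguous at 1 nm pitch")
  if (!is.array(M) || !all(dim(M) == c(8, 8, length(wavelength))))
    abort("M must be an 8 x 8 x n_wavelength array")
  if (any(!is.finite(M))) abort("basis matrices must be finite")
  structure(list(wavelength = wavelength, M = M, provenance = provenance),
            class = "basis_matrix_set")
}

#' @export
print.basis_matrix_set <- function(x, ...) {
  cat(sprintf("<basis_matrix_set> %g-%g nm (%d wavelengths), provenance: %s\n",
              min(x$wavelength), max(x$wavelength), length(x$wavelength),
              x$provenance))
  invisible(x)
}

#' Build a constant-column basis set from eight basis spectra
#'
#' @param wavelength Wavelength grid at 1 nm pitch.
#' @param B 8 x n_wavelength matrix of basis-spectrum values (rows in
#'   canonical component order).
#' @return A `basis_matrix_set` with provenance `"constant-column"`.
#' @export
constant_basis_set <- function(wavelength, B) {
  L <- length(wavelength)
  if (!all(dim(B) == c(8, L))) abort("B must be 8 x n_wavelength")
  M <- array(0, dim = c(8, 8, L))
  ones <- rep(1, 8)
  for (l in seq_len(L)) M[, , l] <- outer(ones, B[, l])
  basis_matrix_set(wavelength, M, provenance = "constant-column")
}

#' Extract the basis spectra of a constant-column set
#'
#' For a constant-column set, column `i` of every matrix is `b_i` times
#' the ones vector, so the column means recover the basis spectra
#' exactly; for a trained set this returns the column means, i.e. the
#' effective basis at the uniform composition.
#'
#' @param m A `basis_matrix_set`.
#' @return Tibble with `wavelength` and one column per component.
#' @export
basis_spectra <- function(m) {
  L <- length(m$wavelength)
  B <- vapply(seq_len(L), function(l) colMeans(m$M[, , l]), numeric(8))
  out <- as_tibble(t(B), .name_repair = "minimal")
  names(out) <- ss_components()
  dplyr::bind_cols(tibble(wavelength = m$wavelength), out)
}

#' Evaluate the quadratic spectral model
#'
#' Computes `CD(lambda) = ss' M_lambda ss` on the requested range.  Only
#' the symmetric part of each matrix affects the quadratic form.
#'
#' @param m A `basis_matrix_set`.
#' @param ss An [ss_vector()] (or numeric length 8 on the simplex).
#' @param range Optional `c(min, max)` wavelength interval; default full
#'   grid.
#' @return A `cd_spectrum` in delta-epsilon units.
#' @export
evaluate_model <- function(m, ss, range = NULL) {
  ss <- ss_vector(ss)
  wl <- m$wavelength
  if (is.null(range)) range <- c(min(wl), max(wl))
  if (range[1] < min(wl) - 1e-9 || range[2] > max(wl) + 1e-9)
    abort("coverage error: requested range extends beyond the model grid")
  idx <- which(wl >= range[1] - 1e-9 & wl <= range[2] + 1e-9)
  vals <- vapply(idx, function(l) {
    as.numeric(ss %*% m$M[, , l] %*% ss)
  }, 0.0)
  cd_spectrum(wl[idx], vals, unit = "delta_epsilon")
}

#' Write a basis-matrix set to delimited text
#'
#' One row per wavelength: the wavelength followed by the 64 matrix
#' entries in row-major order.  Full double precision is used so models
#' round-trip exactly.
#'
#' @param m A `basis_matrix_set`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_basis_matrix_set <- function(m, file) {
  header <- paste(c("wavelength",
                    paste0("m", rep(1:8, each = 8), rep(1:8, times = 8))),
                  collapse = "\t")
  rows <- vapply(seq_along(m$wavelength), function(l) {
    paste(c(fmt_num(m$wavelength[l]), fmt_num(as.vector(t(m$M[, , l])))),
          collapse = "\t")
  }, "")
  writeLines(c(header, rows), file)
  invisible(file)
}

#' Read a basis-matrix set written by [write_basis_matrix_set()]
#'
#' @param file Path to the model file.
#' @return A `basis_matrix_set` with provenance `"loaded"`.
#' @export
read_basis_matrix_set <- function(file) {
  d <- read.table(file, header = TRUE, sep = "\t")
  if (ncol(d) != 65) abort("model file must have 65 columns (wavelength + 64)")
  L <- nrow(d)
  M <- array(0, dim = c(8, 8, L))
  for (l in seq_len(L)) {
    M[, , l] <- matrix(as.numeric(d[l, -1]), nrow = 8, byrow = TRUE)
  }
  basis_matrix_set(d[[1]], M, provenance = "loaded")
}
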