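#' Construct a CD spectrum
#'
#' A CD spectrum is a tibble with columns `wavelength` (nm) and `value`,
#' carrying its unit and optional normalization metadata as attributes.
#' Wavelengths must be strictly monotone on input and are stored ascending;
#' the wavelength pitch must be one of 0.1, 0.2, 0.5 or 1 nm (tolerance
#' 1e-6 nm).
#'
#' @param wavelength Numeric vector of wavelengths in nm.
#' @param value Numeric vector of CD values.
#' @param unit One of `"delta_epsilon"` (M^-1 cm^-1, per mean residue),
#'   `"mre"` (mean residue ellipticity, deg cm^2 dmol^-1) or `"mdeg"`
#'   (measured ellipticity).
#' @param concentration Molar protein concentration (mol/L); required to
#'   normalize `mdeg` data.
#' @param pathlength Cuvette pathlength in cm; required for `mdeg`.
#' @param n_residues Number of residues; required for `mdeg`.
#' @param check_pitch Validate the pitch against the allowed set.
#' @return A `cd_spectrum` tibble.
#' @export
cd_spectrum <- function(wavelength, value,
                        unit = c("delta_epsilon", "mre", "mdeg"),
                        concentration = NULL, pathlength = NULL,
                        n_residues = NULL, check_pitch = TRUE) {
  unit <- match.arg(unit)
  if (length(wavelength) != length(value))
    abort("wavelength and value must have equal length")
  if (any(!is.finite(wavelength))) abort("non-finite wavelengths")
  d <- diff(wavelength)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0)))
    abort("wavelengths must be strictly monotone")
  ord <- order(wavelength)
  wavelength <- wavelength[ord]; value <- value[ord]
  if (check_pitch && length(wavelength) > 1) {
    p <- spectrum_pitch(wavelength)
    if (is.na(p))
      abort("wavelength pitch must be uniform and one of 0.1, 0.2, 0.5, 1 nm")
  }
  out <- tibble(wavelength = as.numeric(wavelength), value = as.numeric(value))
  class(out) <- c("cd_spectrum", class(out))
  attr(out, "unit") <- unit
  attr(out, "meta") <- list(concentration = concentration,
                            pathlength = pathlength,
                            n_residues = n_residues)
  out
}

#' @export
print.cd_spectrum <- function(x, ...) {
  cat(sprintf("<cd_spectrum> %d points, %.6g-%.6g nm, unit = %s\n",
              nrow(x), min(x$wavelength), max(x$wavelength), cd_unit(x)))
  NextMethod()
}

#' Spectrum unit tag
#' @param s A `cd_spectrum`.
#' @return The unit string.
#' @export
cd_unit <- function(s) attr(s, "unit") %||% "delta_epsilon"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect the wavelength pitch of a grid
#'
#' @param wavelength Sorted numeric wavelength grid.
#' @param tol Tolerance in nm.
#' @return The pitch (0.1, 0.2, 0.5 or 1) or `NA` if the grid is
#'   non-uniform or its pitch is outside the allowed set.
#' @export
spectrum_pitch <- function(wavelength, tol = 1e-6) {
  d <- diff(sort(wavelength))
  if (length(d) == 0) return(NA_real_)
  if (max(d) - min(d) > 2 * tol) return(NA_real_)
  allowed <- c(0.1, 0.2, 0.5, 1)
  p <- allowed[abs(allowed - mean(d)) <= tol]
  if (length(p) != 1) NA_real_ else p
}

#' Read a two-column CD spectrum from text
#'
#' Accepts whitespace- or comma-delimited text with any number of leading
#' header lines (skipped automatically: a header line is any line whose
#' first two fields do not both parse as numbers).  The first numeric
#' column is taken as wavelength (nm), the second as the CD value.
#'
#' @param file Path or connection.
#' @inheritParams cd_spectrum
#' @return A `cd_spectrum`.
#' @export
read_cd_spectrum <- function(file, unit = c("delta_epsilon", "mre", "mdeg"),
                             concentration = NULL, pathlength = NULL,
                             n_residues = NULL) {
  unit <- match.arg(unit)
  lines <- readLines(file)
  lines <- trimws(lines)
  parse_line <- function(l) {
    f <- strsplit(l, "[,;[:space:]]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 2) return(NULL)
    suppressWarnings(vals <- as.numeric(f[1:2]))
    if (any(is.na(vals))) return(NA) else vals
  }
  parsed <- lapply(lines, function(l) if (nzchar(l)) parse_line(l) else NULL)
  numeric_row <- vapply(parsed, function(p) is.numeric(p) && length(p) == 2, TRUE)
  started <- cumsum(numeric_row) > 0
  bad <- which(started & !numeric_row & nzchar(lines))
  if (length(bad) > 0)
    abort(sprintf("non-numeric data at line %d: '%s'", bad[1], lines[bad[1]]))
  rows <- parsed[numeric_row]
  if (length(rows) < 10)
    abort(sprintf("insufficient data: %d points found, at least 10 required",
                  length(rows)))
  m <- do.call(rbind, rows)
  cd_spectrum(m[, 1], m[, 2], unit = unit, concentration = concentration,
              pathlength = pathlength, n_residues = n_residues)
}

#' Write a CD spectrum as two-column text
#'
#' Values are written with 17 significant digits so that
#' `read_cd_spectrum(write_cd_spectrum(s))` round-trips bit-identically.
#'
#' @param s A `cd_spectrum`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_cd_spectrum <- function(s, file) {
  writeLines(paste(fmt_num(s$wavelength), fmt_num(s$value), sep = "\t"), file)
  invisible(file)
}

# MRE = MRE_FACTOR * delta_epsilon; mdeg = delta_epsilon * MDEG_FACTOR*c*l*N
MRE_FACTOR <- 3298
MDEG_FACTOR <- 32980

#' Convert CD spectrum units
#'
#' Fixed conversion constants: `[theta]_MRE = 3298 * delta_epsilon` and
#' `theta_mdeg = 32980 * c(M) * l(cm) * N_res * delta_epsilon`.  Conversions
#' are exactly invertible.
#'
#' @param s A `cd_spectrum`.
#' @param to Target unit tag.
#' @return A `cd_spectrum` in the target unit.
#' @export
convert_cd_units <- function(s, to = c("delta_epsilon", "mre", "mdeg")) {
  to <- match.arg(to)
  from <- cd_unit(s)
  meta <- attr(s, "meta") %||% list()
  if (from == to) return(s)
  needs_meta <- "mdeg" %in% c(from, to)
  if (needs_meta) {
    for (f in c("concentration", "pathlength", "n_residues")) {
      v <- meta[[f]]
      if (is.null(v))
        abort(sprintf("normalization error: `%s` required to convert %s",
                      f, "mdeg data"))
      if (!is.numeric(v) || v <= 0)
        abort(sprintf("`%s` must be positive", f))
    }
  }
  # convert to delta_epsilon first
  de <- switch(from,
    delta_epsilon = s$value,
    mre = s$value / MRE_FACTOR,
    mdeg = s$value / (MDEG_FACTOR * meta$concentration * meta$pathlength *
                        meta$n_residues))
  out_val <- switch(to,
    delta_epsilon = de,
    mre = de * MRE_FACTOR,
    mdeg = de * (MDEG_FACTOR * meta$concentration * meta$pathlength *
                   meta$n_residues))
  cd_spectrum(s$wavelength, out_val, unit = to,
              concentration = meta$concentration, pathlength = meta$pathlength,
              n_residues = meta$n_residues, check_pitch = FALSE)
}

#' Smooth a CD spectrum by windowed averaging
#'
#' Each output value is the unweighted mean of the input points lying
#' strictly inside the window around its wavelength (points exactly on
#' the window edge are excluded, so data already at a pitch of half the
#' window pass through unchanged).  The grid is unchanged; edge points
#' average over the truncated window.
#'
#' @param s A `cd_spectrum`.
#' @param window_nm Full window width in nm (default 2).
#' @return Smoothed `cd_spectrum` on the same grid.
#' @export
cd_smooth <- function(s, window_nm = 2) {
  stopifnot_scalar_pos(window_nm, "window_nm")
  w <- s$wavelength
  half <- window_nm / 2 - 1e-9
  sm <- vapply(w, function(wi) mean(s$value[abs(w - wi) <= half]), 0.0)
  out <- s
  out$value <- sm
  out
}

#' Regrid a CD spectrum by bin averaging
#'
#' Output nodes sit at integer multiples of the target pitch spanning the
#' input range; each node value is the mean of the input points within half
#' a pitch of the node.  Bin averaging (not interpolation) is used.
#'
#' @param s A `cd_spectrum`.
#' @param pitch_nm Target pitch in nm (default 1).
#' @return A `cd_spectrum` at the target pitch.
#' @export
cd_regrid <- function(s, pitch_nm = 1) {
  stopifnot_scalar_pos(pitch_nm, "pitch_nm")
  p_in <- spectrum_pitch(s$wavelength)
  if (!is.na(p_in) && p_in > pitch_nm + 1e-9)
    abort("upsampling error: input pitch is coarser than the requested pitch")
  w <- s$wavelength
  nodes <- seq(ceiling(min(w) / pitch_nm - 1e-9) * pitch_nm,
               floor(max(w) / pitch_nm + 1e-9) * pitch_nm, by = pitch_nm)
  half <- pitch_nm / 2 + 1e-9
  vals <- vapply(nodes, function(n) mean(s$value[abs(w - n) <= half]), 0.0)
  meta <- attr(s, "meta") %||% list()
  cd_spectrum(nodes, vals, unit = cd_unit(s),
              concentration = meta$concentration,
              pathlength = meta$pathlength, n_residues = meta$n_residues)
}

#' Fit-quality metrics for a deconvolution
#'
#' RMSD is computed between the raw experimental spectrum and the fitted
#' spectrum; NRMSD between the smoothed experimental spectrum and the
#' fitted spectrum, normalized by the smoothed spectrum's norm.  Keeping
#' RMSD on the raw data preserves its sensitivity to noise while NRMSD
#' reflects the quality of the structural fit itself.
#'
#' @param exp_raw,exp_smoothed,fitted `cd_spectrum` objects sharing the fit
#'   grid on `range`.
#' @param range Optional `c(min, max)` wavelength interval (nm); default is
#'   the common range.
#' @return A one-row tibble with columns `rmsd` and `nrmsd`.
#' @export
fit_quality <- function(exp_raw, exp_smoothed, fitted, range = NULL) {
  grids <- list(exp_raw$wavelength, exp_smoothed$wavelength, fitted$wavelength)
  if (is.null(range)) {
    range <- c(max(vapply(grids, min, 0.0)), min(vapply(grids, max, 0.0)))
  }
  pick <- function(s) {
    keep <- s$wavelength >= range[1] - 1e-9 & s$wavelength <= range[2] + 1e-9
    s[keep, , drop = FALSE]
  }
  a <- pick(exp_raw); b <- pick(exp_smoothed); f <- pick(fitted)
  if (nrow(a) != nrow(f) || nrow(b) != nrow(f) ||
      max(abs(a$wavelength - f$wavelength)) > 1e-6 ||
      max(abs(b$wavelength - f$wavelength)) > 1e-6)
    abort("spectra must share the fit grid on the requested range")
  rmsd <- sqrt(mean((a$value - f$value)^2))
  denom <- sum(b$value^2)
  if (denom == 0) abort("NRMSD undefined: smoothed spectrum is all zero")
  nrmsd <- sqrt(sum((b$value - f$value)^2) / denom)
  tibble(rmsd = rmsd, nrmsd = nrmsd)
}

#' Amplitude-scaling scan
#'
#' Re-fits a spectrum after multiplying it by trial scale factors spaced
#' log-uniformly between 0.5x and 2x a center value, and reports the factor
#' minimizing NRMSD.  Useful to reveal concentration or normalization
#' errors: a best factor far from 1 on a normalized spectrum suggests the
#' amplitude is off.
#'
#' @param s A `cd_spectrum`.
#' @param deconvolver Callback `function(spectrum) -> nrmsd` (a single
#'   number, or an object whose `glance()` has an `nrmsd` column).
#' @param center Center of the scan (default 1).
#' @param n_steps Number of factors (default 31); `n_steps = 1` evaluates
#'   the center only.
#' @return Tibble with columns `factor`, `nrmsd`, `ok`; the best factor is
#'   attached as attribute `"best_factor"` (ties resolved toward the factor
#'   closest to `center`).
#' @export
scale_scan <- function(s, deconvolver, center = 1, n_steps = 31) {
  stopifnot_scalar_pos(center, "center")
  factors <- if (n_steps == 1) center else
    exp(seq(log(0.5 * center), log(2 * center), length.out = n_steps))
  get_nrmsd <- function(res) {
    if (is.numeric(res) && length(res) == 1) return(as.numeric(res))
    g <- glance(res)
    as.numeric(g$nrmsd[1])
  }
  rows <- purrr::map(factors, function(f) {
    scaled <- s
    scaled$value <- s$value * f
    res <- tryCatch(get_nrmsd(deconvolver(scaled)), error = function(e) NA_real_)
    tibble(factor = f, nrmsd = res, ok = is.finite(res))
  })
  out <- dplyr::bind_rows(rows)
  okrows <- out[out$ok, ]
  best <- NA_real_
  if (nrow(okrows) > 0) {
    mn <- min(okrows$nrmsd)
    cand <- okrows$factor[okrows$nrmsd <= mn + 1e-15]
    best <- cand[which.min(abs(log(cand / center)))]
  }
  attr(out, "best_factor") <- best
  out
}

#' Check spectrum amplitude plausibility
#'
#' Warns when the maximum |CD| of a delta-epsilon spectrum falls outside a
#' plausible band, which usually indicates a wrong unit choice or a
#' normalization error.
#'
#' @param s A `cd_spectrum` in delta-epsilon units.
#' @param low,high Plausibility band for max |CD| (defaults 0.1 and 40).
#' @return `TRUE` (normal) or `FALSE` (abnormal, with a warning), invisibly.
#' @export
check_cd_amplitude <- function(s, low = 0.1, high = 40) {
  m <- max(abs(s$value))
  ok <- m >= low && m <= high
  if (!ok)
    warn(sprintf(paste0("abnormal spectral amplitude: max |CD| = %.4g is ",
                        "outside [%g, %g]; check units and normalization"),
                 m, low, high))
  invisible(ok)
}
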