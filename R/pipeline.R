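#' Single-spectrum analysis pipeline
#'
#' The full processing chain for one spectrum: read (if a path), convert
#' to delta-epsilon, smooth with a 2 nm window on the native grid, regrid
#' to 1 nm by bin averaging, deconvolve against the model, and report the
#' eight fractions with grouped sums and fit quality.  RMSD is computed
#' against the un-smoothed (regridded) data, NRMSD against the smoothed
#' data.
#'
#' @param x A `cd_spectrum` or a path to a two-column text file.
#' @param model A `basis_matrix_set` or path to a model file.
#' @param unit,concentration,pathlength,n_residues Input normalization
#'   (see [read_cd_spectrum()]).
#' @param range Optional fit range `c(min, max)` nm.
#' @param smooth_window Smoothing window (nm).
#' @param n_starts,seed Optimizer settings (see
#'   [fit_secondary_structure()]).
#' @param out Optional output directory: writes `fractions.csv`,
#'   `spectra.csv` (wavelength_nm, cd_exp, cd_smoothed, cd_fitted) and a
#'   `provenance.json` record.
#' @return A list with `fit` (`cd_deconv`), `fractions`, `groups`,
#'   `quality` tibbles and `warnings`.
#' @export
run_single <- function(x, model, unit = "delta_epsilon",
                       concentration = NULL, pathlength = NULL,
                       n_residues = NULL, range = NULL, smooth_window = 2,
                       n_starts = 20, seed = 1, out = NULL) {
  call_opts <- list(unit = unit, range = range,
                    smooth_window = smooth_window, n_starts = n_starts,
                    seed = seed)
  if (is.character(model)) model <- read_basis_matrix_set(model)
  s <- if (is.character(x)) {
    read_cd_spectrum(x, unit = unit, concentration = concentration,
                     pathlength = pathlength, n_residues = n_residues)
  } else x
  warnings <- character()
  s <- convert_cd_units(s, "delta_epsilon")
  withCallingHandlers(
    check_cd_amplitude(s),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  raw1 <- cd_regrid(s, 1)
  smoothed <- cd_regrid(cd_smooth(s, smooth_window), 1)
  fit <- fit_secondary_structure(smoothed, model, range = range,
                                 n_starts = n_starts, seed = seed,
                                 raw = raw1)
  fractions <- tidy(fit)
  groups <- ss_groups(fit$ss)
  quality <- glance(fit)
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.table(dplyr::bind_rows(
      fractions,
      setNames(groups, names(fractions))),
      file.path(out, "fractions.csv"), sep = ",", row.names = FALSE,
      quote = FALSE)
    keep <- raw1$wavelength >= min(fit$fitted$wavelength) &
      raw1$wavelength <= max(fit$fitted$wavelength)
    spec_tbl <- tibble(wavelength_nm = raw1$wavelength[keep],
                       cd_exp = raw1$value[keep],
                       cd_smoothed = smoothed$value[keep],
                       cd_fitted = fit$fitted$value)
    write.table(spec_tbl, file.path(out, "spectra.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    write_provenance(file.path(out, "provenance.json"), "single",
                     input = if (is.character(x)) x else "in-memory",
                     options = call_opts)
  }
  list(fit = fit, fractions = fractions, groups = groups,
       quality = quality, warnings = warnings)
}

#' Multi-spectrum analysis pipeline
#'
#' Analyzes a series of spectra sharing a wavelength column (wide-format
#' table: wavelength first, one column per spectrum), applying the same
#' processing chain as [run_single()] to each, and returns a long tidy
#' table with one row per (spectrum, component).
#'
#' @param x Path to a delimited multi-column file, or a data frame whose
#'   first column is wavelength.
#' @param model A `basis_matrix_set` or model path.
#' @inheritParams run_single
#' @return A list with `results` (long tibble: spectrum, component,
#'   fraction), `quality` (one row per spectrum) and `fits`.
#' @export
run_multi <- function(x, model, unit = "delta_epsilon", range = NULL,
                      smooth_window = 2, n_starts = 20, seed = 1,
                      out = NULL) {
  if (is.character(model)) model <- read_basis_matrix_set(model)
  d <- if (is.character(x)) {
    lines <- trimws(readLines(x))
    lines <- lines[nzchar(lines)]
    fields <- lapply(strsplit(lines, "[,;[:space:]]+"),
                     function(f) suppressWarnings(as.numeric(f[nzchar(f)])))
    numeric_row <- vapply(fields, function(f)
      length(f) >= 2 && !anyNA(f), TRUE)
    started <- cumsum(numeric_row) > 0
    if (any(started & !numeric_row))
      abort("format error: non-numeric row inside the data block")
    rows <- fields[numeric_row]
    if (length(rows) < 10) abort("format error: fewer than 10 data rows")
    if (length(unique(lengths(rows))) != 1)
      abort("format error: ragged columns in multi-spectrum input")
    as.data.frame(do.call(rbind, rows))
  } else as.data.frame(x)
  if (any(is.na(d))) abort("format error: missing values in input")
  n_spec <- ncol(d) - 1
  if (n_spec < 1) abort("format error: need at least one spectrum column")
  names(d) <- c("wavelength", paste0("s", seq_len(n_spec)))
  fits <- purrr::map(seq_len(n_spec), function(j) {
    s <- cd_spectrum(d$wavelength, d[[j + 1]], unit = unit)
    run_single(s, model, range = range, smooth_window = smooth_window,
               n_starts = n_starts, seed = seed)
  })
  results <- purrr::imap_dfr(fits, function(f, j) {
    dplyr::mutate(f$fractions, spectrum = paste0("s", j), .before = 1)
  })
  quality <- purrr::imap_dfr(fits, function(f, j) {
    dplyr::mutate(f$quality, spectrum = paste0("s", j), .before = 1)
  })
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    write.table(results, file.path(out, "results.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
    write_provenance(file.path(out, "provenance.json"), "multi",
                     input = if (is.character(x)) x else "in-memory",
                     options = list(unit = unit, range = range,
                                    smooth_window = smooth_window,
                                    n_starts = n_starts, seed = seed))
  }
  list(results = results, quality = quality, fits = purrr::map(fits, "fit"))
}

# machine-readable provenance record for a pipeline run
write_provenance <- function(path, subcommand, input, options) {
  rec <- list(tool = "cdsk",
              version = as.character(utils::packageVersion("cdsk")),
              subcommand = subcommand, input = input, options = options)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
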