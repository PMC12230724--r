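#' Load an extinction-coefficient table
#'
#' Tables ship as versioned plain-text constants files transcribed from
#' the additive far-UV schemes of Kuipers & Gruppen (2007; 214 nm) and
#' Anthis & Clore (2013; 205 nm): per-residue contributions, a peptide
#' bond term applied `L - 1` times, and a net per-disulfide adjustment.
#'
#' @param wavelength 214 or 205, or a path to a custom table CSV with
#'   columns `term`, `epsilon`.
#' @return An `epsilon_table` (named numeric vector with attribute
#'   `source`).
#' @export
load_epsilon_table <- function(wavelength = 214) {
  path <- if (is.character(wavelength)) {
    wavelength
  } else {
    system.file("extdata", sprintf("epsilon_%dnm.csv", wavelength),
                package = "cdsk")
  }
  if (!nzchar(path) || !file.exists(path))
    abort("no extinction table for that wavelength (use 214 or 205)")
  d <- read.table(path, header = TRUE, sep = ",", comment.char = "#",
                  stringsAsFactors = FALSE)
  tab <- setNames(as.numeric(d$epsilon), d$term)
  need <- c(strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]],
            "peptide_bond", "disulfide_bond")
  if (!all(need %in% names(tab)))
    abort("extinction table is missing required terms")
  if (any(tab[setdiff(need, "disulfide_bond")] < 0))
    abort("residue and bond contributions must be nonnegative")
  structure(tab, class = "epsilon_table", source = path)
}

#' Molar extinction coefficient of a peptide at 214 or 205 nm
#'
#' Additive scheme: the sum of per-residue contributions, one peptide-bond
#' term per bond (`L - 1` for a chain of length `L`), and a net adjustment
#' per disulfide bridge.
#'
#' @param sequence One-letter amino-acid sequence (standard 20 letters).
#' @param wavelength 214 (default) or 205 nm.
#' @param n_disulfides Number of disulfide bridges (at most
#'   `floor(n_cysteines / 2)`).
#' @param table Optional `epsilon_table` overriding the shipped one.
#' @return Extinction coefficient in M^-1 cm^-1.
#' @export
epsilon_at <- function(sequence, wavelength = 214, n_disulfides = 0,
                       table = NULL) {
  table <- table %||% load_epsilon_table(wavelength)
  seq <- toupper(gsub("[[:space:]]", "", sequence))
  if (nchar(seq) == 0) return(0)
  letters1 <- strsplit(seq, "")[[1]]
  known <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
  bad <- which(!(letters1 %in% known))
  if (length(bad) > 0)
    abort(sprintf("unknown residue letter(s) %s at position(s) %s",
                  paste(unique(letters1[bad]), collapse = ", "),
                  paste(bad, collapse = ", ")))
  n_cys <- sum(letters1 == "C")
  if (n_disulfides < 0 || n_disulfides > floor(n_cys / 2))
    abort("n_disulfides must be between 0 and floor(n_cysteines/2)")
  sum(table[letters1]) + (length(letters1) - 1) * table[["peptide_bond"]] +
    n_disulfides * table[["disulfide_bond"]]
}

#' Extinction coefficients for every record of a FASTA file
#'
#' @param file FASTA path.
#' @param wavelength,n_disulfides,table As in [epsilon_at()].
#' @return Tibble with `id`, `length`, `epsilon`.
#' @export
epsilon_fasta <- function(file, wavelength = 214, n_disulfides = 0,
                          table = NULL) {
  lines <- readLines(file)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) abort("not a FASTA file: no '>' header found")
  id <- sub("^>\\s*(\\S+).*", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(seq_along(id), function(i)
    paste(lines[!hdr & grp == i], collapse = ""), "")
  tibble(id = id, length = nchar(gsub("[[:space:]]", "", seqs)),
         epsilon = vapply(seqs, epsilon_at, 0.0,
                          wavelength = wavelength,
                          n_disulfides = n_disulfides, table = table,
                          USE.NAMES = FALSE))
}
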