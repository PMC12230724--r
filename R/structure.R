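#' Read a protein structure into a backbone model
#'
#' Parses PDB or mmCIF files, keeps the first model, selects altloc `'A'`
#' (or blank), excludes hetero residues, and retains residues with a
#' complete backbone (N, CA, C, O); incomplete residues are dropped with a
#' count recorded in the `n_dropped` attribute.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"` or `NULL` to infer from the extension.
#' @return A `structure_model`: one row per residue with `chain`,
#'   `resno`, `resid` and backbone coordinate columns `N_x` ... `O_z`
#'   (Angstrom).
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  atoms <- if (format == "mmcif") parse_cif_atoms(path) else
    parse_pdb_atoms(path)
  if (nrow(atoms) == 0) abort("content error: no protein atoms found")
  atoms_to_model(atoms)
}

parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
                  error = function(e)
                    abort(sprintf("content error: %s", conditionMessage(e))))
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  alt_ok <- is.na(a$alt) | a$alt %in% c("", "A")
  a <- a[alt_ok, , drop = FALSE]
  tibble(chain = ifelse(is.na(a$chain), "A", a$chain),
         resno = a$resno, resid = a$resid,
         atom = a$elety, x = a$x, y = a$y, z = a$z)
}

# minimal mmCIF atom_site reader (standard dialect); handles the first
# model, altloc and hetero filtering like the PDB path
parse_cif_atoms <- function(path) {
  lines <- readLines(path)
  loop_starts <- grep("^\\s*loop_", lines)
  for (ls in loop_starts) {
    k <- ls + 1
    fields <- character()
    while (k <= length(lines) && grepl("^\\s*_", lines[k])) {
      fields <- c(fields, trimws(lines[k]))
      k <- k + 1
    }
    if (!any(grepl("^_atom_site\\.", fields))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (k <= length(lines)) {
      l <- trimws(lines[k])
      if (l == "" || grepl("^(#|loop_|_|data_)", l)) break
      rows[[length(rows) + 1]] <- scan(text = l, what = "character",
                                       quiet = TRUE)
      k <- k + 1
    }
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    pick <- function(...) {
      for (nm in c(...)) if (nm %in% fields) return(m[, nm])
      rep(NA_character_, nrow(m))
    }
    grp <- pick("group_PDB")
    mod <- pick("pdbx_PDB_model_num")
    alt <- pick("label_alt_id")
    d <- tibble(
      chain = pick("auth_asym_id", "label_asym_id"),
      resno = suppressWarnings(as.integer(pick("auth_seq_id",
                                               "label_seq_id"))),
      resid = pick("auth_comp_id", "label_comp_id"),
      atom = pick("auth_atom_id", "label_atom_id"),
      x = as.numeric(pick("Cartn_x")), y = as.numeric(pick("Cartn_y")),
      z = as.numeric(pick("Cartn_z")))
    keep <- (is.na(grp) | grp == "ATOM") &
      (is.na(mod) | mod == mod[1]) &
      (is.na(alt) | alt %in% c(".", "", "A"))
    d$atom <- gsub('"', "", d$atom)
    return(d[keep, , drop = FALSE])
  }
  abort("content error: no atom_site loop found in mmCIF file")
}

AMINO3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
            "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
            "TYR", "VAL", "MSE", "SEC", "PYL")

atoms_to_model <- function(atoms) {
  atoms <- atoms[atoms$resid %in% AMINO3 &
                   atoms$atom %in% c("N", "CA", "C", "O"), , drop = FALSE]
  if (nrow(atoms) == 0) abort("content error: no protein chain found")
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  split_idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  rows <- vector("list", length(split_idx))
  dropped <- 0L
  for (s in seq_along(split_idx)) {
    idx <- split_idx[[s]]
    sub <- atoms[idx, ]
    pos <- match(c("N", "CA", "C", "O"), sub$atom)
    if (any(is.na(pos))) { dropped <- dropped + 1L; next }
    sub <- sub[pos, ]
    rows[[s]] <- tibble(
      chain = sub$chain[1], resno = sub$resno[1], resid = sub$resid[2],
      N_x = sub$x[1], N_y = sub$y[1], N_z = sub$z[1],
      CA_x = sub$x[2], CA_y = sub$y[2], CA_z = sub$z[2],
      C_x = sub$x[3], C_y = sub$y[3], C_z = sub$z[3],
      O_x = sub$x[4], O_y = sub$y[4], O_z = sub$z[4])
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0)
    abort("content error: no backbone-complete residues")
  if (dropped > 0)
    warn(sprintf("%d residue(s) dropped for missing backbone atoms", dropped))
  class(out) <- c("structure_model", class(out))
  attr(out, "n_dropped") <- dropped
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %d residues, %d chain(s)\n", nrow(x),
              length(unique(x$chain))))
  NextMethod()
}

#' Write a backbone model as PDB or mmCIF
#'
#' @param model A `structure_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_structure_pdb <- function(model, file) {
  lines <- character()
  serial <- 0L
  for (r in seq_len(nrow(model))) {
    for (atom in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      el <- substr(atom, 1, 1)
      name <- sprintf(" %-3s", atom)
      lines[[serial]] <- sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name, model$resid[r], model$chain[r], model$resno[r],
        model[[paste0(atom, "_x")]][r], model[[paste0(atom, "_y")]][r],
        model[[paste0(atom, "_z")]][r], 1.0, 0.0, el)
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' @rdname write_structure_pdb
#' @export
write_structure_cif <- function(model, file) {
  hdr <- c("data_synthetic", "#", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.auth_atom_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.label_alt_id", "_atom_site.Cartn_x",
           "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.pdbx_PDB_model_num")
  rows <- character()
  serial <- 0L
  for (r in seq_len(nrow(model))) {
    for (atom in c("N", "CA", "C", "O")) {
      serial <- serial + 1L
      rows[[serial]] <- sprintf(
        "ATOM %d %s %s %s %d . %.3f %.3f %.3f 1",
        serial, atom, model$resid[r], model$chain[r], model$resno[r],
        model[[paste0(atom, "_x")]][r], model[[paste0(atom, "_y")]][r],
        model[[paste0(atom, "_z")]][r])
    }
  }
  writeLines(c(hdr, rows, "#"), file)
  invisible(file)
}
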