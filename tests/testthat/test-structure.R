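# structure fixtures are cached after first generation, so the geometry
# searches run once per session

test_that("ideal helix fixtures parse and assign as helix", {
  h <- gen_structure("helix", 20)
  expect_equal(nrow(h), 20)
  expect_equal(length(unique(h$chain)), 1)

  f_pdb <- withr::local_tempfile(fileext = ".pdb")
  f_cif <- withr::local_tempfile(fileext = ".cif")
  write_structure_pdb(h, f_pdb); write_structure_cif(h, f_cif)
  m_pdb <- read_structure(f_pdb); m_cif <- read_structure(f_cif)
  expect_equal(nrow(m_pdb), 20); expect_equal(nrow(m_cif), 20)
  # format equivalence at coordinate precision
  expect_equal(as.matrix(m_pdb[, 4:15]), as.matrix(m_cif[, 4:15]),
               tolerance = 1e-9)

  a <- assign_dssp(m_pdb)
  expect_gte(sum(a$dssp == "H"), 16)
  comp <- ss_composition(m_pdb)
  helix_frac <- comp$ss[["Helix1"]] + comp$ss[["Helix2"]]
  expect_gte(helix_frac, 0.8)
  expect_equal(sum(comp$ss), 1, tolerance = 1e-9)
  # PDB vs mmCIF give identical compositions
  expect_equal(unclass(ss_composition(m_cif)$ss), unclass(comp$ss),
               tolerance = 1e-9)
})

test_that("helix split follows the two-two-ends rule", {
  split_counts <- function(L) {
    lab <- split_helix(c("-", rep("H", L), "-"))
    c(sum(lab == "Helix1", na.rm = TRUE), sum(lab == "Helix2", na.rm = TRUE))
  }
  expect_equal(split_counts(9), c(5, 4))
  expect_equal(split_counts(5), c(1, 4))
  for (L in 1:4) expect_equal(split_counts(L), c(0, L))
  for (L in 5:30) expect_equal(split_counts(L), c(L - 4, 4))
  # conservation: Helix1 + Helix2 equals the H count
  set.seed(31)
  lab <- sample(c("H", "-", "E", "T"), 200, replace = TRUE)
  sp <- split_helix(lab)
  expect_equal(sum(!is.na(sp)), sum(lab == "H"))
})

test_that("strands classify by sense and twist bin", {
  flat <- gen_structure("antiparallel_sheet", 8, twist = 0)
  b_flat <- classify_beta(flat)
  expect_gt(nrow(b_flat), 0)
  expect_lt(abs(mean(b_flat$twist, na.rm = TRUE)), 2)
  expect_true(all(b_flat$beta_class == "Anti1"))

  tw30 <- gen_structure("antiparallel_sheet", 8, twist = 30)
  b_30 <- classify_beta(tw30)
  expect_gte(mean(b_30$twist, na.rm = TRUE), 23)
  expect_equal(names(which.max(table(b_30$beta_class))), "Anti3")

  par <- gen_structure("parallel_sheet", 8)
  b_par <- classify_beta(par)
  expect_true(all(b_par$beta_class == "Parallel"))

  # monotone binning in the imposed twist
  bins <- c(Anti1 = 1, Anti2 = 2, Anti3 = 3)
  mean_bin <- vapply(c(0, 12, 30), function(tw) {
    b <- classify_beta(gen_structure("antiparallel_sheet", 8, twist = tw))
    mean(bins[b$beta_class])
  }, 0.0)
  expect_true(all(diff(mean_bin) > 0))
})

test_that("twist angles match a direct vector-algebra computation", {
  m <- gen_structure("antiparallel_sheet", 8, twist = 15)
  a <- assign_dssp(m)
  br <- attr(a, "bridges")
  b <- classify_beta(m, a)
  CA <- as.matrix(m[, c("CA_x", "CA_y", "CA_z")])
  row <- br[1, ]
  i <- row$i; p <- row$j
  u <- CA[i + 1, ] - CA[i - 1, ]
  v <- -(CA[p + 1, ] - CA[p - 1, ])
  ax <- (CA[p, ] - CA[i, ]); ax <- ax / sqrt(sum(ax^2))
  up <- u - sum(u * ax) * ax; vp <- v - sum(v * ax) * ax
  cr <- c(up[2] * vp[3] - up[3] * vp[2], up[3] * vp[1] - up[1] * vp[3],
          up[1] * vp[2] - up[2] * vp[1])
  want <- atan2(sum(ax * cr), sum(up * vp)) * 180 / pi
  got <- b$twist[b$index == i]
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("assignments are invariant under rigid motion", {
  m <- gen_structure("antiparallel_sheet", 8, twist = 12)
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  R2 <- matrix(c(1, 0, 0, 0, cos(1.2), -sin(1.2), 0, sin(1.2), cos(1.2)),
               3, 3, byrow = TRUE)
  mr <- m
  for (at in c("N", "CA", "C", "O")) {
    cols <- paste0(at, c("_x", "_y", "_z"))
    mr[, cols] <- as.matrix(m[, cols]) %*% t(R %*% R2) +
      matrix(rep(c(11, -4, 7), each = nrow(m)), ncol = 3)
  }
  a0 <- ss_composition(m); a1 <- ss_composition(mr)
  expect_equal(unclass(a1$ss), unclass(a0$ss), tolerance = 1e-9)
  t0 <- a0$residues$twist; t1 <- a1$residues$twist
  expect_equal(t1[!is.na(t1)], t0[!is.na(t0)], tolerance = 1e-6)
})

test_that("coil chains and isolated strands stay unassigned", {
  co <- gen_structure("coil", 20)
  a <- assign_dssp(co)
  expect_false(any(a$dssp == "E"))
  comp <- ss_composition(co)
  expect_gte(comp$ss[["Others"]] + comp$ss[["Turn"]], 0.95)

  # a single extended strand has no bridge partner, hence no E
  single <- gen_structure("antiparallel_sheet", 8)
  single <- single[single$chain == "A", ]
  class(single) <- c("structure_model", class(single))
  expect_false(any(assign_dssp(single)$dssp == "E"))
})

test_that("generated backbones have ideal covalent geometry", {
  for (kind in c("helix", "coil")) {
    m <- gen_structure(kind, 12)
    for (r in seq_len(nrow(m))) {
      nca <- sqrt(sum((as.numeric(m[r, c("N_x", "N_y", "N_z")]) -
                         as.numeric(m[r, c("CA_x", "CA_y", "CA_z")]))^2))
      cac <- sqrt(sum((as.numeric(m[r, c("CA_x", "CA_y", "CA_z")]) -
                         as.numeric(m[r, c("C_x", "C_y", "C_z")]))^2))
      expect_lt(abs(nca - 1.458), 0.02)
      expect_lt(abs(cac - 1.525), 0.02)
    }
  }
  flat <- gen_structure("antiparallel_sheet", 8, twist = 0)
  co <- sqrt(rowSums((as.matrix(flat[, c("C_x", "C_y", "C_z")]) -
                        as.matrix(flat[, c("O_x", "O_y", "O_z")]))^2))
  expect_true(all(abs(co - 1.231) < 0.02))
})

test_that("structure parsing rejects empty and non-protein input", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("", f)
  expect_error(read_structure(f), "content error")
  writeLines(c("HETATM    1  C1  LIG A   1       0.000   0.000   0.000",
               "END"), f)
  expect_error(read_structure(f), "content error")
  expect_error(gen_structure("helix", 3), "length")
})

test_that("residues missing backbone atoms are dropped with a warning", {
  h <- gen_structure("helix", 12)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure_pdb(h, f)
  lines <- readLines(f)
  lines <- lines[!grepl("^ATOM.{9}O   ALA A   5", lines)]
  writeLines(lines, f)
  expect_warning(m <- read_structure(f), "dropped")
  expect_equal(nrow(m), 11)
  expect_equal(attr(m, "n_dropped"), 1L)
})
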