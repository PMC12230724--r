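test_that("per-wavelength basis solve matches the normal equations", {
  truth <- truth_small()
  ref <- gen_reference_set(20, truth, sigma = 0.01, seed = 61)
  l <- 210
  got <- solve_basis_spectra(ref, l)
  li <- which(ref$wavelength == l)
  want <- qr.coef(qr(ref$ss), ref$cd[, li])
  expect_equal(as.numeric(got$b), as.numeric(want), tolerance = 1e-8)
  expect_equal(got$rank, 8)
  expect_error(solve_basis_spectra(ref, 500), "coverage")
})

test_that("exact linear systems reproduce their generating basis", {
  set.seed(62)
  SS <- diag(8) * 0.6 + 0.05             # independent simplex-ish rows
  SS <- SS / rowSums(SS)
  b_true <- rnorm(8, sd = 3)
  wl <- 200:210
  CD <- matrix(rep(SS %*% b_true, length(wl)), ncol = length(wl))
  ref <- reference_set(sprintf("p%02d", 1:8), SS, CD, wl)
  got <- solve_basis_spectra(ref, 205)
  expect_equal(as.numeric(got$b), b_true, tolerance = 1e-10)
})

test_that("rank-deficient reference sets are solved minimum-norm", {
  wl <- 200:210
  ss1 <- rep(1 / 8, 8)
  SS <- matrix(rep(ss1, 10), nrow = 10, byrow = TRUE)
  CD <- matrix(1, 10, length(wl))
  ref <- reference_set(sprintf("p%02d", 1:10), SS, CD, wl)
  got <- solve_basis_spectra(ref, 205)
  expect_equal(got$rank, 1)
  # minimum-norm solution of a rank-1 system: b = ss1 * <cd>/||ss1||^2
  expect_equal(as.numeric(got$b), ss1 / sum(ss1^2), tolerance = 1e-8)
})

test_that("greedy refinement removes a planted outlier first", {
  truth <- truth_small()
  ref <- gen_reference_set(15, truth, sigma = 0.002, seed = 63)
  # outlier: a realistic spectrum paired with the wrong composition
  # (protein 7 is given protein 1's spectrum); the refinement for the
  # most-mismatched component should evict it first
  donor <- 1L; bad <- 7L
  comp <- which.max(abs(ref$ss[bad, ] - ref$ss[donor, ]))
  ref$cd[bad, ] <- ref$cd[donor, ]
  tr <- greedy_subset(ref, comp, max_removed = 4)
  expect_gt(nrow(tr$steps), 1)
  expect_equal(tr$steps$removed_id[2], ref$id[bad])
  # prediction RMSD improves along the trace
  expect_true(all(diff(tr$steps$rmsd) < 0))
})

test_that("noise-free homogeneous sets need no removals", {
  truth <- truth_small()
  ref <- gen_reference_set(14, truth, sigma = 0, seed = 64)
  # linearizable data: use a constant-column truth so Eq.2 is exact
  B <- matrix(rnorm(8 * length(ref$wavelength), sd = 2), 8)
  cc <- constant_basis_set(ref$wavelength, B)
  ref2 <- gen_reference_set(14, cc, sigma = 0, seed = 64)
  tr <- greedy_subset(ref2, 3, max_removed = 4)
  expect_equal(nrow(tr$steps), 1)         # no improving removal exists
})

test_that("greedy traces are deterministic across runs", {
  truth <- truth_small()
  ref <- gen_reference_set(16, truth, sigma = 0.02, seed = 65)
  t1 <- greedy_subset(ref, 2, max_removed = 5)
  t2 <- greedy_subset(ref, 2, max_removed = 5)
  expect_identical(t1$steps, t2$steps)
  expect_identical(t1$b, t2$b)
})

test_that("matrix-column regression recovers constructed columns", {
  set.seed(66)
  X <- random_simplex(20, seed = 67)
  m_true <- rnorm(8, sd = 2)
  b <- as.numeric(X %*% m_true)
  got <- fit_matrix_column(X, b, ridge = 1e-10)
  expect_equal(as.numeric(got), m_true, tolerance = 1e-4)

  # constant targets return (a minimizer equivalent to) the constant column
  bconst <- rep(2.2, 20)
  gc <- fit_matrix_column(X, bconst, ridge = 1e-6)
  expect_equal(as.numeric(X %*% gc), bconst, tolerance = 1e-6)

  few <- fit_matrix_column(X[1:5, ], b[1:5], ridge = 1e-4)
  expect_true(attr(few, "flagged"))
  expect_error(fit_matrix_column(X[0, ], numeric(0)), "no pairs")
})

test_that("training collapses to the constant-column model when disabled", {
  truth <- truth_small()
  ref <- gen_reference_set(12, truth, sigma = 0.01, seed = 68)
  # n < 20 disables CV acceptance, so every column falls back
  model <- train_basis_matrices(ref, max_removed = 2)
  cc <- constant_column_model(ref)
  expect_equal(model$M, cc$M, tolerance = 1e-12)
  expect_true(all(attr(model, "report")$constant_fallback))
})

test_that("training is byte-identical across runs and entry orders", {
  truth <- truth_small()
  ref <- gen_reference_set(24, truth, sigma = 0.01, seed = 69)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_basis_matrix_set(train_basis_matrices(ref, max_removed = 4), f1)
  # shuffle entry order; constructor re-sorts by id
  perm <- sample(seq_along(ref$id))
  ref_shuf <- reference_set(ref$id[perm], ref$ss[perm, ], ref$cd[perm, ],
                            ref$wavelength)
  write_basis_matrix_set(train_basis_matrices(ref_shuf, max_removed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("reference sets round-trip through manifest and spectrum files", {
  truth <- truth_small()
  ref <- gen_reference_set(10, truth, sigma = 0.01, seed = 70)
  dir <- withr::local_tempdir()
  man <- write_reference_set(ref, dir)
  back <- read_reference_set(man)
  expect_identical(back$id, ref$id)
  expect_identical(back$cd, ref$cd)
  expect_equal(back$ss, ref$ss, tolerance = 1e-15)
})
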