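#' Construct a reference set
#'
#' A reference set pairs known secondary-structure compositions with CD
#' spectra on a shared 1 nm wavelength grid.  Entries are sorted by id so
#' that training is invariant to input order.
#'
#' @param id Character vector of unique entry ids.
#' @param ss n x 8 matrix (or data frame) of fractions, canonical
#'   component order.
#' @param cd n x L matrix of delta-epsilon values on `wavelength`.
#' @param wavelength Shared wavelength grid (1 nm pitch).
#' @return A `reference_set`.
#' @export
reference_set <- function(id, ss, cd, wavelength) {
  id <- as.character(id)
  if (anyDuplicated(id)) abort("duplicate reference ids")
  ss <- as.matrix(ss); cd <- as.matrix(cd)
  if (ncol(ss) != 8) abort("ss must have 8 columns")
  if (nrow(ss) != length(id) || nrow(cd) != length(id))
    abort("id, ss and cd must agree in length")
  if (ncol(cd) != length(wavelength))
    abort("cd must have one column per wavelength")
  bad <- abs(rowSums(ss) - 1) > 1e-6 | apply(ss, 1, min) < -1e-9
  if (any(bad)) abort("every ss row must be a valid simplex vector")
  ord <- order(id)
  colnames(ss) <- ss_components()
  structure(list(id = id[ord], ss = ss[ord, , drop = FALSE],
                 cd = cd[ord, , drop = FALSE],
                 wavelength = as.numeric(wavelength)),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d proteins, %g-%g nm\n", length(x$id),
              min(x$wavelength), max(x$wavelength)))
  invisible(x)
}

subset_reference <- function(ref, keep) {
  reference_set(ref$id[keep], ref$ss[keep, , drop = FALSE],
                ref$cd[keep, , drop = FALSE], ref$wavelength)
}

#' Write a reference set as a manifest plus spectrum files
#'
#' The manifest CSV has columns `id`, the eight component fractions and
#' `spectrum_path` (relative); each spectrum is a two-column text file.
#'
#' @param ref A `reference_set`.
#' @param dir Output directory (created if needed).
#' @param manifest Manifest file name.
#' @return Path to the manifest, invisibly.
#' @export
write_reference_set <- function(ref, dir, manifest = "manifest.csv") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- paste0(ref$id, ".txt")
  for (i in seq_along(ref$id)) {
    s <- cd_spectrum(ref$wavelength, ref$cd[i, ], unit = "delta_epsilon")
    write_cd_spectrum(s, file.path(dir, paths[i]))
  }
  man <- data.frame(id = ref$id, ref$ss, spectrum_path = paths,
                    check.names = FALSE)
  num_cols <- ss_components()
  for (cc in num_cols) man[[cc]] <- fmt_num(man[[cc]])
  mpath <- file.path(dir, manifest)
  write.table(man, mpath, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

#' Read a reference set from a manifest CSV
#'
#' @param manifest Path to the manifest written by [write_reference_set()].
#' @return A `reference_set`.
#' @export
read_reference_set <- function(manifest) {
  man <- read.table(manifest, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", ss_components(), "spectrum_path")
  if (!all(need %in% names(man)))
    abort("manifest must have columns id, the 8 components, spectrum_path")
  dir <- dirname(manifest)
  specs <- lapply(man$spectrum_path, function(p)
    read_cd_spectrum(file.path(dir, p)))
  wl <- specs[[1]]$wavelength
  for (s in specs) {
    if (length(s$wavelength) != length(wl) ||
        max(abs(s$wavelength - wl)) > 1e-9)
      abort("all reference spectra must share one wavelength grid")
  }
  cd <- do.call(rbind, lapply(specs, function(s) s$value))
  reference_set(man$id, as.matrix(man[, ss_components()]), cd, wl)
}

# minimum-norm least-squares solve of SS b = cd for all wavelengths at
# once; returns list(B = 8 x L, rank)
solve_basis_all <- function(SS, CD, tol = 1e-10) {
  sv <- svd(SS)
  keep <- sv$d > tol * max(sv$d)
  dinv <- ifelse(keep, 1 / sv$d, 0)
  B <- sv$v %*% (dinv * (t(sv$u) %*% CD))
  list(B = B, rank = sum(keep))
}

#' Solve for the basis-spectrum values at one wavelength
#'
#' Unconstrained linear least squares `min 0.5 ||SS b - CD||^2` over the
#' reference proteins; rank-deficient systems are solved minimum-norm and
#' reported via `rank`.
#'
#' @param ref A `reference_set`.
#' @param lambda Wavelength (nm) on the reference grid.
#' @return List with `b` (named length-8 vector), `residual` (norm) and
#'   `rank`.
#' @export
solve_basis_spectra <- function(ref, lambda) {
  l <- which(abs(ref$wavelength - lambda) < 1e-9)
  if (length(l) != 1) abort("coverage error: wavelength not on the grid")
  sol <- solve_basis_all(ref$ss, ref$cd[, l, drop = FALSE])
  b <- setNames(as.numeric(sol$B), ss_components())
  list(b = b, residual = sqrt(sum((ref$ss %*% b - ref$cd[, l])^2)),
       rank = sol$rank)
}

#' Constant-column model from a full reference set
#'
#' Solves the per-wavelength linear least-squares problem on the whole
#' reference set and assembles the resulting basis spectra into a
#' constant-column `basis_matrix_set` (the composition-independent
#' baseline model).
#'
#' @param ref A `reference_set`.
#' @return A `basis_matrix_set`.
#' @export
constant_column_model <- function(ref) {
  sol <- solve_basis_all(ref$ss, ref$cd)
  constant_basis_set(ref$wavelength, sol$B)
}

# fast path: predict SS of every row of `cd` with a constant-column basis B
# (8 x L) by the simplex-constrained linear solver
predict_ss_linear <- function(B, cd) {
  X <- cpp_simplex_ls_batch(t(B), t(cd))
  t(X)
}

#' Greedy leave-out subset refinement for one component
#'
#' Starting from the full reference set, repeatedly removes the single
#' protein whose removal most improves the root-mean-square error of the
#' chosen component when the constant-column model refit on the remaining
#' subset is used to re-estimate the composition of *every* protein in the
#' full set.  Stops when no removal improves or `max_removed` is reached.
#' The improvement criterion does not depend on wavelength, so one trace
#' per component serves every wavelength; the per-step basis values
#' `b_{i,lambda}` are recorded for all wavelengths.
#'
#' @param ref A `reference_set` (n > 8).
#' @param component Component index 1..8 or name.
#' @param max_removed Maximum removals; must be < n - 8.
#' @return List with `steps` (tibble: step, removed_id, rmsd), `mean_ss`
#'   (matrix, one row per step: mean composition of the retained subset),
#'   `b` (matrix, one row per step: the component's basis values across
#'   wavelengths) and `kept` (ids retained at the end).
#' @export
greedy_subset <- function(ref, component, max_removed = 12) {
  if (is.character(component)) component <- match(component, ss_components())
  if (is.na(component) || component < 1 || component > 8)
    abort("component must be 1..8 or a component name")
  n <- length(ref$id)
  if (max_removed >= n - 8)
    abort("max_removed must be smaller than n - 8")
  truth <- ref$ss[, component]

  eval_subset <- function(keep) {
    sol <- solve_basis_all(ref$ss[keep, , drop = FALSE],
                           ref$cd[keep, , drop = FALSE])
    pred <- predict_ss_linear(sol$B, ref$cd)
    list(rmsd = sqrt(mean((pred[, component] - truth)^2)), B = sol$B)
  }

  keep <- rep(TRUE, n)
  cur <- eval_subset(keep)
  steps <- list(tibble(step = 0L, removed_id = NA_character_,
                       rmsd = cur$rmsd))
  mean_ss <- list(colMeans(ref$ss))
  b_rows <- list(cur$B[component, ])

  for (k in seq_len(max_removed)) {
    cand <- which(keep)
    res <- vapply(cand, function(j) {
      kj <- keep; kj[j] <- FALSE
      eval_subset(kj)$rmsd
    }, 0.0)
    best <- which.min(res)             # ties: lowest index = lexicographic id
    if (res[best] >= cur$rmsd - 1e-15) break
    keep[cand[best]] <- FALSE
    cur <- eval_subset(keep)
    steps[[k + 1L]] <- tibble(step = k, removed_id = ref$id[cand[best]],
                              rmsd = cur$rmsd)
    mean_ss[[k + 1L]] <- colMeans(ref$ss[keep, , drop = FALSE])
    b_rows[[k + 1L]] <- cur$B[component, ]
  }
  list(steps = dplyr::bind_rows(steps),
       mean_ss = do.call(rbind, mean_ss),
       b = do.call(rbind, b_rows),
       kept = ref$id[keep])
}

#' Fit one basis-matrix column from composition/basis-value pairs
#'
#' Ridge-regularized least squares for
#' `min sum_j (ss_j' m - b_j)^2`, shrunk toward the constant column
#' `mean(b) * 1` (the constant-column solution is always representable, so
#' with little composition signal the fit degenerates gracefully to the
#' baseline model rather than to zero).  With fewer than 8 pairs the
#' system is underdetermined and the result is flagged.
#'
#' @param ss Matrix of compositions, one row per pair.
#' @param b Numeric vector of basis values, one per pair.
#' @param ridge Ridge weight, relative to `mean(diag(ss'ss))`.
#' @return Length-8 numeric column with attribute `flagged` (TRUE when
#'   fewer than 8 pairs were supplied).
#' @export
fit_matrix_column <- function(ss, b, ridge = 1e-8) {
  ss <- as.matrix(ss)
  if (nrow(ss) == 0) abort("argument error: no pairs supplied")
  if (nrow(ss) != length(b)) abort("ss and b must agree in length")
  G <- crossprod(ss)
  lam <- ridge * mean(diag(G))
  centre <- mean(b)
  m <- solve(G + lam * diag(8), crossprod(ss, b) + lam * centre)
  m <- as.numeric(m)
  attr(m, "flagged") <- nrow(ss) < 8
  m
}

# composition-stratified subsets: for every component, order the
# reference proteins by that component and cut into contiguous strata.
# These subsets span the composition space much more widely than the
# greedy traces and give the Eq.-3 regression the leverage it needs to
# identify a composition dependence.
stratified_subsets <- function(ref, n_strata = 3, min_size = 9) {
  n <- length(ref$id)
  n_strata <- min(n_strata, floor(n / min_size))
  if (n_strata < 2) return(list())
  subsets <- list()
  for (comp in 1:8) {
    ord <- order(ref$ss[, comp], ref$id)
    cuts <- split(ord, cut(seq_len(n), breaks = max(n_strata, 1),
                           labels = FALSE))
    for (g in cuts) {
      if (length(g) >= min_size) subsets[[length(subsets) + 1]] <- sort(g)
    }
  }
  unique(subsets)
}

# full-reference-set spectrum reconstruction error when component i's
# column is `col_i` (8 x L) and all other components stay constant-column
reconstruction_error <- function(ref, B0, comp, col_i) {
  # prediction: CD_j(l) = sum_i ss_ij * b_i(SS_j, l), with b_i linear in SS
  base <- ref$ss %*% B0                       # n x L constant-column part
  delta <- ref$ss[, comp] *
    (ref$ss %*% col_i - matrix(B0[comp, ], length(ref$id),
                               ncol(B0), byrow = TRUE))
  sum((base + delta - ref$cd)^2)
}

# ridge fit of one matrix column for all wavelengths at once
fit_matrix_columns_all <- function(X, Bvals, ridge) {
  G <- crossprod(X)
  lam <- ridge * mean(diag(G))
  centre <- colMeans(Bvals)
  rhs <- crossprod(X, Bvals) + lam * matrix(centre, 8, length(centre),
                                            byrow = TRUE)
  solve(G + lam * diag(8), rhs)            # 8 x L
}

#' Train a basis-matrix set from a reference set
#'
#' For every component the per-wavelength linear problem is solved on a
#' family of subsets of the reference set -- the greedy leave-out trace
#' of [greedy_subset()] plus composition-stratified subsets that span the
#' composition space -- and the resulting basis values are regressed on
#' the subset mean compositions ([fit_matrix_column()]) at every
#' wavelength, assembling the 8 x 8 basis matrices column by column.  The
#' per-component ridge weight is chosen from `ridge_grid` (which always
#' implicitly includes the constant-column fallback) by the full-set
#' spectrum reconstruction error, so a trained column is only accepted
#' where the composition dependence actually improves the fit.  Training
#' is deterministic: no randomness is used and ties break by id order.
#'
#' @param ref A `reference_set` with more than 8 entries.
#' @param max_removed Maximum greedy removals per component.
#' @param ridge_grid Candidate relative ridge weights.
#' @param n_strata Number of strata per component for the stratified
#'   subset family.
#' @param cv_margin Minimum relative cross-validated improvement over the
#'   constant column required to accept a trained column.
#' @return A `basis_matrix_set` (provenance `"trained"`) with attribute
#'   `"report"`: greedy traces, chosen ridges and degeneracy flags.
#' @export
train_basis_matrices <- function(ref, max_removed = 12,
                                 ridge_grid = c(0.1, 1, 3, 10, 30),
                                 n_strata = 3, cv_margin = 0.01) {
  n <- length(ref$id)
  if (n < 9) abort("training requires more than 8 reference proteins")
  max_removed <- min(max_removed, n - 9L)
  L <- length(ref$wavelength)

  # pair family (greedy traces + stratified subsets) for one reference set
  pair_family <- function(r, mr) {
    subs <- stratified_subsets(r, n_strata = n_strata)
    sols <- lapply(subs, function(idx)
      list(mean_ss = colMeans(r$ss[idx, , drop = FALSE]),
           B = solve_basis_all(r$ss[idx, , drop = FALSE],
                               r$cd[idx, , drop = FALSE])$B))
    traces <- lapply(1:8, function(i) greedy_subset(r, i, max_removed = mr))
    list(traces = traces, subs = sols)
  }
  pairs_for <- function(fam, i) {
    X <- rbind(fam$traces[[i]]$mean_ss,
               do.call(rbind, lapply(fam$subs, `[[`, "mean_ss")))
    Bv <- rbind(fam$traces[[i]]$b,
                do.call(rbind, lapply(fam$subs, function(s) s$B[i, ])))
    list(X = X, B = Bv)
  }

  full <- pair_family(ref, max_removed)
  B0 <- solve_basis_all(ref$ss, ref$cd)$B     # constant-column baseline

  # ridge selection by two-fold cross-validated reconstruction error
  # (deterministic odd/even folds in id order); a trained column is only
  # accepted when it beats the constant column by a decisive margin,
  # otherwise the model degenerates gracefully to the baseline
  use_cv <- n >= 20
  if (use_cv) {
    fold_of <- rep_len(1:2, n)
    halves <- lapply(1:2, function(f) {
      tr_idx <- which(fold_of != f)
      half_ref <- subset_reference(ref, tr_idx)
      mr_half <- max(0L, min(max_removed, length(tr_idx) - 9L))
      list(test = subset_reference(ref, which(fold_of == f)),
           fam = pair_family(half_ref, mr_half),
           B0 = solve_basis_all(half_ref$ss, half_ref$cd)$B)
    })
  }

  M <- array(0, dim = c(8, 8, L))
  ridges <- numeric(8)
  flagged <- logical(8)
  for (i in 1:8) {
    chosen <- Inf
    if (use_cv) {
      # per-fold errors; a ridge is accepted only when it beats the
      # constant column in *every* fold by the margin (guards against
      # lucky single-fold improvements of unstable columns)
      per_fold <- function(col_fun) {
        vapply(halves, function(h)
          reconstruction_error(h$test, h$B0, i, col_fun(h)), 0.0)
      }
      err_const <- per_fold(function(h)
        matrix(rep(h$B0[i, ], each = 8), nrow = 8))
      errs <- vapply(ridge_grid, function(r) {
        e <- per_fold(function(h) {
          p <- pairs_for(h$fam, i)
          fit_matrix_columns_all(p$X, p$B, r)
        })
        if (all(e < err_const * (1 - cv_margin))) sum(e) else Inf
      }, 0.0)
      if (any(is.finite(errs))) chosen <- ridge_grid[which.min(errs)]
    }
    if (is.finite(chosen)) {
      p <- pairs_for(full, i)
      M[, i, ] <- fit_matrix_columns_all(p$X, p$B, chosen)
    } else {
      M[, i, ] <- matrix(rep(B0[i, ], each = 8), nrow = 8)
      flagged[i] <- TRUE
    }
    ridges[i] <- chosen
  }
  # joint "do no harm" screen: the assembled model must not degrade the
  # cross-validated recovery of *any* component relative to the
  # constant-column baseline; otherwise fall back to the baseline model
  accepted <- which(is.finite(ridges))
  if (use_cv && length(accepted) > 0) {
    harm <- FALSE
    for (h in halves) {
      Mh <- array(0, dim = c(8, 8, L))
      for (i in 1:8) {
        Mh[, i, ] <- if (i %in% accepted) {
          p <- pairs_for(h$fam, i)
          fit_matrix_columns_all(p$X, p$B, ridges[i])
        } else matrix(rep(h$B0[i, ], each = 8), nrow = 8)
      }
      mh <- basis_matrix_set(ref$wavelength, Mh, provenance = "trained")
      e_tr <- cv_recovery_rmsd(h$test, mh)
      e_cc <- cv_recovery_rmsd(h$test,
                               constant_basis_set(ref$wavelength, h$B0))
      if (any(e_tr > e_cc * (1 + cv_margin) + 1e-4)) { harm <- TRUE; break }
    }
    if (harm) {
      for (i in accepted) {
        M[, i, ] <- matrix(rep(B0[i, ], each = 8), nrow = 8)
        ridges[i] <- Inf
        flagged[i] <- TRUE
      }
    }
  }
  out <- basis_matrix_set(ref$wavelength, M, provenance = "trained")
  attr(out, "report") <- list(
    removals = lapply(full$traces, function(t) t$steps),
    ridges = ridges, constant_fallback = flagged,
    n_subsets = length(full$subs))
  out
}

# per-component RMSD of re-estimated compositions for a reference set
# under a given model (internal; modest multi-start for speed)
cv_recovery_rmsd <- function(ref, model, n_starts = 10) {
  E <- vapply(seq_along(ref$id), function(j) {
    s <- cd_spectrum(ref$wavelength, ref$cd[j, ], unit = "delta_epsilon")
    fit <- fit_secondary_structure(s, model, n_starts = n_starts, seed = 1)
    as.numeric(fit$ss) - ref$ss[j, ]
  }, numeric(8))
  sqrt(rowMeans(E^2))
}

#' Held-out component error of a model on a reference set
#'
#' K-fold cross-validation: the model is trained on the complement of each
#' fold with `trainer` and used to re-estimate the compositions of the
#' fold's spectra; per-component root-mean-square errors are pooled over
#' folds.
#'
#' @param ref A `reference_set`.
#' @param trainer `function(reference_set) -> basis_matrix_set`.
#' @param folds Number of folds (default 3; fold assignment is by position
#'   in id order, deterministic).
#' @param n_starts,seed Passed to [fit_secondary_structure()].
#' @return Tibble with `component` and `rmsd`.
#' @export
cv_component_rmsd <- function(ref, trainer, folds = 3, n_starts = 12,
                              seed = 1) {
  n <- length(ref$id)
  fold_id <- rep_len(seq_len(folds), n)
  err2 <- matrix(NA_real_, n, 8)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    model <- trainer(subset_reference(ref, -test))
    for (j in test) {
      s <- cd_spectrum(ref$wavelength, ref$cd[j, ], unit = "delta_epsilon")
      fit <- fit_secondary_structure(s, model, n_starts = n_starts,
                                     seed = seed)
      err2[j, ] <- (as.numeric(fit$ss) - ref$ss[j, ])^2
    }
  }
  tibble(component = ss_components(), rmsd = sqrt(colMeans(err2)))
}
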