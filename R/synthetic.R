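# Seeded generators for synthetic study data: ground-truth spectral
# models, reference sets, melting curves, fold databases and
# ordered/disordered references.  Every generator is a pure function of
# its arguments (all randomness flows through the seed).

# smooth band: sum of Gaussians on the wavelength grid
gauss_bands <- function(wl, centers, widths, amps) {
  v <- numeric(length(wl))
  for (b in seq_along(centers)) {
    v <- v + amps[b] * exp(-0.5 * ((wl - centers[b]) / widths[b])^2)
  }
  v
}

#' Generate a ground-truth basis-matrix set
#'
#' Each component's basis spectrum is a sum of two or three Gaussian bands
#' with seeded centers, widths and signed amplitudes chosen in the far-UV
#' amplitude range typical of protein CD.  Off-diagonal composition
#' coupling is added as smooth symmetric perturbation matrices scaled by
#' `coupling`; `coupling = 0` yields an exactly constant-column (linear)
#' model.
#'
#' @param wl_min,wl_max Wavelength range (nm), 1 nm pitch.
#' @param coupling Relative strength of the composition dependence
#'   (default 0.15).
#' @param max_cosine Upper bound on the pairwise cosine similarity of the
#'   component basis spectra (default 0.8).  The modeled components exist
#'   because their spectral signatures are distinct; unconstrained random
#'   bands occasionally draw near-duplicate spectra, which would make the
#'   inverse problem unidentifiable in a way the real system is not.
#'   Candidate spectra are redrawn (deterministically, from the seeded
#'   stream) until they respect the bound.
#' @param seed Integer seed.
#' @return A `basis_matrix_set` with provenance `"synthetic"`.
#' @export
gen_basis_truth <- function(wl_min = 175, wl_max = 250, coupling = 0.15,
                            max_cosine = 0.8, seed = 1) {
  wl <- seq(wl_min, wl_max)
  L <- length(wl)
  with_seed(seed, {
    B <- matrix(0, 8, L)
    draw_bands <- function() {
      nb <- sample(2:3, 1)
      centers <- runif(nb, wl_min + 5, 235)
      widths <- runif(nb, 5, 15)
      amps <- runif(nb, 2, 9) * sample(c(-1, 1), nb, replace = TRUE)
      gauss_bands(wl, centers, widths, amps)
    }
    for (i in 1:8) {
      best <- NULL; best_cos <- Inf
      for (try in 1:50) {
        cand <- draw_bands()
        cmax <- if (i == 1) 0 else max(abs(
          B[1:(i - 1), , drop = FALSE] %*% cand /
            (sqrt(rowSums(B[1:(i - 1), , drop = FALSE]^2)) *
               sqrt(sum(cand^2)))))
        if (cmax < best_cos) { best <- cand; best_cos <- cmax }
        if (cmax <= max_cosine) break
      }
      B[i, ] <- best
    }
    M <- array(0, dim = c(8, 8, L))
    ones <- rep(1, 8)
    for (l in seq_len(L)) M[, , l] <- outer(ones, B[, l])
    if (coupling > 0) {
      scale <- mean(abs(B))
      for (i in 1:8) for (j in i:8) {
        nb <- 2
        centers <- runif(nb, wl_min + 5, 235)
        widths <- runif(nb, 8, 18)
        amps <- runif(nb, -1, 1)
        band <- gauss_bands(wl, centers, widths, amps)
        M[i, j, ] <- M[i, j, ] + coupling * scale * band
        if (j > i) M[j, i, ] <- M[j, i, ] + coupling * scale * band
      }
    }
    basis_matrix_set(wl, M, provenance = "synthetic")
  })
}

#' Generate a synthetic reference set from a ground-truth model
#'
#' Compositions are drawn from a Dirichlet distribution whose default
#' concentration spreads mass toward the corners of the simplex, covering
#' helix-rich, beta-rich and disordered-like proteins; spectra are the
#' model evaluations plus Gaussian noise scaled to the clean spectrum's
#' peak amplitude.
#'
#' @param n Number of proteins.
#' @param truth A `basis_matrix_set` ground truth.
#' @param alpha Dirichlet concentration (length 8 or scalar; default 0.8).
#' @param sigma Noise standard deviation as a fraction of each clean
#'   spectrum's peak |CD| (default 0.01).
#' @param seed Integer seed.
#' @return A `reference_set` with ids `sp001`, `sp002`, ...
#' @export
gen_reference_set <- function(n, truth, alpha = 0.8, sigma = 0.01,
                              seed = 1) {
  if (sigma < 0) abort("sigma must be >= 0")
  alpha <- rep_len(alpha, 8)
  wl <- truth$wavelength
  with_seed(seed, {
    SS <- rdirichlet(n, alpha)
    CD <- matrix(0, n, length(wl))
    for (i in seq_len(n)) {
      clean <- evaluate_model(truth, ss_vector(SS[i, ], normalize = TRUE))
      noise <- if (sigma > 0) rnorm(length(wl), 0,
                                    sigma * max(abs(clean$value))) else 0
      CD[i, ] <- clean$value + noise
    }
    reference_set(sprintf("sp%03d", seq_len(n)), SS, CD, wl)
  })
}

#' Generate a synthetic melting curve
#'
#' Evaluates the two-state model on a temperature grid and adds seeded
#' Gaussian noise scaled to the transition amplitude
#' `|(A_D + m_D T_m) - (A_N + m_N T_m)|`.
#'
#' @param params Thermal parameters as in [model_cd()].
#' @param t_min,t_max,pitch Temperature grid in K (must lie in
#'   250-400 K).
#' @param sigma Noise s.d. as a fraction of the transition amplitude.
#' @param seed Integer seed.
#' @return A `melting_curve`.
#' @export
gen_melting_curve <- function(params, t_min = 293.15, t_max = 363.15,
                              pitch = 0.5, sigma = 0.01, seed = 1) {
  if (t_min < 250 || t_max > 400) abort("temperature grid must lie in 250-400 K")
  T <- seq(t_min, t_max, by = pitch)
  clean <- model_cd(T, params)
  p <- as.list(params)
  amp <- abs((p$A_D + p$m_D * p$T_m) - (p$A_N + p$m_N * p$T_m))
  noise <- if (sigma > 0) with_seed(seed, rnorm(length(T), 0, sigma * amp))
  else 0
  melting_curve(T, clean + noise)
}

#' Generate a synthetic fold database
#'
#' Labels form a 2 x 2 x 2 x 2 hierarchy `C.A.T.H` (class, architecture,
#' topology, homology; 16 leaf folds).  Centroid compositions are built
#' hierarchically -- class centroids drawn from a Dirichlet, each deeper
#' level perturbing its parent by progressively smaller seeded amounts --
#' so records with a common prefix cluster in composition space.  Records
#' scatter around their leaf centroid and are renormalized to the simplex.
#'
#' @param n_per_fold Records per leaf fold.
#' @param spread Gaussian scatter s.d. around each centroid before
#'   renormalization (default 0.03).
#' @param level_sd Perturbation s.d. at the architecture, topology and
#'   homology levels.
#' @param seed Integer seed.
#' @return A `fold_db` with attribute `"centroids"`.
#' @export
gen_fold_db <- function(n_per_fold = 25, spread = 0.03,
                        level_sd = c(0.10, 0.06, 0.03), seed = 1) {
  with_seed(seed, {
    clamp_simplex <- function(v) { v <- pmax(v, 0.005); v / sum(v) }
    cent <- list()
    for (C in 1:2) {
      cC <- clamp_simplex(rdirichlet(1, rep(0.9, 8))[1, ])
      for (A in 1:2) {
        cA <- clamp_simplex(cC + rnorm(8, 0, level_sd[1]))
        for (T in 1:2) {
          cT <- clamp_simplex(cA + rnorm(8, 0, level_sd[2]))
          for (H in 1:2) {
            cH <- clamp_simplex(cT + rnorm(8, 0, level_sd[3]))
            cent[[paste(C, A, T, H, sep = ".")]] <- cH
          }
        }
      }
    }
    rec <- list(); rid <- 0L
    for (label in names(cent)) {
      for (k in seq_len(n_per_fold)) {
        rid <- rid + 1L
        v <- clamp_simplex(cent[[label]] + rnorm(8, 0, spread))
        rec[[rid]] <- tibble(id = sprintf("d%05d", rid),
                             !!!setNames(as.list(v), ss_components()),
                             chain_length = sample(60:400, 1),
                             label = label)
      }
    }
    db <- fold_db(dplyr::bind_rows(rec))
    attr(db, "centroids") <- cent
    db
  })
}

#' Generate a synthetic ordered/disordered reference
#'
#' Ordered and disordered records are drawn inside two cones around
#' distinct direction vectors in triplet space (scaled by random positive
#' amplitudes, so only the direction separates the classes -- matching
#' the scale invariance of the cosine distance).
#'
#' @param n Total records (split evenly).
#' @param wavelength_set `"197-206-233"` or `"212-217-225"`.
#' @param cone_sd Angular scatter (radians-equivalent scale on the unit
#'   sphere) within each class cone; small values give well-separated
#'   classes.
#' @param seed Integer seed.
#' @return A `disorder_reference`.
#' @export
gen_disorder_ref <- function(n = 262, wavelength_set = "197-206-233",
                             cone_sd = 0.08, seed = 1) {
  # characteristic triplet directions: disordered far-UV CD has a deep
  # negative band near 200 nm and near-zero long-wavelength signal;
  # ordered spectra have moderate negative bands at longer wavelengths
  dirs <- if (wavelength_set == "197-206-233") {
    list(ordered = c(-1.5, -4.0, -0.3), disordered = c(-9.0, -2.0, 0.4))
  } else {
    list(ordered = c(-4.0, -4.5, -1.0), disordered = c(-2.5, -1.0, 0.6))
  }
  with_seed(seed, {
    n_ord <- floor(n / 2); n_dis <- n - n_ord
    draw <- function(mu, m) {
      mu <- mu / sqrt(sum(mu^2))
      t(vapply(seq_len(m), function(k) {
        v <- mu + rnorm(3, 0, cone_sd)
        v / sqrt(sum(v^2)) * runif(1, 0.5, 12)   # random positive amplitude
      }, numeric(3)))
    }
    O <- draw(dirs$ordered, n_ord)
    D <- draw(dirs$disordered, n_dis)
    df <- tibble(id = sprintf("ref%03d", seq_len(n)),
                 w1 = c(O[, 1], D[, 1]), w2 = c(O[, 2], D[, 2]),
                 w3 = c(O[, 3], D[, 3]),
                 label = c(rep("ordered", n_ord), rep("disordered", n_dis)))
    disorder_reference(df, wavelength_set = wavelength_set)
  })
}
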