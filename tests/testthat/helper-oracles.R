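# Shared fixtures and independent oracles used across the suite.

# brute-force double sum of the quadratic spectral model
oracle_quadratic_cd <- function(M, ss) {
  vapply(seq_len(dim(M)[3]), function(l) {
    acc <- 0
    for (i in 1:8) for (j in 1:8) acc <- acc + ss[i] * M[i, j, l] * ss[j]
    acc
  }, 0.0)
}

# exact simplex-constrained least-squares oracle by exhaustive support
# enumeration: the optimum lies in the relative interior of some face, so
# enumerating the equality-constrained minimizer of every support and
# keeping the feasible one with least objective is exact
oracle_simplex_ls <- function(A, y) {
  p <- ncol(A)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    AS <- A[, S, drop = FALSE]
    k <- length(S)
    K <- rbind(cbind(crossprod(AS), rep(1, k)), c(rep(1, k), 0))
    rhs <- c(crossprod(AS, y), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    xS <- sol[seq_len(k)]
    if (any(xS < -1e-12)) next
    x <- numeric(p); x[S] <- pmax(xS, 0); x <- x / sum(x)
    obj <- 0.5 * sum((A %*% x - y)^2)
    if (obj < best_obj) { best_obj <- obj; best <- x }
  }
  list(x = best, objective = best_obj)
}

# brute-force windowed mean; `strict` excludes points exactly on the
# window edge (the smoothing convention), otherwise the edge is included
# (the regridding bin convention)
oracle_window_mean <- function(w, v, centers, half, strict = FALSE) {
  eps <- if (strict) -1e-9 else 1e-9
  vapply(centers, function(c0) mean(v[abs(w - c0) <= half + eps]), 0.0)
}

# independent transliteration of the two-state melting model
oracle_model_cd <- function(T, p) {
  R <- 8.314
  y <- (1 / R) * ((p$T_m * p$dCp - p$dH_m) / T + p$dH_m / p$T_m - p$dCp)
  K <- exp(y) * (T / p$T_m)^(p$dCp / R)
  ((p$A_N + p$m_N * T) + (p$A_D + p$m_D * T) * K) / (1 + K)
}

oracle_delta_g <- function(T, p) {
  p$dH_m * (1 - T / p$T_m) - p$dCp * ((p$T_m - T) + T * log(T / p$T_m))
}

# small shared ground-truth model and reference set (module-scale grid)
truth_small <- function() gen_basis_truth(200, 240, coupling = 0.2, seed = 42)

random_simplex <- function(n, seed = 1) {
  set.seed(seed)
  g <- matrix(rgamma(n * 8, 1), n)
  g / rowSums(g)
}
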