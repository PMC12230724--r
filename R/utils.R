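# internal helpers shared across modules

# Seeded local RNG: runs `expr` under a private RNG state so package
# functions are deterministic given `seed` without touching the caller's
# global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Dirichlet draws, one row per sample
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# numeric formatting used by all text writers: full double precision,
# locale-independent, so seeded pipelines are byte-identical across runs
fmt_num <- function(x) formatC(x, format = "g", digits = 17)

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort(sprintf("`%s` must be a single positive number", name))
  invisible(x)
}
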