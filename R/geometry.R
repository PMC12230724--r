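# Ideal-geometry backbone construction (internal coordinates -> Cartesian)
# used by the synthetic structure generator.

# standard backbone bond lengths (Angstrom) and angles (degrees)
BB_GEOM <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8,
  omega = 180
)

deg2rad <- function(x) x * pi / 180
vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# place atom D from A-B-C with bond length r, angle theta(B,C,D) and
# torsion chi(A,B,C,D) (degrees)
place_atom <- function(a, b, c, r, theta, chi) {
  th <- deg2rad(theta); ch <- deg2rad(chi)
  b2 <- vunit(c - b)
  n <- vunit(vcross(b - a, b2))
  m <- vcross(n, b2)
  c + r * (-cos(th) * b2 + sin(th) * (cos(ch) * m + sin(ch) * n))
}

# dihedral angle (degrees, IUPAC sign) of p1-p2-p3-p4
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# build an n-residue backbone from phi/psi vectors; returns list of n x 3
# matrices N, CA, C, O
build_backbone <- function(phi, psi, omega = BB_GEOM$omega) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 2)
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  a <- deg2rad(g$a_NCAC)
  C[1, ] <- CA[1, ] + g$b_CAC * c(-cos(a), sin(a), 0)
  for (i in seq_len(n - 1)) {
    N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_CN, g$a_CACN,
                             psi[i])
    CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$b_NCA,
                              g$a_CNCA, omega)
    C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_CAC,
                             g$a_NCAC, phi[i + 1])
  }
  for (i in seq_len(n)) {
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CACO,
                         psi[i] + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

# assemble a structure_model tibble from per-chain backbone lists
backbone_to_model <- function(chains) {
  rows <- purrr::imap(chains, function(bb, ch) {
    n <- nrow(bb$N)
    tibble(chain = ch, resno = seq_len(n), resid = "ALA",
           N_x = bb$N[, 1], N_y = bb$N[, 2], N_z = bb$N[, 3],
           CA_x = bb$CA[, 1], CA_y = bb$CA[, 2], CA_z = bb$CA[, 3],
           C_x = bb$C[, 1], C_y = bb$C[, 2], C_z = bb$C[, 3],
           O_x = bb$O[, 1], O_y = bb$O[, 2], O_z = bb$O[, 3])
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("structure_model", class(out))
  attr(out, "n_dropped") <- 0L
  out
}

# rotate/translate helpers acting on a backbone list
transform_bb <- function(bb, R = diag(3), t = c(0, 0, 0)) {
  lapply(bb, function(m) sweep(m %*% t(R), 2, -t))
}

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# align a backbone so its CA axis is +x, centroid at origin, and the
# carbonyl directions lie mostly along +/- y (roll chosen on a 5 deg grid)
align_strand <- function(bb) {
  ca <- bb$CA
  cen <- colMeans(ca)
  bb <- transform_bb(bb, t = -cen)
  v <- vunit(bb$CA[nrow(ca), ] - bb$CA[1, ])
  # rotation taking v to +x (Rodrigues)
  x <- c(1, 0, 0)
  axis <- vcross(v, x)
  s <- vnorm(axis)
  if (s > 1e-12) {
    axis <- axis / s
    ang <- atan2(s, sum(v * x))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
    bb <- transform_bb(bb, R = R)
  }
  rolls <- deg2rad(seq(0, 355, by = 5))
  score <- vapply(rolls, function(r) {
    Rb <- transform_bb(bb, R = rot_x(r))
    co <- Rb$O - Rb$C
    sum(abs(co[, 2]) / sqrt(rowSums(co^2)))
  }, 0.0)
  transform_bb(bb, R = rot_x(rolls[which.max(score)]))
}

# amide H positions for a single-chain backbone (NA for the first residue)
bb_amide_h <- function(bb) {
  n <- nrow(bb$N)
  H <- matrix(NA_real_, n, 3)
  co <- bb$C[-n, , drop = FALSE] - bb$O[-n, , drop = FALSE]
  co <- co / sqrt(rowSums(co^2))
  H[-1, ] <- bb$N[-1, , drop = FALSE] + co
  H
}

cross_dist <- function(X, Y) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
  sqrt(pmax(d2, 0))
}

# vectorized Kabsch-Sander H-bond count between two chains (placement
# search scorer); -1 on steric clash
interchain_hbonds <- function(bbA, bbB) {
  XA <- rbind(bbA$N, bbA$CA, bbA$C, bbA$O)
  XB <- rbind(bbB$N, bbB$CA, bbB$C, bbB$O)
  if (min(cross_dist(XA, XB)) < 2.2) return(-1)
  q <- 0.084 * 332
  count_dir <- function(don, acc) {
    H <- bb_amide_h(don)
    ok <- !is.na(H[, 1])
    E <- q * (1 / cross_dist(don$N[ok, , drop = FALSE], acc$O) +
                1 / cross_dist(H[ok, , drop = FALSE], acc$C) -
                1 / cross_dist(H[ok, , drop = FALSE], acc$O) -
                1 / cross_dist(don$N[ok, , drop = FALSE], acc$C))
    sum(E < -0.5)
  }
  count_dir(bbA, bbB) + count_dir(bbB, bbA)
}

rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}

sheet_strand <- function(strand_len, sense) {
  if (sense == "anti") {
    phi <- rep(-139, strand_len); psi <- rep(135, strand_len)
  } else {
    phi <- rep(-119, strand_len); psi <- rep(113, strand_len)
  }
  align_strand(build_backbone(phi, psi))
}

# rigid placement of the partner strand maximizing inter-strand H-bonds.
# Antiparallel partners are the C2 image about the inter-strand (y) axis,
# the natural symmetry of a two-stranded antiparallel ribbon; parallel
# partners are a pure translation.
find_sheet_placement <- function(strand_len, sense = c("anti", "para")) {
  sense <- match.arg(sense)
  A <- sheet_strand(strand_len, sense)
  B0 <- if (sense == "anti") transform_bb(A, R = rot_y(pi)) else A
  best <- list(score = -Inf, shift = c(0, 4.8, 0))
  grid <- expand.grid(dx = seq(-3.5, 3.5, by = 0.25),
                      dy = seq(4.0, 5.6, by = 0.2),
                      dz = seq(-1.5, 1.5, by = 0.25))
  for (r in seq_len(nrow(grid))) {
    B <- transform_bb(B0, t = c(grid$dx[r], grid$dy[r], grid$dz[r]))
    sc <- interchain_hbonds(A, B)
    if (sc > best$score) best <- list(score = sc,
                                      shift = as.numeric(grid[r, ]))
  }
  s0 <- best$shift
  fine <- expand.grid(dx = seq(s0[1] - 0.2, s0[1] + 0.2, by = 0.05),
                      dy = seq(s0[2] - 0.15, s0[2] + 0.15, by = 0.05),
                      dz = seq(s0[3] - 0.2, s0[3] + 0.2, by = 0.05))
  for (r in seq_len(nrow(fine))) {
    B <- transform_bb(B0, t = c(fine$dx[r], fine$dy[r], fine$dz[r]))
    sc <- interchain_hbonds(A, B)
    if (sc > best$score) best <- list(score = sc,
                                      shift = as.numeric(fine[r, ]))
  }
  list(A = A, B = transform_bb(B0, t = best$shift), score = best$score,
       shift = best$shift)
}

# measured mean antiparallel twist of an assembled pair
measure_sheet <- function(model) {
  beta <- tryCatch(classify_beta(model), error = function(e) NULL)
  if (is.null(beta) || nrow(beta) == 0) return(NA_real_)
  tw <- beta$twist[!is.na(beta$twist)]
  if (length(tw) == 0) NA_real_ else mean(tw)
}

# helicoid map: rotate every atom about the ribbon's central x axis by an
# angle proportional to its x coordinate.  Cross-sections at equal x
# rotate rigidly, so inter-strand hydrogen-bond geometry (partners sit at
# matching x) is preserved exactly; covalent bonds shear slightly at
# large twist because neighbouring residues sit at different x.
twist_ribbon <- function(bb, slope, x_mid, y_mid, z_mid) {
  lapply(bb, function(m) {
    a <- slope * (m[, 1] - x_mid)
    y <- m[, 2] - y_mid; z <- m[, 3] - z_mid
    cbind(m[, 1], y * cos(a) - z * sin(a) + y_mid,
          y * sin(a) + z * cos(a) + z_mid)
  })
}

# deterministic caches: placements depend only on geometry
.sheet_cache <- new.env(parent = emptyenv())

# assemble a two-stranded sheet with a target measured inter-strand
# twist: apply the helicoid with the nominal slope for the target, then
# correct once using the measured value (the flat assembly has a small
# intrinsic twist offset)
build_sheet_pair <- function(strand_len, sense, twist) {
  pl <- find_sheet_placement(strand_len, sense)
  assemble <- function(tau_eff) {
    if (abs(tau_eff) < 1e-9) {
      return(backbone_to_model(list(A = pl$A, B = pl$B)))
    }
    sep <- abs(mean(pl$B$CA[, 2]) - mean(pl$A$CA[, 2]))
    slope <- tan(deg2rad(tau_eff)) / sep
    allCA <- rbind(pl$A$CA, pl$B$CA)
    x_mid <- mean(allCA[, 1]); y_mid <- mean(allCA[, 2])
    z_mid <- mean(allCA[, 3])
    A <- twist_ribbon(pl$A, slope, x_mid, y_mid, z_mid)
    B <- twist_ribbon(pl$B, slope, x_mid, y_mid, z_mid)
    backbone_to_model(list(A = A, B = B))
  }
  if (sense == "para") return(assemble(if (abs(twist) > 0) -twist else 0))
  base <- measure_sheet(assemble(0))
  if (is.na(base)) abort("sheet assembly failed to hydrogen-bond")
  tau <- base - twist                    # measured ~ baseline - tau_eff
  m <- assemble(tau)
  got <- measure_sheet(m)
  if (!is.na(got) && abs(got - twist) > 1) {
    m2 <- assemble(tau + (got - twist))
    got2 <- measure_sheet(m2)
    if (!is.na(got2) && abs(got2 - twist) < abs(got - twist)) m <- m2
  }
  m
}

#' Generate an idealized synthetic structure
#'
#' Backbones built from ideal internal coordinates: alpha-helix
#' (phi = -57, psi = -47), two-stranded antiparallel or parallel beta
#' sheets (strand placement optimized deterministically for inter-strand
#' hydrogen bonding; an imposed inter-strand twist rotates residues
#' progressively about the strand axis), or an irregular coil.  These are
#' synthetic fixtures for exercising the assignment machinery, not models
#' of real proteins.
#'
#' @param kind `"helix"`, `"antiparallel_sheet"`, `"parallel_sheet"` or
#'   `"coil"`.
#' @param length Residues per chain (>= 4).
#' @param twist Imposed inter-strand twist in degrees (sheets only;
#'   right-hand positive).
#' @return A `structure_model` tibble (one or two chains).
#' @export
gen_structure <- function(kind = c("helix", "antiparallel_sheet",
                                   "parallel_sheet", "coil"),
                          length = 12, twist = 0) {
  kind <- match.arg(kind)
  if (length < 4) abort("argument error: length must be >= 4")
  if (kind == "helix") {
    bb <- build_backbone(rep(-57, length), rep(-47, length))
    return(backbone_to_model(list(A = bb)))
  }
  if (kind == "coil") {
    i <- seq_len(length)
    phi <- -75 + 20 * sin(1.7 * i)
    psi <- 150 - 25 * cos(2.3 * i)
    bb <- build_backbone(phi, psi)
    return(backbone_to_model(list(A = bb)))
  }
  sense <- if (kind == "antiparallel_sheet") "anti" else "para"
  key <- paste("model", sense, length, round(twist, 3), sep = "_")
  if (!is.null(.sheet_cache[[key]])) return(.sheet_cache[[key]])
  model <- build_sheet_pair(length, sense, twist)
  .sheet_cache[[key]] <- model
  model
}
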