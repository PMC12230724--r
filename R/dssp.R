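# Hydrogen-bond based secondary-structure assignment in the style of the
# Kabsch-Sander dictionary: backbone amide H reconstruction, electrostatic
# H-bond energy, n-turns, helices, bridges and ladders.

model_coords <- function(model, atom) {
  as.matrix(model[, paste0(atom, c("_x", "_y", "_z"))])
}

# Kabsch-Sander H-bond energies for all donor/acceptor residue pairs.
# Returns list(bond = logical [donor, acceptor], energy = numeric matrix).
ks_hbond_matrix <- function(model, cutoff = -0.5) {
  n <- nrow(model)
  N <- model_coords(model, "N"); CA <- model_coords(model, "CA")
  C <- model_coords(model, "C"); O <- model_coords(model, "O")
  chain <- model$chain
  # peptide connectivity: same chain and bonded C(i-1)-N(i)
  bonded_prev <- c(FALSE, chain[-1] == chain[-n] &
                     sqrt(rowSums((N[-1, , drop = FALSE] -
                                     C[-n, , drop = FALSE])^2)) < 2.0)
  # amide H: 1.0 A from N along the C(i-1)=O(i-1) direction (O -> C)
  H <- matrix(NA_real_, n, 3)
  for (i in which(bonded_prev)) {
    H[i, ] <- N[i, ] + vunit(C[i - 1, ] - O[i - 1, ])
  }
  E <- matrix(Inf, n, n)   # E[donor, acceptor]
  d2 <- outer(rowSums(CA^2), rowSums(CA^2), "+") - 2 * CA %*% t(CA)
  near <- d2 < 81          # 9 A CA-CA prefilter
  q <- 0.084 * 332
  for (i in seq_len(n)) {
    if (!bonded_prev[i]) next       # chain starts cannot donate
    for (j in seq_len(n)) {
      if (i == j || !near[i, j]) next
      if (chain[i] == chain[j] && abs(model$resno[i] - model$resno[j]) < 2)
        next
      rON <- vnorm(O[j, ] - N[i, ]); rCH <- vnorm(C[j, ] - H[i, ])
      rOH <- vnorm(O[j, ] - H[i, ]); rCN <- vnorm(C[j, ] - N[i, ])
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      E[i, j] <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
    }
  }
  list(bond = E < cutoff, energy = E)
}

#' Secondary-structure assignment from backbone hydrogen bonding
#'
#' Implements the hydrogen-bond pattern rules of the Dictionary of
#' Secondary Structure of Proteins: the backbone amide H is reconstructed
#' from the preceding peptide geometry, H-bonds are detected with the
#' electrostatic energy criterion `E < -0.5 kcal/mol`
#' (`E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)`), and
#' patterns of bonded n-turns and bridges yield helix (`H`), 3-10/pi
#' helix (`G`/`I`), extended strand (`E`), isolated bridge (`B`) and turn
#' (`T`) states.  Strand beats helix when both patterns apply.
#'
#' @param model A `structure_model`.
#' @return A `dssp_assignment`: tibble with `chain`, `resno`, `dssp`, plus
#'   attributes `bridges` (tibble `i`, `j`, `type`, `ladder`) and
#'   `hbonds`.
#' @export
assign_dssp <- function(model) {
  n <- nrow(model)
  out <- tibble(chain = model$chain, resno = model$resno,
                dssp = rep("-", n))
  if (n < 4) {
    return(structure(out, bridges = tibble(i = integer(), j = integer(),
                                           type = character(),
                                           ladder = integer()),
                     class = c("dssp_assignment", class(out))))
  }
  hb <- ks_hbond_matrix(model)
  HB <- hb$bond
  chain <- model$chain
  same_chain_run <- function(i, j) {
    i >= 1 && j <= n && i <= j && all(chain[i:j] == chain[i])
  }
  # ks_turn(i, m): CO(i) accepts from NH(i+m)
  ks_turn <- function(i, m) {
    j <- i + m
    j <= n && chain[i] == chain[j] && same_chain_run(i, j) && HB[j, i]
  }
  turn3 <- vapply(seq_len(n), ks_turn, TRUE, m = 3L)
  turn4 <- vapply(seq_len(n), ks_turn, TRUE, m = 4L)
  turn5 <- vapply(seq_len(n), ks_turn, TRUE, m = 5L)

  lab <- rep("-", n)
  mark <- function(lab, from, to, code, over = "-") {
    idx <- from:to
    idx <- idx[lab[idx] %in% over]
    lab[idx] <- code
    lab
  }
  # turns first (lowest priority), then G/I, then H, then E/B on top
  for (i in seq_len(n)) {
    for (m in c(3L, 4L, 5L)) {
      t_ok <- switch(as.character(m), "3" = turn3[i], "4" = turn4[i],
                     "5" = turn5[i])
      if (t_ok && i + m - 1 <= n) lab <- mark(lab, i + 1, i + m - 1, "T")
    }
  }
  for (i in 2:n) {
    if (turn3[i - 1] && turn3[i] && i + 2 <= n)
      lab <- mark(lab, i, i + 2, "G", over = c("-", "T"))
    if (turn5[i - 1] && turn5[i] && i + 4 <= n)
      lab <- mark(lab, i, i + 4, "I", over = c("-", "T"))
  }
  for (i in 2:n) {
    if (turn4[i - 1] && turn4[i] && i + 3 <= n)
      lab <- mark(lab, i, i + 3, "H", over = c("-", "T", "G", "I"))
  }

  # bridges; KS Hbond(a, b) = CO(a) accepts from NH(b) = HB[b, a]
  ks_hb <- function(a, b) {
    a >= 1 && b >= 1 && a <= n && b <= n && HB[b, a]
  }
  bridges <- list()
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (j <= i) next
      if (chain[i] == chain[j] && j - i <= 2) next
      has_i_nb <- chain[i - 1] == chain[i] && chain[i + 1] == chain[i]
      has_j_nb <- chain[j - 1] == chain[j] && chain[j + 1] == chain[j]
      if (!has_i_nb || !has_j_nb) next
      para <- (ks_hb(i - 1, j) && ks_hb(j, i + 1)) ||
        (ks_hb(j - 1, i) && ks_hb(i, j + 1))
      anti <- (ks_hb(i, j) && ks_hb(j, i)) ||
        (ks_hb(i - 1, j + 1) && ks_hb(j - 1, i + 1))
      if (para) bridges[[length(bridges) + 1]] <-
          tibble(i = i, j = j, type = "parallel")
      if (anti) bridges[[length(bridges) + 1]] <-
          tibble(i = i, j = j, type = "antiparallel")
    }
  }
  br <- if (length(bridges) > 0) dplyr::bind_rows(bridges) else
    tibble(i = integer(), j = integer(), type = character())

  # ladders: bridges at consecutive i with j stepping by the sense
  br$ladder <- 0L
  if (nrow(br) > 0) {
    lad <- 0L
    br <- br[order(br$type, br$i, br$j), ]
    for (r in seq_len(nrow(br))) {
      if (br$ladder[r] != 0L) next
      lad <- lad + 1L
      br$ladder[r] <- lad
      cur <- r
      repeat {
        step_j <- if (br$type[cur] == "parallel") 1L else -1L
        nxt <- which(br$type == br$type[cur] & br$i == br$i[cur] + 1L &
                       br$j == br$j[cur] + step_j & br$ladder == 0L)
        if (length(nxt) == 0) break
        br$ladder[nxt[1]] <- lad
        cur <- nxt[1]
      }
    }
    lad_sizes <- table(br$ladder)
    in_ladder <- br$ladder %in% as.integer(names(lad_sizes)[lad_sizes >= 2])
    e_res <- unique(c(br$i[in_ladder], br$j[in_ladder]))
    b_res <- setdiff(unique(c(br$i, br$j)), e_res)
    lab[e_res] <- "E"
    lab[b_res[lab[b_res] %in% c("-", "T", "G", "I")]] <- "B"
  }
  out$dssp <- lab
  structure(out, bridges = br,
            class = c("dssp_assignment", class(out)))
}

#' Split helix residues into middle and end components
#'
#' In every maximal run of helix (`H`) residues of length `L >= 5`, the
#' two residues at each end become `Helix2` (distorted) and the middle
#' `L - 4` become `Helix1` (regular); runs with `L <= 4` are entirely
#' `Helix2`.
#'
#' @param dssp Character vector of per-residue states (`"H"` marks helix)
#'   or a `dssp_assignment`.
#' @param chain Optional chain vector; runs never cross chains.
#' @return Character vector: `"Helix1"`, `"Helix2"` or `NA` per residue.
#' @export
split_helix <- function(dssp, chain = NULL) {
  if (inherits(dssp, "dssp_assignment")) {
    chain <- dssp$chain
    dssp <- dssp$dssp
  }
  n <- length(dssp)
  chain <- chain %||% rep("A", n)
  out <- rep(NA_character_, n)
  is_h <- dssp == "H"
  run_id <- cumsum(c(TRUE, is_h[-1] != is_h[-n] | chain[-1] != chain[-n]))
  for (r in unique(run_id[is_h])) {
    idx <- which(run_id == r & is_h)
    L <- length(idx)
    if (L >= 5) {
      out[idx] <- "Helix1"
      out[idx[c(1, 2, L - 1, L)]] <- "Helix2"
    } else {
      out[idx] <- "Helix2"
    }
  }
  out
}

# signed twist angle between the chain vectors of residue i and partner p,
# measured as the dihedral about the inter-strand axis CA_i -> CA_p;
# for antiparallel partners the partner vector is reversed first
strand_twist <- function(CA, i, p, anti) {
  u <- CA[i + 1, ] - CA[i - 1, ]
  v <- CA[p + 1, ] - CA[p - 1, ]
  if (anti) v <- -v
  a <- vunit(CA[p, ] - CA[i, ])
  up <- u - sum(u * a) * a
  vp <- v - sum(v * a) * a
  if (vnorm(up) < 1e-9 || vnorm(vp) < 1e-9) return(NA_real_)
  atan2(sum(a * vcross(up, vp)), sum(up * vp)) * 180 / pi
}

#' Classify strand residues by sheet sense and twist
#'
#' Parallel-sense strand residues map to `Parallel`.  Antiparallel
#' residues get a per-residue twist angle -- the signed dihedral between
#' the `CA(i-1) -> CA(i+1)` chain vectors of the residue and of its bridge
#' partner about the inter-strand axis, right-hand twist positive -- and
#' are binned at two thresholds: twist `< t1` is `Anti1` (left-hand
#' twisted), `t1 <= twist < t2` is `Anti2` (relaxed), `>= t2` is `Anti3`
#' (right-hand twisted).  Strand-terminal residues that lack `i +/- 1`
#' neighbours inherit their ladder's mean twist.
#'
#' @param model A `structure_model`.
#' @param dssp A `dssp_assignment` from [assign_dssp()] (computed if
#'   omitted).
#' @param t1,t2 Twist thresholds in degrees (defaults 3 and 23).
#' @return Tibble with `index`, `beta_class`, `twist` for every strand
#'   (`E`) residue.
#' @export
classify_beta <- function(model, dssp = NULL, t1 = 3, t2 = 23) {
  if (t1 >= t2) abort("t1 must be smaller than t2")
  dssp <- dssp %||% assign_dssp(model)
  br <- attr(dssp, "bridges")
  CA <- model_coords(model, "CA")
  chain <- model$chain
  n <- nrow(model)
  e_idx <- which(dssp$dssp == "E")
  if (length(e_idx) == 0) {
    return(tibble(index = integer(), beta_class = character(),
                  twist = numeric()))
  }
  # residue -> bridges involving it (antiparallel preferred)
  res_info <- purrr::map(e_idx, function(i) {
    rows <- br[br$i == i | br$j == i, ]
    if (nrow(rows) == 0) return(list(sense = NA, partner = NA, ladder = NA))
    rows <- rows[order(rows$type), ]      # "antiparallel" < "parallel"
    sense <- rows$type[1]
    partner <- if (rows$i[1] == i) rows$j[1] else rows$i[1]
    list(sense = sense, partner = partner, ladder = rows$ladder[1])
  })
  twist <- rep(NA_real_, length(e_idx))
  ladder <- vapply(res_info, function(x) as.integer(x$ladder %||% NA), 1L)
  for (k in seq_along(e_idx)) {
    info <- res_info[[k]]
    if (!identical(info$sense, "antiparallel")) next
    i <- e_idx[k]; p <- info$partner
    ok_i <- i > 1 && i < n && chain[i - 1] == chain[i] &&
      chain[i + 1] == chain[i]
    ok_p <- p > 1 && p < n && chain[p - 1] == chain[p] &&
      chain[p + 1] == chain[p]
    if (ok_i && ok_p) twist[k] <- strand_twist(CA, i, p, anti = TRUE)
  }
  # terminal residues inherit the ladder mean
  for (k in which(is.na(twist))) {
    if (!identical(res_info[[k]]$sense, "antiparallel")) next
    same <- which(ladder == ladder[k] & !is.na(twist))
    twist[k] <- if (length(same) > 0) mean(twist[same]) else 0
  }
  beta_class <- vapply(seq_along(e_idx), function(k) {
    if (identical(res_info[[k]]$sense, "parallel")) return("Parallel")
    if (!identical(res_info[[k]]$sense, "antiparallel")) return("Parallel")
    tw <- twist[k]
    if (tw < t1) "Anti1" else if (tw < t2) "Anti2" else "Anti3"
  }, "")
  tibble(index = e_idx, beta_class = beta_class, twist = twist)
}

#' Eight-component secondary-structure composition of a structure
#'
#' Runs the hydrogen-bond assignment, the helix middle/end split and the
#' beta sense/twist classification, then counts residues: strand residues
#' map to their beta class, helix residues to `Helix1`/`Helix2`,
#' hydrogen-bonded turns to `Turn`, and everything else -- including
#' 3-10/pi helices and isolated beta bridges under the default mapping --
#' to `Others`.
#'
#' @param model A `structure_model`.
#' @param t1,t2 Antiparallel twist thresholds (degrees).
#' @param helix310 Mapping for 3-10/pi helix states: `"Others"` (default)
#'   or `"Turn"`.
#' @param bridge Mapping for isolated beta bridges: `"Others"` (default)
#'   or `"Anti2"`.
#' @return An `ss_assignment`: list with `ss` (an [ss_vector()]) and
#'   `residues` (per-residue tibble with `chain`, `resno`, `dssp`,
#'   `component`, `twist`).
#' @export
ss_composition <- function(model, t1 = 3, t2 = 23,
                           helix310 = c("Others", "Turn"),
                           bridge = c("Others", "Anti2")) {
  helix310 <- match.arg(helix310)
  bridge <- match.arg(bridge)
  n <- nrow(model)
  if (n == 0) abort("content error: no assignable residues")
  dssp <- assign_dssp(model)
  helix_part <- split_helix(dssp)
  beta <- classify_beta(model, dssp, t1 = t1, t2 = t2)
  comp <- rep("Others", n)
  comp[dssp$dssp == "T"] <- "Turn"
  comp[dssp$dssp %in% c("G", "I")] <- helix310
  comp[dssp$dssp == "B"] <- bridge
  comp[!is.na(helix_part)] <- helix_part[!is.na(helix_part)]
  comp[beta$index] <- beta$beta_class
  twist <- rep(NA_real_, n)
  twist[beta$index] <- beta$twist
  counts <- table(factor(comp, levels = ss_components()))
  ss <- ss_vector(as.numeric(counts) / n)
  residues <- tibble(chain = model$chain, resno = model$resno,
                     dssp = dssp$dssp, component = comp, twist = twist)
  structure(list(ss = ss, residues = residues),
            class = "ss_assignment")
}

#' @export
print.ss_assignment <- function(x, ...) {
  cat(sprintf("<ss_assignment> %d residues\n", nrow(x$residues)))
  print(round(unclass(x$ss), 4))
  invisible(x)
}

#' Per-residue tidy view of a structure assignment
#'
#' @param x An `ss_assignment`.
#' @param ... Unused.
#' @return The per-residue tibble.
#' @export
tidy.ss_assignment <- function(x, ...) x$residues

#' One-row fractions summary of a structure assignment
#'
#' @param x An `ss_assignment`.
#' @param ... Unused.
#' @return One-row tibble with the eight fractions.
#' @export
glance.ss_assignment <- function(x, ...) {
  as_tibble(as.list(unclass(x$ss)))
}
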