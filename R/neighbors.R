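#' Construct a fold database
#'
#' A fold database is a tibble of protein records positioned in the
#' eight-dimensional secondary-structure space, each carrying a four-level
#' hierarchical fold label `"C.A.T.H"` (class, architecture, topology,
#' homology) and a chain length (metadata only; it does not enter any
#' distance).
#'
#' @param df Data frame with columns `id`, the eight component fractions
#'   (canonical names), `chain_length` and `label`.
#' @return A `fold_db` tibble.
#' @export
fold_db <- function(df) {
  need <- c("id", ss_components(), "chain_length", "label")
  if (!all(need %in% names(df))) {
    abort(paste("fold_db needs columns:", paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0) abort("argument error: empty fold database")
  parts <- strsplit(as.character(df$label), ".", fixed = TRUE)
  if (any(lengths(parts) != 4))
    abort("every label must have exactly 4 dot-separated levels")
  ssm <- as.matrix(df[, ss_components()])
  if (any(abs(rowSums(ssm) - 1) > 1e-6) || any(ssm < -1e-9))
    abort("fold_db fractions must be valid simplex vectors")
  out <- as_tibble(df[, need])
  class(out) <- c("fold_db", class(out))
  out
}

#' Read / write a fold database as CSV
#'
#' @param file Path.
#' @return A `fold_db` (reader) or `file` invisibly (writer).
#' @export
read_fold_db <- function(file) {
  fold_db(read.table(file, header = TRUE, sep = ",",
                     stringsAsFactors = FALSE, check.names = FALSE))
}

#' @rdname read_fold_db
#' @param db A `fold_db`.
#' @export
write_fold_db <- function(db, file) {
  out <- as.data.frame(db)
  for (cc in ss_components()) out[[cc]] <- fmt_num(out[[cc]])
  write.table(out, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

db_ss_matrix <- function(db) as.matrix(db[, ss_components()])

label_prefix <- function(label, level) {
  parts <- strsplit(label, ".", fixed = TRUE)
  vapply(parts, function(p) paste(p[seq_len(level)], collapse = "."), "")
}

#' k closest structures in secondary-structure space
#'
#' Euclidean distance over the eight components; ties broken by id.
#'
#' @param query An [ss_vector()] or numeric length 8.
#' @param db A `fold_db`.
#' @param k Number of hits (default 20, the whole-PDB convention; 10 is
#'   used for single-domain searches).
#' @return Tibble of hits: `rank`, `id`, `distance`, `chain_length`,
#'   `label`.
#' @export
closest_k <- function(query, db, k = 20) {
  query <- ss_vector(query)
  if (k > nrow(db)) abort("k cannot exceed the database size")
  d <- sqrt(colSums((t(db_ss_matrix(db)) - as.numeric(query))^2))
  ord <- order(d, db$id)
  idx <- ord[seq_len(k)]
  tibble(rank = seq_len(k), id = db$id[idx], distance = d[idx],
         chain_length = db$chain_length[idx], label = db$label[idx])
}

#' Radius search with per-level fold frequencies
#'
#' A record is a hit when its composition differs from the query by at
#' most the per-component radius in *every* component (axis-aligned box;
#' set `mode = "ball"` for a Euclidean ball of radius `sqrt(sum(radii^2))`
#' instead).  Radii are usually taken as 1.5x the per-component RMSD of
#' the deconvolution on a reference set.  Hits are tallied by label prefix
#' at each of the four hierarchy levels.
#'
#' @param query An [ss_vector()].
#' @param db A `fold_db`.
#' @param radii Positive numeric, length 8 (or 1, recycled).
#' @param mode `"box"` (default) or `"ball"`.
#' @return List with `hits` (tibble of hit records with distances) and
#'   `frequencies` (tibble: `level`, `label`, `count`, sorted by count
#'   then label).
#' @export
radius_search <- function(query, db, radii, mode = c("box", "ball")) {
  mode <- match.arg(mode)
  query <- ss_vector(query)
  radii <- rep_len(as.numeric(radii), 8)
  if (any(radii <= 0)) abort("radii must be positive")
  dev <- abs(t(db_ss_matrix(db)) - as.numeric(query))
  inside <- if (mode == "box") {
    colSums(dev <= radii + 1e-12) == 8
  } else {
    sqrt(colSums(dev^2)) <= sqrt(sum(radii^2)) + 1e-12
  }
  hits <- db[inside, ]
  d <- sqrt(colSums(dev[, inside, drop = FALSE]^2))
  hits_tbl <- tibble(id = hits$id, distance = d,
                     chain_length = hits$chain_length, label = hits$label)
  hits_tbl <- hits_tbl[order(hits_tbl$distance, hits_tbl$id), ]
  freq <- purrr::map_dfr(1:4, function(v) {
    if (nrow(hits) == 0) {
      return(tibble(level = integer(), label = character(),
                    count = integer()))
    }
    tab <- table(label_prefix(hits$label, v))
    out <- tibble(level = v, label = names(tab), count = as.integer(tab))
    out[order(-out$count, out$label), ]
  })
  list(hits = hits_tbl, frequencies = freq)
}

#' Weighted k-nearest-neighbor fold prediction
#'
#' Scores each candidate label at each hierarchy level as the sum of
#' kernel weights of the neighbors carrying it; the default kernel is
#' `1/(d + 1e-9)` so closer structures dominate.  The per-level ranking
#' reports the top `n_top` labels.
#'
#' @param query An [ss_vector()].
#' @param db A `fold_db`.
#' @param k Number of neighbors (default 10).
#' @param kernel Weight function of the distance vector.
#' @param n_top Ranks to report per level (default 15, covering the
#'   conventional top-1/5/10/15 cuts).
#' @return Tibble: `level`, `rank`, `label`, `score`.
#' @export
wknn_predict <- function(query, db, k = 10,
                         kernel = function(d) 1 / (d + 1e-9), n_top = 15) {
  nn <- closest_k(query, db, k = k)
  w <- kernel(nn$distance)
  purrr::map_dfr(1:4, function(v) {
    pref <- label_prefix(nn$label, v)
    sc <- tapply(w, pref, sum)
    out <- tibble(level = v, label = names(sc), score = as.numeric(sc))
    out <- out[order(-out$score, out$label), ]
    out$rank <- seq_len(nrow(out))
    head(out[, c("level", "rank", "label", "score")], n_top)
  })
}

#' Construct an ordered/disordered reference
#'
#' Reference records hold CD values at one of the two canonical
#' wavelength triplets, 197-206-233 nm or 212-217-225 nm, with a binary
#' label.
#'
#' @param df Data frame with columns `id`, `w1`, `w2`, `w3`, `label`
#'   (values `"ordered"`/`"disordered"`).
#' @param wavelength_set `"197-206-233"` or `"212-217-225"`.
#' @return A `disorder_reference` tibble.
#' @export
disorder_reference <- function(df, wavelength_set = c("197-206-233",
                                                      "212-217-225")) {
  wavelength_set <- match.arg(wavelength_set)
  need <- c("id", "w1", "w2", "w3", "label")
  if (!all(need %in% names(df))) {
    abort(paste("disorder_reference needs columns:",
                paste(need, collapse = ", ")))
  }
  if (!all(df$label %in% c("ordered", "disordered")))
    abort("labels must be 'ordered' or 'disordered'")
  out <- as_tibble(df[, need])
  attr(out, "wavelength_set") <- wavelength_set
  class(out) <- c("disorder_reference", class(out))
  out
}

#' @rdname disorder_reference
#' @param file Path to a CSV with the reference columns plus a
#'   `wavelength_set` column (constant).
#' @export
read_disorder_reference <- function(file) {
  d <- read.table(file, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  ws <- unique(d$wavelength_set)
  if (length(ws) != 1) abort("wavelength_set must be consistent")
  disorder_reference(d, wavelength_set = ws)
}

#' @rdname disorder_reference
#' @param ref A `disorder_reference`.
#' @export
write_disorder_reference <- function(ref, file) {
  out <- as.data.frame(ref)
  out$wavelength_set <- attr(ref, "wavelength_set")
  for (cc in c("w1", "w2", "w3")) out[[cc]] <- fmt_num(out[[cc]])
  write.table(out, file, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(file)
}

triplet_wavelengths <- function(ref) {
  as.numeric(strsplit(attr(ref, "wavelength_set"), "-")[[1]])
}

#' Ordered/disordered classification of a CD spectrum
#'
#' Reduces the query to the reference's wavelength triplet (full spectra
#' are accepted) and takes a majority vote of the `k` nearest reference
#' records under the cosine distance
#' `d = 1 - (a . b)/(|a||b|)`, which makes the vote invariant to positive
#' rescaling of the query.  A tied vote is resolved conservatively to
#' `"disordered"` and flagged.
#'
#' @param query A `cd_spectrum`, or a numeric length-3 triplet in the
#'   reference's wavelength order.
#' @param ref A `disorder_reference`.
#' @param k Number of neighbors (default 10).
#' @return List with `label`, `tie` flag, and `votes` (tibble of the k
#'   neighbors: id, distance, label).
#' @export
classify_disorder <- function(query, ref, k = 10) {
  wl <- triplet_wavelengths(ref)
  q <- if (inherits(query, "cd_spectrum") || is.data.frame(query)) {
    idx <- match(wl, round(query$wavelength, 6))
    if (any(is.na(idx)))
      abort(sprintf("query spectrum must cover %s nm",
                    paste(wl, collapse = ", ")))
    query$value[idx]
  } else {
    if (length(query) != 3) abort("query triplet must have 3 values")
    as.numeric(query)
  }
  if (sqrt(sum(q^2)) == 0)
    abort("undefined distance: query triplet has zero norm")
  R <- as.matrix(ref[, c("w1", "w2", "w3")])
  nr <- sqrt(rowSums(R^2))
  if (any(nr == 0)) abort("undefined distance: zero-norm reference triplet")
  d <- 1 - as.numeric(R %*% q) / (nr * sqrt(sum(q^2)))
  ord <- order(d, ref$id)
  k <- min(k, nrow(ref))
  idx <- ord[seq_len(k)]
  votes <- tibble(id = ref$id[idx], distance = d[idx], label = ref$label[idx])
  n_dis <- sum(votes$label == "disordered")
  tie <- n_dis * 2 == k
  label <- if (n_dis * 2 >= k) "disordered" else "ordered"
  list(label = label, tie = tie, votes = votes)
}
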