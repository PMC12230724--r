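make_db <- function(n = 1000, seed = 91) gen_fold_db(
  n_per_fold = ceiling(n / 16), seed = seed)

test_that("closest-k matches an exhaustive sort", {
  db <- make_db(1000)
  q <- ss_vector(random_simplex(1, seed = 5)[1, ])
  got <- closest_k(q, db, k = 20)
  d <- sqrt(colSums((t(as.matrix(db[, ss_components()])) -
                       as.numeric(q))^2))
  ord <- order(d, db$id)
  expect_equal(got$id, db$id[ord[1:20]])
  expect_equal(got$distance, d[ord[1:20]])

  # a query equal to a record comes back first at distance zero
  q2 <- ss_vector(as.numeric(db[17, ss_components()]), normalize = TRUE)
  expect_equal(closest_k(q2, db, k = 1)$id, db$id[17])
  expect_equal(closest_k(q2, db, k = 1)$distance, 0, tolerance = 1e-12)

  all_hits <- closest_k(q, db, k = nrow(db))
  expect_equal(nrow(all_hits), nrow(db))
  expect_true(!is.unsorted(all_hits$distance))
  expect_error(closest_k(q, db, k = nrow(db) + 1), "exceed")
})

test_that("radius search is an axis-aligned box with level tallies", {
  db <- make_db(1000)
  q <- ss_vector(as.numeric(db[3, ss_components()]), normalize = TRUE)
  tiny <- radius_search(q, db, radii = rep(1e-9, 8))
  expect_true(db$id[3] %in% tiny$hits$id)

  res <- radius_search(q, db, radii = rep(0.05, 8))
  dev <- abs(t(as.matrix(db[, ss_components()])) - as.numeric(q))
  want <- sum(colSums(dev <= 0.05 + 1e-12) == 8)
  expect_equal(nrow(res$hits), want)
  for (v in 1:4) {
    lv <- res$frequencies[res$frequencies$level == v, ]
    expect_equal(sum(lv$count), nrow(res$hits))
  }
  # monotone in the radius
  res2 <- radius_search(q, db, radii = rep(0.10, 8))
  expect_true(all(res$hits$id %in% res2$hits$id))
  # far query: empty tables, not an error
  far <- ss_vector(as.numeric(1:8 == 5))
  res3 <- radius_search(far, db, radii = rep(1e-6, 8))
  expect_equal(nrow(res3$hits), 0)
})

test_that("WKNN scores match a brute-force kernel sum", {
  db <- make_db(1000)
  q <- ss_vector(random_simplex(1, seed = 6)[1, ])
  k <- 25
  got <- wknn_predict(q, db, k = k, n_top = 100)
  nn <- closest_k(q, db, k = k)
  w <- 1 / (nn$distance + 1e-9)
  for (v in 1:4) {
    pref <- vapply(strsplit(nn$label, ".", fixed = TRUE),
                   function(p) paste(p[1:v], collapse = "."), "")
    want <- sort(tapply(w, pref, sum), decreasing = TRUE)
    lv <- got[got$level == v, ]
    expect_equal(lv$score, as.numeric(want[lv$label]), tolerance = 1e-12)
    # parent scores dominate their children
    if (v > 1) {
      parent <- got[got$level == v - 1, ]
      for (r in seq_len(nrow(lv))) {
        pl <- paste(strsplit(lv$label[r], ".", fixed = TRUE)[[1]][1:(v - 1)],
                    collapse = ".")
        expect_gte(parent$score[parent$label == pl] + 1e-12, lv$score[r])
      }
    }
  }
  # coincident query with k = 1 wins every level
  q2 <- ss_vector(as.numeric(db[8, ss_components()]), normalize = TRUE)
  top <- wknn_predict(q2, db, k = 1)
  lab <- strsplit(db$label[8], ".", fixed = TRUE)[[1]]
  for (v in 1:4) {
    expect_equal(top$label[top$level == v & top$rank == 1],
                 paste(lab[1:v], collapse = "."))
  }
})

test_that("well-separated fold clusters are recovered near centroids", {
  db <- gen_fold_db(n_per_fold = 30, spread = 0.01, seed = 93)
  cents <- attr(db, "centroids")
  hits <- vapply(names(cents), function(lab) {
    pred <- wknn_predict(ss_vector(cents[[lab]], normalize = TRUE), db,
                         k = 10)
    pred$label[pred$level == 4 & pred$rank == 1] == lab
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("disorder classification matches the exhaustive cosine vote", {
  ref <- gen_disorder_ref(262, seed = 94)
  R <- as.matrix(ref[, c("w1", "w2", "w3")])
  set.seed(95)
  for (k in 1:100) {
    q <- rnorm(3)
    got <- classify_disorder(q, ref)
    d <- 1 - as.numeric(R %*% q) / (sqrt(rowSums(R^2)) * sqrt(sum(q^2)))
    nn <- order(d, ref$id)[1:10]
    n_dis <- sum(ref$label[nn] == "disordered")
    want <- if (n_dis * 2 >= 10) "disordered" else "ordered"
    expect_identical(got$label, want)
  }
})

test_that("disorder votes are scale-invariant and handle ties/edge cases", {
  ref <- gen_disorder_ref(262, seed = 96)
  q <- c(-4, -2.5, 0.3)
  a <- classify_disorder(q, ref)
  b <- classify_disorder(q * 37.5, ref)
  expect_identical(a$label, b$label)
  expect_equal(a$votes$distance, b$votes$distance, tolerance = 1e-12)
  # identical to a reference record: distance 0, and doubling it too
  r1 <- as.numeric(ref[1, c("w1", "w2", "w3")])
  v <- classify_disorder(r1 * 2, ref)$votes
  expect_equal(v$distance[v$id == ref$id[1]], 0, tolerance = 1e-12)
  expect_error(classify_disorder(c(0, 0, 0), ref), "zero norm")

  # constructed 5-5 tie resolves to disordered and is flagged
  tie_df <- data.frame(id = sprintf("t%02d", 1:10),
                       w1 = rep(c(1, 1), each = 5),
                       w2 = rep(c(0, 0), each = 5),
                       w3 = rep(c(0, 0), each = 5),
                       label = rep(c("ordered", "disordered"), each = 5))
  tie_ref <- disorder_reference(tie_df)
  out <- classify_disorder(c(1, 0, 0), tie_ref)
  expect_identical(out$label, "disordered")
  expect_true(out$tie)
})

test_that("fold and disorder references survive CSV round-trips", {
  db <- gen_fold_db(n_per_fold = 3, seed = 97)
  f <- withr::local_tempfile(fileext = ".csv")
  write_fold_db(db, f)
  back <- read_fold_db(f)
  expect_identical(back$id, db$id)
  expect_equal(as.matrix(back[, ss_components()]),
               as.matrix(db[, ss_components()]), tolerance = 1e-15)

  ref <- gen_disorder_ref(40, seed = 98)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_disorder_reference(ref, f2)
  back2 <- read_disorder_reference(f2)
  expect_identical(back2$label, ref$label)
  expect_identical(attr(back2, "wavelength_set"), attr(ref, "wavelength_set"))

  bad <- db; bad$label[1] <- "1.2.3"
  expect_error(fold_db(bad), "4 dot-separated")
})
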