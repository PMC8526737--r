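# Post-hoc connection statistics.

test_that("patch centroids are coordinate-wise means", {
  expect_equal(patch_centroid(matrix(c(1, 2, 3), 1)), c(1, 2, 3))
  expect_equal(patch_centroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  set.seed(2)
  vc <- matrix(rnorm(30), 10, 3)
  expect_equal(patch_centroid(vc), apply(vc, 2, mean))   # mean oracle
  expect_error(patch_centroid(matrix(numeric(0), 0, 3)), "at least one vertex")
})

test_that("connection distances are Euclidean norms", {
  expect_equal(connection_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(connection_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(connection_distance(a, b), sqrt(sum((a - b)^2)))
  }
  expect_error(connection_distance(c(Inf, 0, 0), c(0, 0, 0)), "finite")
})

test_that("length classes respect the 10/20 boundaries exactly", {
  expect_equal(as.character(classify_length(10)), "low")
  expect_equal(as.character(classify_length(20)), "medium")
  expect_equal(as.character(classify_length(20.01)), "long")
  expect_equal(as.character(classify_length(0)), "low")
  expect_error(classify_length(-1), "nonnegative")
  # classes partition any distance vector
  d <- runif(200, 0, 40)
  cl <- classify_length(d)
  expect_false(anyNA(cl))
  expect_equal(sum(table(cl)), 200)
})

test_that("hemisphere classification distinguishes inter from intra", {
  parc <- make_tiny_parcellation()
  expect_equal(as.character(classify_hemisphere(1, 4, parc)), "inter")
  expect_equal(as.character(classify_hemisphere(1, 2, parc)), "intra")
  expect_equal(as.character(classify_hemisphere(4, 1, parc)), "inter")  # order-invariant
  set.seed(4)
  i <- sample(1:6, 50, replace = TRUE); j <- sample(1:6, 50, replace = TRUE)
  cl <- classify_hemisphere(i, j, parc)
  oracle <- mapply(function(a, b) {                       # tally oracle
    if (parc$hemisphere[parc$patch_id == a] == parc$hemisphere[parc$patch_id == b])
      "intra" else "inter"
  }, i, j)
  expect_equal(as.character(cl), oracle)
  expect_error(classify_hemisphere(1, 99, parc), "not in parcellation")
})

test_that("percentages reproduce printed worked examples with half-up rounding", {
  expect_identical(proportion_pct(4, 89), 4.49)
  expect_identical(proportion_pct(27, 97), 27.84)
  expect_identical(proportion_pct(85, 89), 95.51)
  expect_identical(proportion_pct(0, 50), 0)
  # half-up, not banker's: 0.125 -> 12.50? use a case where round() differs
  expect_identical(proportion_pct(1, 800), 0.13)   # 0.125% rounds up
  expect_error(proportion_pct(1, 0), "total")
  expect_error(proportion_pct(5, 4), "count")
})

test_that("RSN co-occurrence conserves edges and matches a pair tally", {
  parc <- make_tiny_parcellation()
  one <- rsn_cooccurrence(make_edges(c(1, 2)), parc)     # both in network 5
  expect_equal(one$matrix[5, 5], 1)
  expect_equal(sum(one$matrix), 1)
  expect_equal(one$unassigned, 0)

  none <- rsn_cooccurrence(make_edges(integer(0)), parc)
  expect_true(all(none$matrix == 0))
  expect_equal(none$n_edges, 0)

  set.seed(5)
  pairs <- cbind(sample(1:6, 60, replace = TRUE), sample(1:6, 60, replace = TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  edges <- make_edges(t(pairs))
  co <- rsn_cooccurrence(edges, parc)
  # conservation
  expect_equal(sum(co$matrix) + co$unassigned, co$n_edges)
  # brute-force tally oracle
  Mo <- matrix(0L, 9, 9); un <- 0L
  for (e in seq_len(nrow(pairs))) {
    ra <- parc$rsn_label[parc$patch_id == pairs[e, 1]]
    rb <- parc$rsn_label[parc$patch_id == pairs[e, 2]]
    if (is.na(ra) || is.na(rb)) un <- un + 1L
    else Mo[min(ra, rb), max(ra, rb)] <- Mo[min(ra, rb), max(ra, rb)] + 1L
  }
  expect_equal(unname(co$matrix), Mo)
  expect_equal(co$unassigned, un)
  # mirrored display matrix is symmetric with same diagonal
  full <- rsn_matrix_full(co)
  expect_equal(full, t(full))
  expect_equal(diag(full), diag(co$matrix))
})

test_that("folding classes follow the curvature cut with 0.5 counted as gyrus", {
  parc <- make_tiny_parcellation()   # curvatures 0.7 0.9 0.3 0.5 0.2 0.8
  expect_equal(as.character(classify_folding(1, 2, parc)), "g-g")
  expect_equal(as.character(classify_folding(1, 3, parc)), "g-s")
  expect_equal(as.character(classify_folding(3, 5, parc)), "s-s")
  expect_equal(as.character(classify_folding(4, 1, parc)), "g-g")   # 0.5 boundary
  expect_equal(classify_folding(1, 3, parc), classify_folding(3, 1, parc))
  set.seed(6)
  i <- sample(1:6, 40, replace = TRUE); j <- sample(1:6, 40, replace = TRUE)
  cl <- classify_folding(i, j, parc)
  oracle <- mapply(function(a, b) {
    g <- c(parc$mean_curvature[parc$patch_id == a],
           parc$mean_curvature[parc$patch_id == b]) >= 0.5
    c("s-s", "g-s", "g-g")[sum(g) + 1]
  }, i, j)
  expect_equal(as.character(cl), oracle)
})

test_that("activation overlap is a (weighted) Jaccard over touched patches", {
  e1 <- make_edges(c(1, 2, 3, 4))
  expect_equal(unname(activation_overlap(e1, e1)), c(100, 100))
  e2 <- make_edges(c(5, 6))
  expect_equal(unname(activation_overlap(e1, e2)), c(0, 0))
  expect_error(activation_overlap(make_edges(integer(0)), make_edges(integer(0))),
               "empty")
  set.seed(7)
  for (rep in 1:10) {
    pf <- cbind(sample(1:8, 12, TRUE), sample(1:8, 12, TRUE))
    ps <- cbind(sample(1:8, 9, TRUE), sample(1:8, 9, TRUE))
    ef <- make_edges(t(pf)); es <- make_edges(t(ps))
    got <- activation_overlap(ef, es)
    # brute-force set/multiset oracle
    cf <- table(factor(c(pf), levels = 1:8))
    cs <- table(factor(c(ps), levels = 1:8))
    jac <- 100 * sum(cf > 0 & cs > 0) / sum(cf > 0 | cs > 0)
    wj <- 100 * sum(pmin(cf, cs)) / sum(pmax(cf, cs))
    expect_equal(unname(got["jaccard_pct"]), cclpp:::round_half_up(jac, 2))
    expect_equal(unname(got["weighted_pct"]), cclpp:::round_half_up(wj, 2))
    expect_true(all(got >= 0 & got <= 100))
  }
})

test_that("grouped connection summaries compare intra vs inter cell counts", {
  parc <- make_tiny_parcellation()  # areas A1 = {1,2}, A2 = {3,4}, A3 = {5,6}
  # all edges inside A1 -> inter-cell distribution all zeros
  s <- group_connection_summary(make_edges(c(1, 2, 1, 2)), parc, "atlas_area")
  expect_equal(s$intra, c(2L, 0L, 0L))
  expect_true(all(s$inter == 0))
  # identical intra and inter count distributions -> p = 1 (no effect)
  edges <- make_edges(c(1, 2,            # A1-A1
                        3, 4, 3, 4,      # A2-A2 twice
                        5, 6, 5, 6, 5, 6,# A3-A3 three times
                        1, 3,            # A1-A2
                        1, 5, 1, 5,      # A1-A3 twice
                        3, 5, 3, 5, 3, 5))# A2-A3 three times
  s2 <- group_connection_summary(edges, parc, "atlas_area")
  expect_equal(sort(s2$intra), sort(s2$inter))
  expect_equal(s2$p_value, 1, tolerance = 1e-12)
  # moments match direct recomputation
  expect_equal(s2$intra_mean, mean(s2$intra))
  expect_equal(s2$inter_sd, stats::sd(s2$inter))
  expect_error(group_connection_summary(edges, parc[0, ], "atlas_area"), "cells|patch")
})

test_that("annotate_connections combines all per-edge classifications", {
  parc <- make_tiny_parcellation()
  edges <- make_edges(c(1, 2, 1, 4, 2, 6), weights = c(0.5, -0.2, 0.1))
  ann <- annotate_connections(edges, parc)
  expect_equal(nrow(ann), 3)
  d12 <- sqrt(sum((c(-10, 0, 0) - c(-20, 5, 0))^2))
  expect_equal(ann$distance[1], d12)
  expect_equal(as.character(ann$hemi_class), c("intra", "inter", "inter"))
  expect_true(all(c("length_class", "fold_class", "rsn_i", "rsn_j") %in% names(ann)))
  # each edge gets exactly one length class (partition)
  expect_false(anyNA(ann$length_class))
})
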