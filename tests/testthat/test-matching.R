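# Patch weights, patch distance, bipartite matching, pocket scoring,
# search and ligand prediction.

test_that("dispersion weights reproduce hand-evaluated cases", {
  # avg (1,1,1,1), std (0,0,0,0.5): inverse denominators (1,1,1,1/2)
  w <- patchsurf:::.weights_from_stats(c(1, 1, 1, 1), c(0, 0, 0, 0.5))
  expect_equal(unname(w), c(2, 2, 2, 1) / 7, tolerance = 1e-12)
  # symmetric statistics: uniform weights
  w2 <- patchsurf:::.weights_from_stats(rep(0.3, 4), rep(0.1, 4))
  expect_equal(unname(w2), rep(0.25, 4))
  # degenerate zero-dispersion channel floors instead of dividing by zero
  w3 <- patchsurf:::.weights_from_stats(c(0, 1, 1, 1), c(0, 0, 0, 0))
  expect_true(all(is.finite(w3)))
  expect_gt(w3[1], 0.999)
})

test_that("compute_weights sums to one and favors stable channels", {
  set.seed(41)
  # equivalent patches: identical across channels except hyd, which varies
  # far more between group members
  base <- lapply(1:4, function(ch) rnorm(72))
  patches <- lapply(1:4, function(i) {
    toy_patch(shape = base[[1]] + rnorm(72, sd = 0.02),
              conc = base[[2]] + rnorm(72, sd = 0.02),
              ele = c(base[[3]], base[[4]]) + rnorm(144, sd = 0.02),
              hyd = rnorm(144))
  })
  w <- compute_weights(patches)
  expect_equal(sum(w), 1, tolerance = 1e-9)
  expect_true(all(w >= 0))
  expect_lt(w[["hyd"]], min(w[["shape"]], w[["ele"]], w[["conc"]]))
  expect_error(compute_weights(patches[1]), "at least two")
})

test_that("patch_distance implements the weighted channel sum", {
  a <- toy_patch(shape = c(1, 0, rep(0, 70)))
  b <- toy_patch(shape = c(0, 1, rep(0, 70)))
  # identical patches: zero
  expect_equal(patch_distance(a, a), 0)
  # shape-only weights: exactly the shape-channel L2 of unit vectors
  expect_equal(patch_distance(a, b, weights = c(shape = 1, hyd = 0,
                                                ele = 0, conc = 0)),
               sqrt(2))
  expect_equal(patch_distance(a, b, property_set = "shape"), sqrt(2))

  # two-element toy: hand-computed weighted sum over two channels
  p <- toy_patch(shape = c(3, 4, rep(0, 70)), conc = c(1, 0, rep(0, 70)))
  q <- toy_patch(shape = c(4, 3, rep(0, 70)), conc = c(0, 1, rep(0, 70)))
  # unit-normalized: shape L2 = |(.6,.8)-(.8,.6)| = sqrt(0.08)
  got <- patch_distance(p, q, weights = c(shape = 0.5, hyd = 0, ele = 0,
                                          conc = 0.5))
  expect_equal(got, 0.5 * sqrt(0.08) + 0.5 * sqrt(2), tolerance = 1e-12)

  bad <- toy_patch(shape = rnorm(36))
  expect_error(patch_distance(a, bad, weights = c(shape = 1, hyd = 0,
                                                  ele = 0, conc = 0)),
               "length mismatch")
})

test_that("the assignment solver is exact against permutation enumeration", {
  set.seed(43)
  for (n in 2:6) {
    for (rep in 1:4) {
      cost <- matrix(runif(n * n), n, n)
      got <- solve_assignment(cost)
      oracle <- brute_force_assignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), got)]), oracle$cost,
                   tolerance = 1e-12)
    }
  }
})

test_that("match_patches is optimal, one-to-one and threshold-aware", {
  set.seed(47)
  mk <- function(k) toy_pocket(lapply(seq_len(k), function(i) rnorm(72)))
  q <- mk(4)
  t <- mk(5)

  # pocket vs itself, no threshold: identity matching at distance zero
  self <- match_patches(q, q, threshold = NULL)
  expect_identical(nrow(self$pairs), 4L)
  expect_equal(self$pairs$distance, rep(0, 4))
  expect_identical(self$pairs$query, self$pairs$target)

  # optimality vs enumeration on the rectangular case: compare totals of
  # the full matching (all 4 query patches matched)
  m <- match_patches(q, t, threshold = NULL)
  expect_identical(nrow(m$pairs), 4L)
  M <- sapply(t$patches, function(tp) sapply(q$patches, function(qp) {
    patch_distance(qp, tp)
  }))
  # brute force over all ordered injections of 4 rows into 5 columns
  best <- Inf
  for (perm in combn(5, 4, simplify = FALSE)) {
    # enumerate orders of the chosen columns
    for (ord in list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2),
                     c(1,4,2,3), c(1,4,3,2), c(2,1,3,4), c(2,1,4,3),
                     c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
                     c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1),
                     c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                     c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))) {
      cols <- perm[ord]
      best <- min(best, sum(M[cbind(1:4, cols)]))
    }
  }
  expect_equal(sum(m$pairs$distance), best, tolerance = 1e-9)

  # tight threshold: no pairs, everything unmatched
  tiny <- match_patches(q, t, threshold = min(M) / 2)
  expect_identical(nrow(tiny$pairs), 0L)
  expect_length(tiny$unmatched_query, 4L)
  expect_length(tiny$unmatched_target, 5L)

  # threshold monotonicity; infinite threshold = no threshold
  taus <- quantile(M, c(0.2, 0.5, 0.8))
  counts <- sapply(taus, function(tau) {
    nrow(match_patches(q, t, threshold = tau)$pairs)
  })
  expect_true(all(diff(counts) >= 0))
  expect_identical(nrow(match_patches(q, t, threshold = Inf)$pairs), 4L)
  # with a threshold, every pair respects it
  mid <- match_patches(q, t, threshold = taus[2])
  expect_true(all(mid$pairs$distance <= taus[2]))
})

test_that("pocket_score combines the three terms as documented", {
  q <- toy_pocket(list(rnorm(72), rnorm(72)))
  expect_equal(pocket_score(match_patches(q, q, NULL), q, q), 0)

  # c = (1, 0, 0): score is the mean matched distance
  fake <- structure(list(
    pairs = data.frame(query = 1:2, target = 1:2,
                       distance = c(0.1, 0.3)),
    unmatched_query = integer(0), unmatched_target = integer(0),
    threshold = NULL), class = "patch_matching")
  expect_equal(pocket_score(fake, q, q, term_weights = c(1, 0, 0)), 0.2)

  # unmatched query patches raise the score when c2 > 0
  t3 <- toy_pocket(list(q$patches[[1]]$descriptors$shape,
                        q$patches[[2]]$descriptors$shape))
  q3 <- toy_pocket(list(q$patches[[1]]$descriptors$shape,
                        q$patches[[2]]$descriptors$shape,
                        rnorm(72) + 50))
  thr <- 0.05
  m2 <- match_patches(q, t3, thr)
  m3 <- match_patches(q3, t3, thr)
  expect_gt(pocket_score(m3, q3, t3), pocket_score(m2, q, t3))

  # empty matching ranks behind everything matched
  qa <- toy_pocket(list(c(1, rep(0, 71))))
  tb <- toy_pocket(list(c(0, 1, rep(0, 70))))
  me <- match_patches(qa, tb, threshold = 0.01)
  expect_identical(nrow(me$pairs), 0L)
  expect_equal(pocket_score(me, qa, tb, term_weights = c(1, 0.5, 0.5)),
               1 * 0.01 + 0.5)
})

test_that("search_database ranks deterministically and self-finds", {
  set.seed(53)
  fam_a <- lapply(1:3, function(i) {
    toy_pocket(lapply(1:2, function(k) c(rnorm(36, mean = 2), rep(0, 36))),
               source_id = sprintf("A%d", i), ligand_code = "AAA")
  })
  fam_b <- lapply(1:3, function(i) {
    toy_pocket(lapply(1:2, function(k) c(rep(0, 36), rnorm(36, mean = 2))),
               source_id = sprintf("B%d", i), ligand_code = "BBB")
  })
  db <- toy_database(c(fam_a, fam_b))

  r <- search_database(fam_a[[1]], db, threshold = NULL)
  expect_identical(r$pocket_id[1], "A1")
  expect_equal(r$score[1], 0)
  expect_true(all(diff(r$score) >= 0))
  # well-separated families: all A entries rank above all B entries
  expect_identical(r$ligand_code, c(rep("AAA", 3), rep("BBB", 3)))

  # order mismatch is rejected
  qbad <- fam_a[[1]]; qbad$order <- 10L
  expect_error(search_database(qbad, db), "order")
})

test_that("shape-only search ignores the other channels", {
  shp <- c(rnorm(36, mean = 2), rep(0, 36))
  mk <- function(id, lig, ele_shift) {
    p <- toy_pocket(list(shp), source_id = id, ligand_code = lig)
    p$patches[[1]]$descriptors$ele <- rep(ele_shift, 144)
    p
  }
  db <- toy_database(list(mk("E1", "EEE", 1), mk("F1", "FFF", 9)))
  q <- mk("Q", "QQQ", 5)
  r <- search_database(q, db, threshold = NULL, property_set = "shape")
  expect_equal(r$score[1], r$score[2])
})

test_that("predict_ligand aggregates reciprocal ranks over the top k", {
  r <- structure(data.frame(
    rank = 1:4, pocket_id = c("p1", "p2", "p3", "p4"),
    ligand_code = c("HEM", "ATP", "HEM", "GLC"),
    score = c(0.1, 0.2, 0.3, 0.4), stringsAsFactors = FALSE),
    class = c("retrieval_result", "data.frame"))
  pred <- predict_ligand(r, k = 3L)
  expect_identical(pred$ligand_code[1], "HEM")
  expect_equal(pred$score[pred$ligand_code == "HEM"], 1 + 1 / 3)
  expect_equal(pred$score[pred$ligand_code == "ATP"], 1 / 2)
  # k = 1: the top entry's ligand
  expect_identical(predict_ligand(r, 1L)$ligand_code[1], "HEM")
  # k beyond the ranking clamps with a warning
  expect_warning(pk <- predict_ligand(r, 10L), "clamped")
  expect_identical(pk$ligand_code[1], "HEM")
  expect_error(predict_ligand(r, 0L), "at least 1")
})
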