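test_that("transport solver agrees with the two-phase LP route", {
  set.seed(61)
  for (rep in 1:25) {
    n <- sample(1:8, 1); m <- sample(1:8, 1)
    d1 <- runif(n); d1 <- d1 / sum(d1)
    d2 <- runif(m); d2 <- d2 / sum(d2)
    C <- if (rep %% 3 == 0) matrix(sample(0:3, n * m, TRUE), n, m)
         else matrix(runif(n * m, 0, 5), n, m)
    if (rep %% 5 == 0) { d1 <- rep(1 / n, n); d2 <- rep(1 / m, m) }
    fast <- peerecho:::solve_transport(d1, d2, C)
    expect_equal(fast$status, "optimal")
    expect_lt(max(abs(rowSums(fast$flow) - d1)), 1e-8)
    expect_lt(max(abs(colSums(fast$flow) - d2)), 1e-8)
    expect_true(all(fast$flow >= -1e-12))
    lp <- peerecho:::solve_transport_lp(d1, d2, C)
    expect_equal(fast$objective, lp$objective, tolerance = 1e-8)
  }
})

test_that("exact WMD solves closed-form instances", {
  emb <- toy_embeddings()
  a <- nbow(c("exam", "stress"), emb)

  # identity of indiscernibles
  expect_equal(wmd_exact(a, a, emb)$objective, 0)

  # singleton documents: distance equals the word distance
  s1 <- nbow("exam", emb); s2 <- nbow("dog", emb)
  expect_equal(wmd_exact(s1, s2, emb)$objective,
               word_distance(emb, "exam", "dog"), tolerance = 1e-10)

  # any document versus a singleton: mass-weighted sum of distances
  b <- nbow(c("exam", "exam", "dog"), emb)
  expected <- (2 / 3) * word_distance(emb, "exam", "sad") +
    (1 / 3) * word_distance(emb, "dog", "sad")
  expect_equal(wmd_exact(b, nbow("sad", emb), emb)$objective, expected,
               tolerance = 1e-10)

  expect_error(wmd_exact(nbow("zzzq", emb), s1, emb), "empty document")
})

# 1-D instance with a hand-enumerated optimum: u=0, v=4 vs w=1, z=2;
# the 2x2 transport polytope is a segment, cost 2.5 - 2t minimized at
# t = 0.5 giving objective 1.5 via flow u->w 0.5, v->z 0.5.
line_embeddings <- function() {
  path <- tempfile()
  writeLines(c("4 2", "u 0 0", "v 4 0", "w 1 0", "z 2 0"), path)
  load_word2vec_text(path)
}

test_that("the 2x2 hand instance reproduces its enumerated optimum and bounds", {
  emb <- line_embeddings()
  a <- nbow(c("u", "v"), emb)
  b <- nbow(c("w", "z"), emb)
  plan <- wmd_exact(a, b, emb)
  expect_equal(plan$objective, 1.5, tolerance = 1e-10)
  expect_equal(plan$flow["u", "w"], 0.5, tolerance = 1e-10)
  expect_equal(plan$flow["v", "z"], 0.5, tolerance = 1e-10)

  # centroid bound: |(0.5*0 + 0.5*4) - (0.5*1 + 0.5*2)| = 0.5
  expect_equal(wcd_lower_bound(a, b, emb), 0.5, tolerance = 1e-12)
  # relaxed bound: nearest-neighbor assignment per side gives 1.5 each
  expect_equal(rwmd_lower_bound(a, b, emb), 1.5, tolerance = 1e-12)
  expect_equal(wcd_lower_bound(a, a, emb), 0)
  expect_equal(rwmd_lower_bound(a, a, emb), 0)

  # singletons: centroid bound is exact
  s1 <- nbow("u", emb); s2 <- nbow("z", emb)
  expect_equal(wcd_lower_bound(s1, s2, emb),
               wmd_exact(s1, s2, emb)$objective, tolerance = 1e-12)
})

test_that("returned transport plans conserve their marginals", {
  set.seed(71)
  emb <- random_embeddings(20L)
  for (i in 1:20) {
    a <- random_nbow(emb); b <- random_nbow(emb)
    plan <- wmd_exact(a, b, emb)
    expect_lt(max(abs(rowSums(plan$flow) - plan$source_weights)), 1e-8)
    expect_lt(max(abs(colSums(plan$flow) - plan$target_weights)), 1e-8)
    expect_gte(plan$objective, 0)
  }
})

test_that("centroid and relaxed bounds never exceed the exact distance", {
  set.seed(81)
  emb <- random_embeddings(25L)
  rwmd_tighter <- 0L
  for (i in 1:40) {
    a <- random_nbow(emb); b <- random_nbow(emb)
    wcd <- wcd_lower_bound(a, b, emb)
    rwmd <- rwmd_lower_bound(a, b, emb)
    wmd <- wmd_exact(a, b, emb)$objective
    expect_lte(wcd, wmd + 1e-9)
    expect_lte(rwmd, wmd + 1e-9)
    rwmd_tighter <- rwmd_tighter + (rwmd >= wcd)
  }
  # the relaxed bound is the tighter screen for most pairs (the two
  # bounds are not mutually ordered in general)
  expect_gt(rwmd_tighter, 20L)
})

test_that("WMD behaves as a metric on random non-degenerate instances", {
  set.seed(91)
  emb <- random_embeddings(18L)
  for (i in 1:15) {
    a <- random_nbow(emb); b <- random_nbow(emb); c <- random_nbow(emb)
    ab <- wmd_exact(a, b, emb)$objective
    ba <- wmd_exact(b, a, emb)$objective
    ac <- wmd_exact(a, c, emb)$objective
    cb <- wmd_exact(c, b, emb)$objective
    expect_lt(abs(ab - ba), 1e-9)
    expect_lte(ab, ac + cb + 1e-8)
    expect_equal(wmd_exact(a, a, emb)$objective, 0)
  }
})

test_that("small-document objectives match the independent LP oracle", {
  set.seed(101)
  emb <- random_embeddings(15L)
  pairs <- replicate(25, list(a = random_nbow(emb, 6L),
                              b = random_nbow(emb, 6L)), simplify = FALSE)
  probs <- lapply(pairs, function(p) wmd_problem(p$a, p$b, emb))
  oracle <- oracle_transport_batch(probs)
  ours <- vapply(pairs, function(p) wmd_exact(p$a, p$b, emb)$objective,
                 numeric(1))
  expect_lt(max(abs(ours - oracle)), 1e-6)
})

test_that("pruned ranking equals exhaustive exact ranking", {
  set.seed(111)
  emb <- random_embeddings(30L)
  for (rep in 1:5) {
    query <- random_nbow(emb, 8L)
    cands <- replicate(20, random_nbow(emb, 8L), simplify = FALSE)
    names(cands) <- sprintf("c%02d", seq_along(cands))
    for (top_m in c(1L, 3L, 20L, 25L)) {
      pruned <- prune_and_rank(query, cands, emb, top_m = top_m)
      exhaustive <- vapply(cands, function(d)
        wmd_exact(query, d, emb)$objective, numeric(1))
      ord <- order(exhaustive, names(cands))
      keep <- ord[seq_len(min(top_m, length(ord)))]
      expect_equal(pruned$post_id, names(cands)[keep])
      expect_equal(pruned$wmd, unname(exhaustive[keep]), tolerance = 1e-9)
    }
    audit <- attr(prune_and_rank(query, cands, emb, top_m = 1L), "audit")
    expect_setequal(audit$post_id, names(cands))
    expect_true(all(audit$outcome %in%
                      c("exact", "pruned-by-wcd", "pruned-by-rwmd")))
  }
})

test_that("a candidate identical to the query ranks first at distance zero", {
  emb <- toy_embeddings()
  query <- nbow(c("exam", "stress"), emb)
  cands <- list(self = query,
                other = nbow(c("dog", "cat"), emb),
                near = nbow(c("exam", "study"), emb))
  ranked <- prune_and_rank(query, cands, emb, top_m = 3L)
  expect_equal(ranked$post_id[1], "self")
  expect_equal(ranked$wmd[1], 0)
  # empty candidates are dropped; empty query is an error
  cands$void <- nbow("zzzq", emb)
  expect_equal(nrow(prune_and_rank(query, cands, emb, top_m = 10L)), 4L - 1L)
  expect_error(prune_and_rank(nbow("zzzq", emb), cands, emb),
               "empty document")
})
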