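# k-NN inference, micrograph aggregation with the conservative tie rule,
# embedding averaging, and validation-based k selection.

test_that("knn_classify_crops counts neighbors with the bad-on-tie rule", {
  sup <- embedding_set(matrix(c(0, 1, 10), 3, 1),
                       c("good", "good", "bad"), paste0("s", 1:3))
  # query identical to a support vector, k = 1
  q <- embedding_set(matrix(10, 1, 1), "unknown", "q1")
  r1 <- knn_classify_crops(sup, q, 1)
  expect_equal(r1$label, "bad")
  expect_equal(r1$good_fraction, 0)
  # k = 3, neighbors (good, good, bad)
  r3 <- knn_classify_crops(sup, q, 3)
  expect_equal(r3$label, "good")
  expect_equal(r3$good_fraction, 2 / 3)
  # k = 2 tie (good, bad) -> bad
  sup2 <- embedding_set(matrix(c(0, 2), 2, 1), c("good", "bad"), c("a", "b"))
  r2 <- knn_classify_crops(sup2, embedding_set(matrix(1, 1, 1), "unknown", "q"), 2)
  expect_equal(r2$label, "bad")
  expect_equal(r2$good_fraction, 0.5)
  expect_error(knn_classify_crops(sup2, q, 5), class = "cryoscreen_validation_error")
})

test_that("knn matches an exhaustive sort oracle and its limit laws", {
  set.seed(20)
  for (trial in 1:100) {
    n_sup <- sample(5:200, 1)
    n_good <- sample(seq_len(n_sup - 1), 1)
    sup <- random_embedding_set(n_good, n_sup - n_good, dim = 8L)
    qry <- random_embedding_set(3, 2, dim = 8L)
    k <- sample(seq_len(n_sup), 1)
    got <- knn_classify_crops(sup, qry, k)
    for (i in seq_len(5)) {
      d <- colSums((t(sup$vectors) - qry$vectors[i, ])^2)
      nb <- order(d, seq_along(d))[seq_len(k)]
      expect_equal(got$good_fraction[i], mean(sup$labels[nb] == "good"))
    }
  }
  # k = support size: every query sees global prevalence
  sup <- random_embedding_set(7, 3)
  out <- knn_classify_crops(sup, random_embedding_set(2, 2), 10)
  expect_true(all(out$good_fraction == 0.7))
  # duplicating every support vector with k doubled changes nothing
  sup2 <- embedding_set(rbind(sup$vectors, sup$vectors),
                        c(sup$labels, sup$labels),
                        c(sup$parent_ids, paste0(sup$parent_ids, "_dup")))
  q <- random_embedding_set(4, 4)
  expect_equal(knn_classify_crops(sup, q, 5)$good_fraction,
               knn_classify_crops(sup2, q, 10)$good_fraction)
})

test_that("micrograph aggregation votes with ties to bad", {
  # 2 good / 2 bad crops -> bad (conservative tie rule)
  agg <- aggregate_micrographs(rep("m1", 4), c("good", "good", "bad", "bad"),
                               c(1, 2/3, 1/3, 0))
  expect_equal(agg$decision, "bad")
  expect_equal(agg$score, 0.5)     # mean of the crop good-fractions
  expect_equal(agg$vote_good + agg$vote_bad, 4)
  # strict majority -> good
  expect_equal(aggregate_micrographs(rep("m", 4),
                                     c("good", "good", "good", "bad"),
                                     rep(0.75, 4))$decision, "good")
  # order invariance
  set.seed(21)
  ids <- rep(c("a", "b", "c"), each = 4)
  labs <- sample(c("good", "bad"), 12, replace = TRUE)
  gf <- runif(12)
  perm <- sample(12)
  a1 <- aggregate_micrographs(ids, labs, gf)
  a2 <- aggregate_micrographs(ids[perm], labs[perm], gf[perm])
  a2 <- a2[match(a1$micrograph_id, a2$micrograph_id), ]
  rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("average_micrograph_embeddings means crops per parent", {
  # 4 crops per parent, 89 good + 22 bad parents -> 356 + 88 crop rows in,
  # 89 + 22 micrograph rows out
  n_parents <- c(good = 89, bad = 22)
  ids <- unlist(lapply(names(n_parents), function(cl)
    rep(paste0(cl, seq_len(n_parents[[cl]])), each = 4)))
  labs <- sub("[0-9]+$", "", ids)
  set.seed(22)
  es <- embedding_set(matrix(rnorm(length(ids) * 5), length(ids), 5), labs, ids)
  avg <- average_micrograph_embeddings(es)
  expect_equal(nrow(avg$vectors), 111)
  expect_equal(sum(avg$labels == "good"), 89)
  expect_equal(sum(avg$labels == "bad"), 22)
  i <- which(avg$parent_ids == "good3")
  expect_equal(avg$vectors[i, ], colMeans(es$vectors[es$parent_ids == "good3", ]))

  # mean of identical crops is that vector; (v, -v) averages to zero
  v <- rnorm(4)
  es2 <- embedding_set(rbind(v, v, v, -v), rep(c("good", "bad"), c(2, 2)),
                       c("p", "p", "q", "q"))
  avg2 <- average_micrograph_embeddings(es2)
  expect_equal(avg2$vectors[1, ], v)
  expect_equal(avg2$vectors[2, ], rep(0, 4))
})

test_that("select_k maximizes validation AUPRC, ties to smallest k", {
  # singleton grid
  sup <- random_embedding_set(5, 5)
  val <- random_embedding_set(4, 4)
  expect_equal(select_k(sup, val, 1L), 1L)

  # constructed geometry: k = 1 trusts a mislabeled support outlier, k = 5
  # averages it away
  sup_v <- matrix(c(0, 0.2, 0.4, 0.6, 0.8, 10, 10.2, 10.4, 10.6, 0.05), 10, 1)
  sup2 <- embedding_set(sup_v, c(rep("good", 5), rep("bad", 5)),
                        paste0("s", 1:10))
  val_v <- matrix(c(0.06, 0.07, 0.08, 0.09, 10.1, 10.2, 10.3, 10.4), 8, 1)
  val2 <- embedding_set(val_v, rep(c("good", "bad"), each = 4),
                        rep(c("vg1", "vg2", "vb1", "vb2"), each = 2))
  expect_equal(select_k(sup2, val2, c(1L, 5L)), 5L)

  # identical performance across the grid -> smallest k
  sep_sup <- embedding_set(matrix(c(0, 0, 0, 9, 9, 9), 6, 1),
                           rep(c("good", "bad"), each = 3), paste0("s", 1:6))
  sep_val <- embedding_set(matrix(c(0.1, 0.2, 8.9, 8.8), 4, 1),
                           rep(c("good", "bad"), each = 2),
                           c("a", "a", "b", "b"))
  expect_equal(select_k(sep_sup, sep_val, c(1L, 3L)), 1L)
  expect_error(select_k(sep_sup, sep_val, c(1L, 99L)),
               class = "cryoscreen_validation_error")
})
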