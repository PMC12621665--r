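# Splits, episodes, average precision (against a brute-force oracle),
# normalized AUPRC, per-class precision/recall and the experiment runner.

test_that("make_splits stratifies, partitions, and is seed-deterministic", {
  man <- data.frame(micrograph_id = paste0("m", 1:100),
                    label = rep(c("good", "bad"), each = 50),
                    stringsAsFactors = FALSE)
  sp <- make_splits(man, c(0.6, 0.2, 0.2), seed = 1)
  expect_length(sp$train_ids, 60)
  expect_length(sp$val_ids, 20)
  expect_length(sp$test_ids, 20)
  all_ids <- c(sp$train_ids, sp$val_ids, sp$test_ids)
  expect_setequal(all_ids, man$micrograph_id)
  expect_equal(anyDuplicated(all_ids), 0)
  expect_identical(make_splits(man, seed = 1), sp)
  expect_false(identical(make_splits(man, seed = 2), sp))

  # stratification: 90/10 mix stays within one micrograph of 0.9 per split
  man2 <- data.frame(micrograph_id = paste0("m", 1:100),
                     label = rep(c("good", "bad"), c(90, 10)),
                     stringsAsFactors = FALSE)
  sp2 <- make_splits(man2, c(0.6, 0.2, 0.2), seed = 3)
  for (ids in list(sp2$train_ids, sp2$val_ids, sp2$test_ids)) {
    n_good <- sum(man2$label[match(ids, man2$micrograph_id)] == "good")
    expect_lte(abs(n_good - 0.9 * length(ids)), 1)
  }
  # impossible stratification
  tiny <- data.frame(micrograph_id = c("a", "b"), label = c("good", "bad"))
  expect_error(make_splits(tiny, c(0.6, 0.2, 0.2)),
               class = "cryoscreen_validation_error")
})

test_that("sample_episode draws per-class without replacement", {
  man <- fixture_dataset()$manifest
  sp <- make_splits(man, seed = 4)
  ep <- sample_episode(sp, man, 1, seed = 5)
  expect_length(ep$chosen_ids, 2)
  labs <- man$label[match(ep$chosen_ids, man$micrograph_id)]
  expect_setequal(labs, c("good", "bad"))
  expect_true(all(ep$chosen_ids %in% sp$train_ids))
  expect_identical(sample_episode(sp, man, 2, seed = 6)$chosen_ids,
                   sample_episode(sp, man, 2, seed = 6)$chosen_ids)
  expect_error(sample_episode(sp, man, 1000, seed = 5),
               class = "cryoscreen_validation_error")
})

test_that("average_precision follows the tied-block convention", {
  # perfect ranking
  expect_equal(average_precision(c(4, 3, 2, 1), c("good", "good", "bad", "bad")),
               1.0)
  # all scores tied: one block, AP = prevalence
  expect_equal(average_precision(rep(0.5, 10), rep(c("good", "bad"), c(9, 1))),
               0.9)
  # hand enumeration: blocks at ranks 1 and 3
  expect_equal(average_precision(c(0.9, 0.8, 0.7, 0.6),
                                 c("good", "bad", "good", "bad")),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_error(average_precision(c(1, 2), c("good", "good")),
               class = "cryoscreen_validation_error")
})

test_that("average_precision matches the brute-force oracle", {
  set.seed(30)
  for (trial in 1:200) {
    n <- sample(4:500, 1)
    # coarse scores force plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    labels <- sample(c("good", "bad"), n, replace = TRUE,
                     prob = c(runif(1, 0.1, 0.9), 1))
    if (length(unique(labels)) < 2) next
    expect_equal(average_precision(scores, labels),
                 ap_oracle(scores, labels), tolerance = 1e-9)
  }
})

test_that("constant-score AP equals prevalence; AP is rank-invariant", {
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(10:200, 1)
    n_pos <- sample(seq_len(n - 1), 1)
    labels <- sample(rep(c("good", "bad"), c(n_pos, n - n_pos)))
    expect_equal(average_precision(rep(1, n), labels), n_pos / n)
    # strictly increasing transform leaves AP unchanged
    scores <- runif(n)
    expect_equal(average_precision(scores, labels),
                 average_precision(exp(3 * scores) + 2, labels))
  }
})

test_that("auprc_gain divides by the majority proportion", {
  expect_equal(auprc_gain(0.988, 0.898), 0.988 / 0.898)
  expect_equal(round(auprc_gain(0.988, 0.898), 3), 1.1)
  expect_equal(auprc_gain(0.7, 1), 0.7)       # identity denominator
  expect_error(auprc_gain(0.5, 0), class = "cryoscreen_validation_error")
  # collapsed constant-score classifier on a majority-positive set: gain 1
  labels <- rep(c("good", "bad"), c(80, 20))
  ap <- average_precision(rep(0, 100), labels)
  expect_identical(auprc_gain(ap, 0.8), 1)
})

test_that("precision_recall_per_class handles collapse corners", {
  labs <- rep(c("good", "bad"), c(6, 4))
  perfect <- precision_recall_per_class(labs, labs)
  expect_equal(unlist(perfect[c("precision_good", "recall_good",
                                "precision_bad", "recall_bad")]),
               c(precision_good = 1, recall_good = 1,
                 precision_bad = 1, recall_bad = 1))
  collapsed <- precision_recall_per_class(rep("bad", 10), labs)
  expect_equal(collapsed$recall_bad, 1)
  expect_equal(collapsed$recall_good, 0)
  expect_equal(collapsed$precision_good, 0)
  expect_match(collapsed$flags, "precision_good")
  # hand confusion: TPg = 8, FPg = 2, FNg = 2
  dec <- rep(c("good", "good", "bad", "bad"), c(8, 2, 2, 3))
  lab <- rep(c("good", "bad", "good", "bad"), c(8, 2, 2, 3))
  pr <- precision_recall_per_class(dec, lab)
  expect_equal(pr$precision_good, 0.8)
  expect_equal(pr$recall_good, 0.8)
})

test_that("run_experiment produces a consistent, leakage-free grid", {
  ds <- fixture_dataset()
  cfg_train <- train_config(max_epochs = 1L, batches_per_epoch = 2L)
  res <- run_experiment(ds$manifest, model_config("tiny_cnn"), cfg_train,
                        inference_config(k_grid = c(1L, 3L)), tiny_preproc(),
                        shots_list = 1L, seeds = c(0L, 1L, 2L))
  # 3 seeds x 2 levels + 2 mean rows
  expect_equal(nrow(res), 8)
  expect_equal(sum(res$seed == "mean"), 2)
  # internal identity on every row
  expect_equal(res$auprc_gain, res$auprc / res$majority_proportion,
               tolerance = 1e-9)
  # leakage: episodes live entirely inside the train split
  split <- attr(res, "split")
  for (ep in attr(res, "episodes")) {
    expect_true(all(ep %in% split$train_ids))
    expect_length(intersect(ep, c(split$val_ids, split$test_ids)), 0)
  }
  expect_length(intersect(split$train_ids, split$test_ids), 0)
  expect_length(intersect(split$val_ids, split$test_ids), 0)
  # mean rows really are seed means
  sel <- res$level == "micrograph" & res$seed != "mean"
  expect_equal(res$auprc[res$level == "micrograph" & res$seed == "mean"],
               mean(res$auprc[sel]))
})
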