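# Evaluation: leakage-free micrograph-level splits, n-shot episodes,
# tied-block average precision, normalized AUPRC (Gain), per-class
# precision/recall and the multi-seed experiment runner.

#' Stratified micrograph-level splits
#'
#' Partitions a manifest into train/val/test at the micrograph level,
#' stratified by label (largest-remainder allocation per class), so no crop
#' of a held-out micrograph can ever reach training. Deterministic per seed.
#'
#' @param manifest data.frame with columns micrograph_id and label.
#' @param fractions numeric length-3 (train, val, test), summing to 1.
#' @param seed split seed.
#' @return a `split_spec` list with train_ids, val_ids, test_ids, seed.
#' @export
make_splits <- function(manifest, fractions = c(0.6, 0.2, 0.2), seed = 0L) {
  assert_that(length(fractions) == 3 && abs(sum(fractions) - 1) <= 1e-9,
              "fractions must be length 3 and sum to 1")
  assert_that(all(fractions >= 0), "fractions must be non-negative")
  ids <- list(train = character(0), val = character(0), test = character(0))
  for (cl in unique(manifest$label)) {
    members <- manifest$micrograph_id[manifest$label == cl]
    n <- length(members)
    raw <- fractions * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      take <- order(raw - sizes, c(3, 2, 1), decreasing = TRUE)[seq_len(rem)]
      sizes[take] <- sizes[take] + 1L
    }
    if (any(sizes == 0 & fractions > 0)) {
      stop_validation("impossible stratification: class '", cl, "' (n = ", n,
                      ") cannot populate every non-empty split")
    }
    shuffled <- with_seed(mix_seed(seed, "split", cl), sample(members))
    ids$train <- c(ids$train, shuffled[seq_len(sizes[1])])
    ids$val <- c(ids$val, shuffled[sizes[1] + seq_len(sizes[2])])
    ids$test <- c(ids$test, shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  structure(list(train_ids = ids$train, val_ids = ids$val,
                 test_ids = ids$test, seed = as.integer(seed)),
            class = "split_spec")
}

#' Sample an n-shot training episode
#'
#' Draws exactly `n_per_class` training micrographs per class, uniformly
#' without replacement, deterministic per seed. Validation and test sets
#' stay fixed; only the training subset varies across episodes.
#'
#' @param split a `split_spec` from [make_splits].
#' @param manifest the manifest data.frame.
#' @param n_per_class micrographs per class (the few-shot "n").
#' @param seed episode seed.
#' @return an `episode_spec` list with n_per_class, seed, chosen_ids.
#' @export
sample_episode <- function(split, manifest, n_per_class, seed = 0L) {
  assert_that(is_count(n_per_class) && n_per_class >= 1,
              "n_per_class must be >= 1")
  lab <- manifest$label[match(split$train_ids, manifest$micrograph_id)]
  chosen <- character(0)
  for (cl in sort(unique(manifest$label))) {
    members <- split$train_ids[lab == cl]
    if (length(members) < n_per_class) {
      stop_validation("class '", cl, "' has only ", length(members),
                      " training micrographs; cannot sample ", n_per_class)
    }
    chosen <- c(chosen,
                with_seed(mix_seed(seed, "episode", cl),
                          sample(members, n_per_class)))
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 seed = as.integer(seed), chosen_ids = chosen),
            class = "episode_spec")
}

#' Step-wise average precision with tied-score blocks
#'
#' Sorts by score descending and processes equal scores as a single block:
#' block precision is computed after including the whole block, and
#' AP = sum over blocks of (delta recall x block precision), with no
#' interpolation. Under this convention a constant-score classifier scores
#' exactly the positive-class prevalence.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels class labels aligned with scores.
#' @param positive the positive-class label (default "good").
#' @return AP in [0, 1].
#' @export
average_precision <- function(scores, labels, positive = "good") {
  assert_that(length(scores) == length(labels) && length(scores) >= 2,
              "scores and labels must align, length >= 2")
  assert_that(all(is.finite(scores)), "scores must be finite")
  y <- labels == positive
  P <- sum(y)
  assert_that(P >= 1 && P < length(y),
              "average precision needs at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  block_ends <- which(diff(s) != 0)
  block_ends <- c(block_ends, length(s))
  tp <- cumsum(y)[block_ends]
  n_at <- block_ends
  d_recall <- diff(c(0, tp)) / P
  sum(d_recall * (tp / n_at))
}

#' Normalized AUPRC (AUPRC Gain)
#'
#' AUPRC divided by the majority-class proportion of the evaluation set. The
#' denominator is exactly the AUPRC of a collapsed constant-score classifier
#' (under the tied-block convention), so values above 1 indicate genuine
#' discriminative ability.
#'
#' @param auprc AUPRC value.
#' @param majority_proportion majority-class proportion in (0, 1].
#' @return the gain, `auprc / majority_proportion`.
#' @export
auprc_gain <- function(auprc, majority_proportion) {
  assert_that(is.numeric(majority_proportion) && majority_proportion > 0 &&
                majority_proportion <= 1,
              "majority_proportion must be in (0, 1]")
  auprc / majority_proportion
}

#' One-vs-rest precision and recall for both classes
#'
#' @param decisions predicted labels ("good"/"bad").
#' @param labels true labels (both classes must occur).
#' @return list with precision_good, recall_good, precision_bad, recall_bad
#'   and a `flags` character vector naming any precision reported as 0
#'   because its class was never predicted.
#' @export
precision_recall_per_class <- function(decisions, labels) {
  assert_that(length(decisions) == length(labels), "inputs must align")
  assert_that(all(c("good", "bad") %in% labels), "both classes must be present")
  out <- list(flags = character(0))
  for (cl in c("good", "bad")) {
    tp <- sum(decisions == cl & labels == cl)
    fp <- sum(decisions == cl & labels != cl)
    fn <- sum(decisions != cl & labels == cl)
    if (tp + fp == 0) {
      out[[paste0("precision_", cl)]] <- 0
      out$flags <- c(out$flags, paste0("precision_", cl, ": no predictions"))
    } else out[[paste0("precision_", cl)]] <- tp / (tp + fp)
    out[[paste0("recall_", cl)]] <- tp / (tp + fn)
  }
  out
}

# subset a crop_batch by a logical or integer index over crops
subset_crop_batch <- function(batch, idx) {
  structure(list(real = batch$real[, , idx, drop = FALSE],
                 spec = batch$spec[, , idx, drop = FALSE],
                 labels = batch$labels[idx],
                 parent_ids = batch$parent_ids[idx],
                 crop_indices = batch$crop_indices[idx]),
            class = "crop_batch")
}

# metrics at one level from scores/decisions/labels
level_report <- function(scores, decisions, labels) {
  maj <- max(table(labels)) / length(labels)
  ap <- average_precision(scores, labels, positive = "good")
  pr <- precision_recall_per_class(decisions, labels)
  c(list(auprc = ap, auprc_gain = auprc_gain(ap, maj),
         majority_proportion = maj), pr[setdiff(names(pr), "flags")])
}

#' Run the full few-shot experiment grid
#'
#' For every shot count and every seed: sample an episode from the fixed
#' training split, train the embedding model on the episode's crops, select
#' k on the fixed validation split, classify the fixed test split, and
#' report crop-level and micrograph-level AUPRC, Gain and per-class
#' precision/recall. Seed-mean rows (`seed = "mean"`) are appended per
#' (level, n).
#'
#' @param manifest manifest data.frame or path (see [read_manifest]).
#' @param model_cfg a [model_config].
#' @param train_cfg a [train_config]; its seed is overridden per cell.
#' @param infer_cfg an [inference_config] (its k_grid feeds [select_k]).
#' @param preproc_cfg a [preprocess_config].
#' @param shots_list integer vector of micrographs per class.
#' @param seeds integer vector of experiment seeds (three seeds by default).
#' @param split optional precomputed `split_spec`; by default stratified
#'   (0.6, 0.2, 0.2) splits under the first seed.
#' @param dataset_name label for the `dataset` column.
#' @param out_csv optional path; the tidy results table is written there.
#' @return data.frame of results (one row per dataset x level x n x seed,
#'   plus mean rows).
#' @export
run_experiment <- function(manifest, model_cfg = model_config(),
                           train_cfg = train_config(),
                           infer_cfg = inference_config(),
                           preproc_cfg = preprocess_config(),
                           shots_list = c(1L, 5L), seeds = c(0L, 1L, 2L),
                           split = NULL, dataset_name = "synthetic",
                           out_csv = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  assert_that(length(seeds) >= 1, "need at least one seed")
  if (is.null(split)) split <- make_splits(manifest, seed = seeds[1])
  all_crops <- preprocess_manifest(manifest, preproc_cfg, seed = seeds[1])
  # crop labels must equal their parent's manifest label (leakage precursor)
  stopifnot(identical(all_crops$labels,
                      manifest$label[match(all_crops$parent_ids,
                                           manifest$micrograph_id)]))
  in_split <- function(ids) subset_crop_batch(all_crops,
                                              all_crops$parent_ids %in% ids)
  val_crops <- in_split(split$val_ids)
  test_crops <- in_split(split$test_ids)
  rows <- list()
  episodes <- list()
  histories <- list()
  for (n in shots_list) {
    for (sd_ in seeds) {
      episode <- sample_episode(split, manifest, n, seed = mix_seed(sd_, n))
      stopifnot(all(episode$chosen_ids %in% split$train_ids))
      cell <- sprintf("n=%d,seed=%s", n, sd_)
      episodes[[cell]] <- episode$chosen_ids
      train_crops <- in_split(episode$chosen_ids)
      cell_train_cfg <- train_cfg
      cell_train_cfg$seed <- mix_seed(sd_, "cell", n)
      model <- build_model(model_cfg, preproc_cfg$model_input_size,
                           seed = cell_train_cfg$seed)
      fit <- train_triplet(model, train_crops, val_crops, cell_train_cfg)
      histories[[cell]] <- fit$history
      support <- embed_crops(fit$model, train_crops, "eval")
      val_emb <- embed_crops(fit$model, val_crops, "eval")
      test_emb <- embed_crops(fit$model, test_crops, "eval")
      k_grid <- infer_cfg$k_grid[infer_cfg$k_grid <= nrow(support$vectors)]
      if (!length(k_grid)) k_grid <- nrow(support$vectors)
      k_sel <- select_k(support, val_emb, k_grid)
      res <- knn_classify_crops(support, test_emb, k_sel)
      crop_rep <- level_report(res$good_fraction, res$label, test_emb$labels)
      agg <- aggregate_micrographs(test_emb$parent_ids, res$label,
                                   res$good_fraction)
      mic_labels <- manifest$label[match(agg$micrograph_id,
                                         manifest$micrograph_id)]
      mic_rep <- level_report(agg$score, agg$decision, mic_labels)
      for (lvl in c("crop", "micrograph")) {
        rep_ <- if (lvl == "crop") crop_rep else mic_rep
        rows[[length(rows) + 1L]] <- data.frame(
          dataset = dataset_name, level = lvl, n_per_class = n,
          seed = as.character(sd_), auprc = rep_$auprc,
          auprc_gain = rep_$auprc_gain,
          majority_proportion = rep_$majority_proportion,
          precision_good = rep_$precision_good, recall_good = rep_$recall_good,
          precision_bad = rep_$precision_bad, recall_bad = rep_$recall_bad,
          k_selected = k_sel, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  num_cols <- c("auprc", "auprc_gain", "majority_proportion", "precision_good",
                "recall_good", "precision_bad", "recall_bad")
  for (n in shots_list) {
    for (lvl in c("crop", "micrograph")) {
      sel <- out$n_per_class == n & out$level == lvl & out$seed != "mean"
      mrow <- out[which(sel)[1], ]
      mrow$seed <- "mean"
      mrow[num_cols] <- colMeans(out[sel, num_cols, drop = FALSE])
      mrow$k_selected <- NA_integer_
      out <- rbind(out, mrow)
    }
  }
  rownames(out) <- NULL
  attr(out, "split") <- split
  attr(out, "episodes") <- episodes
  attr(out, "histories") <- histories
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
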