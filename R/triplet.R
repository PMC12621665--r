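# Triplet loss with online batch-hard mining, class-balanced batch
# composition, the training loop, and the cross-entropy baseline that
# demonstrates majority-class collapse in the few-shot regime.

#' Training configuration
#'
#' @param margin triplet margin alpha (> 0). Default 0.2, the common metric
#'   learning convention.
#' @param learning_rate Adam learning rate; default 1e-4.
#' @param optimizer only "adam".
#' @param batch_classes P, classes per batch (>= 2 for mining).
#' @param batch_samples K, crops per class per batch (>= 2 for mining);
#'   classes with fewer crops are sampled with replacement.
#' @param max_epochs maximum training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @param batches_per_epoch batches per epoch (episode pools are tiny, so an
#'   "epoch" is a fixed batch count rather than a data pass).
#' @param seed seed keying all training randomness.
#' @param distance only "squared_euclidean".
#' @param val_k neighbor count used for the per-epoch validation metric.
#' @return a `train_config` list.
#' @export
train_config <- function(margin = 0.2, learning_rate = 1e-4,
                         optimizer = "adam", batch_classes = 2L,
                         batch_samples = 8L, max_epochs = 100L,
                         patience = 10L, batches_per_epoch = 20L, seed = 0L,
                         distance = "squared_euclidean", val_k = 5L) {
  optimizer <- match.arg(optimizer, "adam")
  distance <- match.arg(distance, "squared_euclidean")
  assert_that(is.numeric(margin) && margin > 0, "margin must be > 0")
  assert_that(is.numeric(learning_rate) && learning_rate > 0,
              "learning_rate must be > 0")
  assert_that(is_count(batch_classes) && batch_classes >= 2,
              "batch_classes must be >= 2")
  assert_that(is_count(batch_samples) && batch_samples >= 2,
              "batch_samples must be >= 2")
  assert_that(is_count(max_epochs) && max_epochs >= 0, "max_epochs must be >= 0")
  assert_that(is_count(patience) && patience >= 1, "patience must be >= 1")
  assert_that(is_count(batches_per_epoch) && batches_per_epoch >= 1,
              "batches_per_epoch must be >= 1")
  structure(list(margin = margin, learning_rate = learning_rate,
                 optimizer = optimizer, batch_classes = as.integer(batch_classes),
                 batch_samples = as.integer(batch_samples),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batches_per_epoch = as.integer(batches_per_epoch),
                 seed = as.integer(seed), distance = distance,
                 val_k = as.integer(val_k)),
            class = "train_config")
}

#' Triplet loss (hinge on squared Euclidean distances)
#'
#' `max(0, d(a, p) - d(a, n) + margin)` with `d` the squared Euclidean
#' distance.
#'
#' @param anchor,positive,negative numeric vectors of equal length.
#' @param margin margin alpha.
#' @return non-negative scalar loss.
#' @export
triplet_loss <- function(anchor, positive, negative, margin = 0.2) {
  assert_that(length(anchor) == length(positive) &&
                length(anchor) == length(negative),
              "anchor, positive and negative must have equal dimension")
  dap <- sum((anchor - positive)^2)
  dan <- sum((anchor - negative)^2)
  max(0, dap - dan + margin)
}

# full pairwise squared-distance matrix of an N x D embedding matrix
pairwise_sqdist <- function(X) {
  sq <- rowSums(X * X)
  d <- outer(sq, sq, `+`) - 2 * tcrossprod(X)
  d[d < 0] <- 0
  d
}

#' Batch-hard triplet mining
#'
#' For every anchor whose class has at least two members in the batch,
#' selects the farthest same-class sample as positive and the nearest
#' other-class sample as negative (squared Euclidean distances; ties go to
#' the lowest index via `which.max` / `which.min`). Single-class batches and
#' batches with no valid anchor yield an empty result.
#'
#' @param batch an [embedding_set].
#' @param margin unused by the batch-hard scheme itself; accepted so callers
#'   can pass the full training configuration.
#' @return integer matrix with columns anchor, positive, negative (0 rows
#'   when no triplet exists).
#' @export
mine_hard_triplets <- function(batch, margin = 0.2) {
  assert_that(inherits(batch, "embedding_set"), "batch must be an embedding_set")
  lab <- batch$labels
  N <- length(lab)
  empty <- matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("anchor", "positive", "negative")))
  if (length(unique(lab)) < 2L) return(empty)
  D <- pairwise_sqdist(batch$vectors)
  out <- matrix(NA_integer_, N, 3)
  n_ok <- 0L
  for (i in seq_len(N)) {
    same <- which(lab == lab[i]); same <- same[same != i]
    if (!length(same)) next
    other <- which(lab != lab[i])
    pos <- same[which.max(D[i, same])]
    neg <- other[which.min(D[i, other])]
    n_ok <- n_ok + 1L
    out[n_ok, ] <- c(i, pos, neg)
  }
  if (n_ok == 0L) return(empty)
  out <- out[seq_len(n_ok), , drop = FALSE]
  colnames(out) <- c("anchor", "positive", "negative")
  out
}

#' Compose a class-balanced training batch
#'
#' Samples P classes, then K crops per class (with replacement when a class
#' holds fewer than K crops). Deterministic given `(seed, step)`.
#'
#' @param labels character vector of pool labels.
#' @param P classes per batch.
#' @param K crops per class.
#' @param seed,step batch stream key.
#' @return integer vector of pool indices (length P * K).
#' @export
compose_batch <- function(labels, P = 2L, K = 8L, seed = 0L, step = 0L) {
  classes <- unique(labels)
  assert_that(length(classes) >= 2L, "batch composition needs >= 2 classes in the pool")
  assert_that(P <= length(classes), "P = ", P, " exceeds available classes")
  with_seed(mix_seed(seed, "compose", step), {
    chosen <- if (length(classes) == P) sample(classes) else sample(classes, P)
    idx <- integer(0)
    for (cl in chosen) {
      members <- which(labels == cl)
      take <- if (length(members) >= K) sample(members, K)
              else members[sample.int(length(members), K, replace = TRUE)]
      idx <- c(idx, take)
    }
    idx
  })
}

# mean batch-hard triplet loss and its gradient wrt the embedding matrix
triplet_loss_and_grad <- function(E, triples, margin) {
  n_t <- nrow(triples)
  dE <- matrix(0, nrow(E), ncol(E))
  if (n_t == 0L) return(list(loss = NA_real_, dE = dE, n_active = 0L))
  losses <- numeric(n_t)
  for (t in seq_len(n_t)) {
    a <- triples[t, 1]; p <- triples[t, 2]; n <- triples[t, 3]
    va <- E[a, ]; vp <- E[p, ]; vn <- E[n, ]
    l <- sum((va - vp)^2) - sum((va - vn)^2) + margin
    if (l > 0) {
      losses[t] <- l
      g <- 2 / n_t
      dE[a, ] <- dE[a, ] + g * (vn - vp)
      dE[p, ] <- dE[p, ] - g * (va - vp)
      dE[n, ] <- dE[n, ] + g * (va - vn)
    }
  }
  list(loss = mean(losses), dE = dE, n_active = sum(losses > 0))
}

# micrograph-level average precision of k-NN classification, used as the
# per-epoch validation metric and by select_k
knn_val_auprc <- function(support, query, k) {
  res <- knn_classify_crops(support, query, k = k)
  agg <- aggregate_micrographs(query$parent_ids, res$label, res$good_fraction)
  lab <- vapply(split(query$labels, query$parent_ids)[agg$micrograph_id],
                `[`, "", 1)
  if (length(unique(lab)) < 2L) return(NA_real_)
  average_precision(agg$score, lab, positive = "good")
}

#' Train the embedding model with triplet loss and batch-hard mining
#'
#' Each step composes a class-balanced batch, embeds it in train mode, mines
#' batch-hard triplets, takes an Adam step on the mean triplet loss; each
#' epoch ends with a micrograph-level validation AUPRC (k-NN against the
#' training crops) used for best-checkpoint selection and early stopping.
#' Fully reproducible given `cfg$seed`.
#'
#' @param model an `embedding_model` from [build_model].
#' @param train_crops `crop_batch` of training crops (both classes required).
#' @param val_crops `crop_batch` of validation crops (parents disjoint from
#'   training parents).
#' @param cfg a [train_config].
#' @return list with elements `model` (best-validation weights), `history`
#'   (data.frame epoch / mean_loss / val_auprc_micrograph) and `last_grads`
#'   (gradients of the final step, for diagnostics).
#' @export
train_triplet <- function(model, train_crops, val_crops, cfg = train_config()) {
  assert_that(inherits(model, "embedding_model"), "model must be an embedding_model")
  assert_that(inherits(train_crops, "crop_batch") && inherits(val_crops, "crop_batch"),
              "crops must be crop_batch objects")
  assert_that(length(unique(train_crops$labels)) >= 2L,
              "triplet training needs both classes in the training set")
  leak <- intersect(unique(train_crops$parent_ids), unique(val_crops$parent_ids))
  assert_that(length(leak) == 0L,
              "leakage: micrographs in both train and val: ",
              paste(utils::head(leak, 3), collapse = ", "))
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0),
                        val_auprc_micrograph = numeric(0))
  if (cfg$max_epochs == 0L) {
    return(list(model = model, history = history, last_grads = NULL))
  }
  state <- list(real = adam_init_layers(model$stream_real),
                spec = adam_init_layers(model$stream_spec),
                head = adam_init_layers(model$head))
  best <- list(metric = -Inf, model = model)
  wait <- 0L
  t_global <- 0L
  last_grads <- NULL
  with_seed(mix_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      losses <- numeric(0)
      for (step in seq_len(cfg$batches_per_epoch)) {
        idx <- compose_batch(train_crops$labels, cfg$batch_classes,
                             cfg$batch_samples,
                             seed = mix_seed(cfg$seed, "batch", epoch), step = step)
        xr <- train_crops$real[, , idx, drop = FALSE]
        xs <- train_crops$spec[, , idx, drop = FALSE]
        fwd <- model_forward(model, xr, xs, "train")
        model <- fwd$model
        es <- embedding_set(fwd$emb, train_crops$labels[idx],
                            train_crops$parent_ids[idx],
                            train_crops$crop_indices[idx])
        triples <- mine_hard_triplets(es, cfg$margin)
        if (nrow(triples) == 0L) next
        lg <- triplet_loss_and_grad(fwd$emb, triples, cfg$margin)
        losses <- c(losses, lg$loss)
        if (lg$n_active == 0L) next
        grads <- model_backward(model, fwd$caches, lg$dE)
        last_grads <- grads
        t_global <- t_global + 1L
        up <- adam_update_layers(model$stream_real, grads$real, state$real,
                                 cfg$learning_rate, t_global)
        model$stream_real <- up$layers; state$real <- up$state
        up <- adam_update_layers(model$stream_spec, grads$spec, state$spec,
                                 cfg$learning_rate, t_global)
        model$stream_spec <- up$layers; state$spec <- up$state
        up <- adam_update_layers(model$head, grads$head, state$head,
                                 cfg$learning_rate, t_global)
        model$head <- up$layers; state$head <- up$state
      }
      support <- embed_crops(model, train_crops, "eval")
      queries <- embed_crops(model, val_crops, "eval")
      k <- min(cfg$val_k, nrow(support$vectors))
      val_auprc <- knn_val_auprc(support, queries, k)
      history <- rbind(history, data.frame(
        epoch = epoch,
        mean_loss = if (length(losses)) mean(losses) else NA_real_,
        val_auprc_micrograph = val_auprc))
      if (!is.na(val_auprc) && val_auprc > best$metric + 1e-12) {
        best <- list(metric = val_auprc, model = model)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  final <- if (is.finite(best$metric)) best$model else model
  list(model = final, history = history, last_grads = last_grads)
}

#' Cross-entropy baseline (majority-class collapse reference)
#'
#' Trains the same backbone with a 2-way softmax head on crop labels using
#' unweighted cross-entropy, then reports the predicted-class histogram on a
#' held-out set. In the few-shot regime this baseline tends to collapse onto
#' a single class, which is exactly what the histogram exposes.
#'
#' @param model a `crop_classifier` from `build_classifier`, or an
#'   [model_config] (a classifier is then built with `cfg$seed`).
#' @param train_crops,eval_crops `crop_batch` objects; `eval_crops` is the
#'   held-out set whose predictions are counted.
#' @param cfg a [train_config] (margin ignored).
#' @param input_size model input size when `model` is a config.
#' @return list with `model`, `history` (epoch / mean_loss), `pred_counts`
#'   (named counts of predicted micrograph classes on the held-out set) and
#'   `decisions` (per-micrograph decisions on the held-out set).
#' @export
train_crossentropy_baseline <- function(model, train_crops, eval_crops,
                                        cfg = train_config(), input_size = 64L) {
  if (inherits(model, "model_config")) {
    model <- build_classifier(model, input_size, seed = cfg$seed)
  }
  assert_that(inherits(model, "crop_classifier"),
              "model must be a crop_classifier or model_config")
  assert_that(length(unique(train_crops$labels)) >= 2L,
              "baseline training needs both classes")
  leak <- intersect(unique(train_crops$parent_ids), unique(eval_crops$parent_ids))
  assert_that(length(leak) == 0L, "leakage: micrographs in both train and eval")
  state <- list(real = adam_init_layers(model$stream_real),
                spec = adam_init_layers(model$stream_spec),
                head = adam_init_layers(model$head))
  history <- data.frame(epoch = integer(0), mean_loss = numeric(0))
  y <- ifelse(train_crops$labels == "good", 1L, 2L)  # logit columns
  B <- cfg$batch_classes * cfg$batch_samples
  n_pool <- length(train_crops$labels)
  t_global <- 0L
  with_seed(mix_seed(cfg$seed, "ce_train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      losses <- numeric(0)
      for (step in seq_len(cfg$batches_per_epoch)) {
        idx <- sample.int(n_pool, min(B, n_pool),
                          replace = n_pool < B)
        fwd <- classifier_forward(model, train_crops$real[, , idx, drop = FALSE],
                                  train_crops$spec[, , idx, drop = FALSE], "train")
        model <- fwd$model
        z <- fwd$emb
        zmax <- pmax(z[, 1], z[, 2])
        lse <- zmax + log(exp(z[, 1] - zmax) + exp(z[, 2] - zmax))
        yi <- y[idx]
        losses <- c(losses, mean(lse - z[cbind(seq_along(idx), yi)]))
        p <- exp(z - lse)            # softmax, recycled column-wise
        dz <- p
        dz[cbind(seq_along(idx), yi)] <- dz[cbind(seq_along(idx), yi)] - 1
        dz <- dz / length(idx)
        class(model) <- "embedding_model"
        grads <- model_backward(model, fwd$caches, dz)
        t_global <- t_global + 1L
        up <- adam_update_layers(model$stream_real, grads$real, state$real,
                                 cfg$learning_rate, t_global)
        model$stream_real <- up$layers; state$real <- up$state
        up <- adam_update_layers(model$stream_spec, grads$spec, state$spec,
                                 cfg$learning_rate, t_global)
        model$stream_spec <- up$layers; state$spec <- up$state
        up <- adam_update_layers(model$head, grads$head, state$head,
                                 cfg$learning_rate, t_global)
        model$head <- up$layers; state$head <- up$state
        class(model) <- "crop_classifier"
      }
      history <- rbind(history, data.frame(epoch = epoch,
                                           mean_loss = mean(losses)))
    }
  })
  p_good <- classifier_predict(model, eval_crops)
  crop_label <- ifelse(p_good > 0.5, "good", "bad")  # prob ties -> bad
  agg <- aggregate_micrographs(eval_crops$parent_ids, crop_label, p_good)
  counts <- table(factor(agg$decision, levels = c("good", "bad")))
  list(model = model, history = history,
       pred_counts = c(good = unname(counts["good"]), bad = unname(counts["bad"])),
       decisions = agg)
}
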