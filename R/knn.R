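# Few-shot inference: k-NN on crop embeddings against a labeled support set,
# validation-based k selection, and crop -> micrograph aggregation with the
# conservative tie rule (ties vote "bad").

#' Inference configuration
#'
#' @param k neighbor count.
#' @param k_grid strictly increasing candidate k values for [select_k]; odd
#'   defaults keep neighbor-vote ties rare.
#' @param distance only "euclidean".
#' @return an `inference_config` list.
#' @export
inference_config <- function(k = 5L, k_grid = c(1L, 3L, 5L, 7L, 9L),
                             distance = "euclidean") {
  distance <- match.arg(distance, "euclidean")
  assert_that(is_count(k) && k >= 1, "k must be >= 1")
  assert_that(length(k_grid) >= 1 && all(diff(k_grid) > 0),
              "k_grid must be strictly increasing")
  structure(list(k = as.integer(k), k_grid = as.integer(k_grid),
                 distance = distance),
            class = "inference_config")
}

#' Classify query crops by k nearest neighbors in embedding space
#'
#' For each query embedding, the k support rows with smallest Euclidean
#' distance vote on the label (distance ties broken by lower support index).
#' `good_fraction` is the fraction of good neighbors; the label is "good"
#' only on a strict majority (neighbor-vote ties resolve to "bad").
#'
#' @param support labeled [embedding_set] (labels in {good, bad}).
#' @param query [embedding_set] to classify.
#' @param k neighbor count (or an [inference_config] whose `k` is used).
#' @return data.frame with columns `label` and `good_fraction`, one row per
#'   query crop.
#' @export
knn_classify_crops <- function(support, query, k = 5L) {
  if (inherits(k, "inference_config")) k <- k$k
  assert_that(inherits(support, "embedding_set") && inherits(query, "embedding_set"),
              "support and query must be embedding_sets")
  n_sup <- nrow(support$vectors)
  assert_that(n_sup >= 1, "support set is empty")
  assert_that(all(support$labels %in% c("good", "bad")),
              "support labels must be good/bad")
  assert_that(is_count(k) && k >= 1 && k <= n_sup,
              "k = ", k, " must be between 1 and the support size ", n_sup)
  sq_s <- rowSums(support$vectors^2)
  sq_q <- rowSums(query$vectors^2)
  D <- outer(sq_q, sq_s, `+`) - 2 * tcrossprod(query$vectors, support$vectors)
  good <- support$labels == "good"
  gf <- apply(D, 1, function(drow) {
    nb <- order(drow, seq_along(drow))[seq_len(k)]
    sum(good[nb]) / k
  })
  data.frame(label = ifelse(gf > 0.5, "good", "bad"), good_fraction = gf,
             stringsAsFactors = FALSE)
}

#' Aggregate crop-level predictions into micrograph decisions
#'
#' Majority vote over crop labels (ties default to "bad", the conservative
#' filtering rule); the continuous micrograph score is the mean crop
#' good-fraction, used for precision-recall analysis.
#'
#' @param parent_ids character vector of parent micrograph ids per crop.
#' @param crop_labels predicted crop labels ("good"/"bad").
#' @param good_fractions per-crop good fractions in [0, 1].
#' @return data.frame with one row per micrograph: `micrograph_id`,
#'   `vote_good`, `vote_bad`, `decision`, `score`. Row order follows the
#'   first appearance of each parent id.
#' @export
aggregate_micrographs <- function(parent_ids, crop_labels, good_fractions) {
  N <- length(parent_ids)
  assert_that(N >= 1, "no crops to aggregate")
  assert_that(length(crop_labels) == N && length(good_fractions) == N,
              "inputs must have equal length")
  ids <- unique(parent_ids)
  rows <- lapply(ids, function(id) {
    sel <- parent_ids == id
    vg <- sum(crop_labels[sel] == "good")
    vb <- sum(sel) - vg
    data.frame(micrograph_id = id, vote_good = vg, vote_bad = vb,
               decision = if (vg > vb) "good" else "bad",
               score = mean(good_fractions[sel]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Average crop embeddings into micrograph-level embeddings
#'
#' One output row per distinct parent id, the arithmetic mean of that
#' micrograph's crop embeddings; labels are inherited from the crops.
#'
#' @param crops an [embedding_set].
#' @return an [embedding_set] with one row per micrograph.
#' @export
average_micrograph_embeddings <- function(crops) {
  assert_that(inherits(crops, "embedding_set"), "crops must be an embedding_set")
  assert_that(nrow(crops$vectors) >= 1, "empty embedding set")
  ids <- unique(crops$parent_ids)
  fac <- factor(crops$parent_ids, levels = ids)
  sums <- rowsum(crops$vectors, fac)
  counts <- as.vector(table(fac))
  vecs <- sums / counts
  labels <- vapply(ids, function(id) crops$labels[match(id, crops$parent_ids)], "")
  embedding_set(unname(vecs), labels, ids, rep(0L, length(ids)))
}

#' Select k by validation micrograph-level AUPRC
#'
#' Evaluates every candidate in `k_grid` on the validation crops and returns
#' the AUPRC-maximizing k; exact performance ties resolve to the smallest k.
#'
#' @param support labeled [embedding_set].
#' @param val_crops validation [embedding_set] (with parent ids and labels).
#' @param k_grid strictly increasing candidate values, all <= support size.
#' @return the selected integer k.
#' @export
select_k <- function(support, val_crops, k_grid = c(1L, 3L, 5L, 7L, 9L)) {
  assert_that(length(k_grid) >= 1, "k_grid is empty")
  assert_that(all(diff(k_grid) > 0), "k_grid must be strictly increasing")
  n_sup <- nrow(support$vectors)
  assert_that(all(k_grid <= n_sup),
              "k_grid values must not exceed the support size ", n_sup)
  scores <- vapply(k_grid, function(k) knn_val_auprc(support, val_crops, k),
                   numeric(1))
  assert_that(!all(is.na(scores)), "validation AUPRC undefined for every k")
  as.integer(k_grid[which.max(scores)])  # which.max: first (smallest k) on ties
}
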