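# Dual-input embedding model: two independent backbone streams (one for
# real-space crops, one for centered log power spectra), feature
# concatenation, then the embedding head: linear -> 256 -> ReLU ->
# dropout(0.5) -> linear -> 128 -> batch norm.

#' Embedding model configuration
#'
#' @param backbone "tiny_cnn" (a ~100k-parameter 4-block CNN that trains in
#'   minutes on CPU; the tested default) or "resnet18" (stem + 8 basic
#'   residual blocks; the documented full-scale choice).
#' @param pretrained logical; ImageNet initialization. Weight download is
#'   unsupported in this offline build, so `TRUE` errors at build time;
#'   `tiny_cnn` forbids it outright.
#' @param fusion only "two_stream_concat" is implemented: independent
#'   backbone weights per stream, features concatenated before the head.
#' @param hidden_dim hidden layer width (256).
#' @param embedding_dim output embedding dimension (128).
#' @param dropout_rate dropout probability in the head (0.5).
#' @return a `model_config` list.
#' @export
model_config <- function(backbone = c("tiny_cnn", "resnet18"),
                         pretrained = FALSE, fusion = "two_stream_concat",
                         hidden_dim = 256L, embedding_dim = 128L,
                         dropout_rate = 0.5) {
  backbone <- match.arg(backbone)
  fusion <- match.arg(fusion, "two_stream_concat")
  assert_that(is.logical(pretrained) && length(pretrained) == 1L,
              "pretrained must be a single logical")
  if (backbone == "tiny_cnn" && pretrained) {
    stop_validation("tiny_cnn has no pretrained weights; set pretrained = FALSE")
  }
  assert_that(is_count(hidden_dim) && hidden_dim >= 1, "hidden_dim must be >= 1")
  assert_that(is_count(embedding_dim) && embedding_dim >= 1,
              "embedding_dim must be >= 1")
  assert_that(is.numeric(dropout_rate) && dropout_rate >= 0 && dropout_rate < 1,
              "dropout_rate must be in [0, 1)")
  structure(list(backbone = backbone, pretrained = pretrained, fusion = fusion,
                 hidden_dim = as.integer(hidden_dim),
                 embedding_dim = as.integer(embedding_dim),
                 dropout_rate = dropout_rate),
            class = "model_config")
}

tiny_cnn_stream <- function() {
  widths <- c(8L, 16L, 32L, 64L)
  layers <- list()
  cin <- 1L
  for (w in widths) {
    layers <- c(layers, list(nn_conv(cin, w, 3L, 1L), nn_relu(), nn_maxpool2()))
    cin <- w
  }
  c(layers, list(nn_gap()))
}

resnet18_stream <- function() {
  layers <- list(nn_conv(1L, 64L, 7L, 2L, pad = 3L), nn_bn(64L, spatial = TRUE),
                 nn_relu(), nn_maxpool2())
  plan <- list(c(64L, 64L, 1L), c(64L, 64L, 1L),
               c(64L, 128L, 2L), c(128L, 128L, 1L),
               c(128L, 256L, 2L), c(256L, 256L, 1L),
               c(256L, 512L, 2L), c(512L, 512L, 1L))
  for (p in plan) layers <- c(layers, list(nn_resblock(p[1], p[2], p[3])))
  c(layers, list(nn_gap()))
}

backbone_feature_dim <- function(backbone) {
  switch(backbone, tiny_cnn = 64L, resnet18 = 512L)
}

#' Build a dual-input embedding model
#'
#' @param cfg a [model_config].
#' @param input_size side length of the (square) model inputs.
#' @param seed seed for weight initialization.
#' @return an `embedding_model` object.
#' @export
build_model <- function(cfg = model_config(), input_size = 64L, seed = 0L) {
  assert_that(inherits(cfg, "model_config"), "cfg must be a model_config")
  assert_that(is_count(input_size) && input_size >= 32, "input_size must be >= 32")
  if (cfg$pretrained) {
    stop_validation("pretrained = TRUE requires downloaded ImageNet weights, ",
                    "which are unavailable in this offline build")
  }
  fd <- backbone_feature_dim(cfg$backbone)
  with_seed(seed, {
    stream <- switch(cfg$backbone, tiny_cnn = tiny_cnn_stream,
                     resnet18 = resnet18_stream)
    structure(list(cfg = cfg, input_size = as.integer(input_size),
                   feature_dim = fd,
                   stream_real = stream(), stream_spec = stream(),
                   head = list(nn_linear(2L * fd, cfg$hidden_dim), nn_relu(),
                               nn_dropout(cfg$dropout_rate),
                               nn_linear(cfg$hidden_dim, cfg$embedding_dim),
                               nn_bn(cfg$embedding_dim))),
              class = "embedding_model")
  })
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> backbone = %s, input %d x %d, embedding dim %d\n",
              x$cfg$backbone, x$input_size, x$input_size, x$cfg$embedding_dim))
  invisible(x)
}

# Forward pass on arrays xr, xs of dim (H, W, N). Returns the (N x 128)
# embedding plus the caches needed for backprop and the (possibly updated,
# via batch-norm running stats) model.
model_forward <- function(model, xr, xs, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  dr <- dim(xr)
  assert_that(length(dr) == 3 && all(dim(xs) == dr),
              "real and spectrum inputs must share dim (H, W, N)")
  assert_that(dr[1] == model$input_size && dr[2] == dr[1],
              "inputs must be ", model$input_size, " x ", model$input_size,
              " (got ", dr[1], " x ", dr[2], ")")
  xr4 <- array(xr, dim = c(dr[1], dr[2], 1L, dr[3]))
  xs4 <- array(xs, dim = c(dr[1], dr[2], 1L, dr[3]))
  fr <- seq_forward(model$stream_real, xr4, mode)
  fs <- seq_forward(model$stream_spec, xs4, mode)
  feats <- cbind(fr$out, fs$out)
  fh <- seq_forward(model$head, feats, mode)
  model$stream_real <- fr$layers
  model$stream_spec <- fs$layers
  model$head <- fh$layers
  list(emb = fh$out, model = model,
       caches = list(real = fr$caches, spec = fs$caches, head = fh$caches))
}

# Backprop from an (N x 128) embedding gradient; returns per-stream grads.
model_backward <- function(model, caches, demb) {
  bh <- seq_backward(model$head, caches$head, demb)
  fd <- model$feature_dim
  d_real <- bh$dx[, seq_len(fd), drop = FALSE]
  d_spec <- bh$dx[, fd + seq_len(fd), drop = FALSE]
  br <- seq_backward(model$stream_real, caches$real, d_real)
  bs <- seq_backward(model$stream_spec, caches$spec, d_spec)
  list(head = bh$grads, real = br$grads, spec = bs$grads)
}

#' Construct an embedding set
#'
#' @param vectors N x D numeric matrix of embeddings.
#' @param labels length-N character vector in {good, bad, unknown}.
#' @param parent_ids length-N parent micrograph ids.
#' @param crop_indices length-N integer crop indices.
#' @return an `embedding_set`.
#' @export
embedding_set <- function(vectors, labels, parent_ids,
                          crop_indices = rep(0L, length(labels))) {
  assert_that(is.matrix(vectors) && all(is.finite(vectors)),
              "vectors must be a finite numeric matrix")
  N <- nrow(vectors)
  assert_that(length(labels) == N && length(parent_ids) == N &&
                length(crop_indices) == N,
              "labels, parent_ids and crop_indices must align with vectors")
  assert_that(all(labels %in% c("good", "bad", "unknown")),
              "labels must be good/bad/unknown")
  structure(list(vectors = vectors, labels = as.character(labels),
                 parent_ids = as.character(parent_ids),
                 crop_indices = as.integer(crop_indices)),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set> %d x %d (%s)\n", nrow(x$vectors), ncol(x$vectors),
              paste(sprintf("%s: %d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

#' Embed prepared crops
#'
#' Runs the model forward over a `crop_batch` (see [prepare_model_inputs]).
#' In eval mode the map is deterministic (dropout off, batch norm uses
#' accumulated statistics) and independent of how the batch is chunked.
#'
#' @param model an `embedding_model`.
#' @param crops a `crop_batch`.
#' @param mode "eval" or "train".
#' @param chunk_size forward-pass chunk size (memory control; does not affect
#'   eval-mode results).
#' @return an [embedding_set] (in train mode, attribute "model" carries the
#'   updated batch-norm state).
#' @export
embed_crops <- function(model, crops, mode = c("eval", "train"),
                        chunk_size = 64L) {
  mode <- match.arg(mode)
  assert_that(inherits(crops, "crop_batch"), "crops must be a crop_batch")
  dr <- dim(crops$real)
  assert_that(all(dim(crops$spec) == dr), "mixed input sizes in crop batch")
  assert_that(dr[1] == model$input_size && dr[2] == model$input_size,
              "crop batch size ", dr[1], " does not match model input size ",
              model$input_size)
  N <- dr[3]
  out <- matrix(0, N, model$cfg$embedding_dim)
  for (start in seq(1L, N, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, N)
    r <- model_forward(model, crops$real[, , idx, drop = FALSE],
                       crops$spec[, , idx, drop = FALSE], mode)
    out[idx, ] <- r$emb
    if (mode == "train") model <- r$model
  }
  es <- embedding_set(out, crops$labels, crops$parent_ids, crops$crop_indices)
  attr(es, "model") <- model
  es
}

#' Save / load model checkpoints
#'
#' Checkpoints are R's standard serialized container (RDS) holding the full
#' model (config, weights, batch-norm buffers), so reloads are shape-safe.
#'
#' @param model an `embedding_model`.
#' @param path checkpoint path.
#' @return `path` invisibly ([save_checkpoint]); the model ([load_checkpoint]).
#' @export
save_checkpoint <- function(model, path) {
  assert_that(inherits(model, c("embedding_model", "crop_classifier")),
              "model must be an embedding_model or crop_classifier")
  saveRDS(list(format = "cryoscreen_checkpoint", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  assert_that(identical(obj$format, "cryoscreen_checkpoint"),
              "not a cryoscreen checkpoint: ", path)
  obj$model
}

# Classifier variant for the cross-entropy baseline: same backbone streams,
# head's final layer swapped for a 2-way softmax.
build_classifier <- function(cfg = model_config(), input_size = 64L, seed = 0L) {
  emb <- build_model(cfg, input_size, seed)
  emb$head <- list(nn_linear(2L * emb$feature_dim, cfg$hidden_dim), nn_relu(),
                   nn_dropout(cfg$dropout_rate), nn_linear(cfg$hidden_dim, 2L))
  class(emb) <- "crop_classifier"
  emb
}

# Forward logits for the classifier (columns: good, bad).
classifier_forward <- function(model, xr, xs, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  class(model) <- "embedding_model"
  r <- model_forward(model, xr, xs, mode)
  class(r$model) <- "crop_classifier"
  r
}

# Per-crop class probabilities P(good) for a crop_batch.
classifier_predict <- function(model, crops, chunk_size = 64L) {
  dr <- dim(crops$real)
  N <- dr[3]
  p_good <- numeric(N)
  for (start in seq(1L, N, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, N)
    r <- classifier_forward(model, crops$real[, , idx, drop = FALSE],
                            crops$spec[, , idx, drop = FALSE], "eval")
    z <- r$emb
    p_good[idx] <- 1 / (1 + exp(z[, 2] - z[, 1]))
  }
  p_good
}
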