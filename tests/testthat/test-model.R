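# Embedding model: construction contracts, eval-mode determinism, batch-norm
# health, gradient flow, and an end-to-end finite-difference gradient check
# of the backprop implementation.

test_that("model_config enforces the architecture invariants", {
  cfg <- model_config()
  expect_equal(cfg$hidden_dim, 256L)
  expect_equal(cfg$embedding_dim, 128L)
  expect_equal(cfg$dropout_rate, 0.5)
  expect_error(model_config("tiny_cnn", pretrained = TRUE),
               class = "cryoscreen_validation_error")
  expect_error(build_model(model_config("resnet18", pretrained = TRUE)),
               "offline")
})

test_that("embeddings are 128-d, seeded-deterministic, and fast to build", {
  t0 <- proc.time()
  m <- build_model(model_config("tiny_cnn"), 64L, seed = 1)
  xr <- array(rnorm(64 * 64 * 3), c(64, 64, 3)); xs <- xr
  emb <- cryoscreen:::model_forward(m, xr, xs, "eval")$emb
  expect_lt((proc.time() - t0)[3], 1)          # smoke: < 1 s on one CPU
  expect_equal(dim(emb), c(3L, 128L))
  expect_true(all(is.finite(emb)))

  m2 <- build_model(model_config("tiny_cnn"), 64L, seed = 1)
  m3 <- build_model(model_config("tiny_cnn"), 64L, seed = 2)
  expect_identical(m$stream_real[[1]]$params$W, m2$stream_real[[1]]$params$W)
  expect_false(identical(m$stream_real[[1]]$params$W,
                         m3$stream_real[[1]]$params$W))
  # two streams do not share weights
  expect_false(identical(m$stream_real[[1]]$params$W,
                         m$stream_spec[[1]]$params$W))
})

test_that("resnet18 backbone builds and runs forward", {
  m <- build_model(model_config("resnet18"), 64L, seed = 0)
  xr <- array(rnorm(64 * 64 * 2), c(64, 64, 2))
  emb <- cryoscreen:::model_forward(m, xr, xr, "eval")$emb
  expect_equal(dim(emb), c(2L, 128L))
  expect_true(all(is.finite(emb)))
})

test_that("eval-mode embedding is deterministic and chunking-invariant", {
  model <- fixture_model()
  crops <- fixture_crops()
  sub <- subset_crops(crops, unique(crops$parent_ids)[1:4])
  e1 <- embed_crops(model, sub, "eval")
  e2 <- embed_crops(model, sub, "eval")
  expect_identical(e1$vectors, e2$vectors)
  # batch size 1 vs N give the same rows
  e_one <- embed_crops(model, sub, "eval", chunk_size = 1L)
  expect_equal(e1$vectors, e_one$vectors, tolerance = 1e-5)
  # a duplicated crop embeds identically
  dup <- cryoscreen:::subset_crop_batch(sub, c(1L, 1L, 2L))
  ed <- embed_crops(model, dup, "eval")
  expect_identical(ed$vectors[1, ], ed$vectors[2, ])
})

test_that("embeddings have healthy batch statistics on real inputs", {
  es <- embed_crops(fixture_model(), fixture_crops(), "eval")
  expect_true(all(is.finite(es$vectors)))
  v <- apply(es$vectors, 2, var)
  expect_true(all(is.finite(v)))
  expect_true(all(v > 0))
})

test_that("one training step produces gradients in both streams and head", {
  model <- fixture_model()
  crops <- fixture_crops()
  sub <- cryoscreen:::subset_crop_batch(crops, 1:8)
  fwd <- cryoscreen:::model_forward(model, sub$real, sub$spec, "train")
  demb <- matrix(rnorm(8 * 128), 8, 128)
  grads <- cryoscreen:::model_backward(fwd$model, fwd$caches, demb)
  expect_gt(cryoscreen:::grads_max_abs(grads$real), 0)
  expect_gt(cryoscreen:::grads_max_abs(grads$spec), 0)
  expect_gt(cryoscreen:::grads_max_abs(grads$head), 0)
})

test_that("analytic gradients match finite differences", {
  # dropout 0 so the train-mode forward is deterministic; loss = sum(emb * R)
  cfg <- model_config("tiny_cnn", dropout_rate = 0)
  model <- build_model(cfg, 32L, seed = 3)
  set.seed(4)
  xr <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  xs <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  R <- matrix(rnorm(4 * 128), 4, 128)
  loss_at <- function(m) {
    sum(cryoscreen:::model_forward(m, xr, xs, "train")$emb * R)
  }
  fwd <- cryoscreen:::model_forward(model, xr, xs, "train")
  grads <- cryoscreen:::model_backward(fwd$model, fwd$caches, R)
  eps <- 1e-5
  check <- function(path_set, path_get, analytic, label) {
    for (probe in 1:4) {
      i <- sample(length(path_get(model)), 1)
      m_plus <- path_set(model, i, eps); m_minus <- path_set(model, i, -eps)
      num <- (loss_at(m_plus) - loss_at(m_minus)) / (2 * eps)
      ana <- analytic[i]
      expect_equal(ana, num, tolerance = 1e-3,
                   label = paste(label, "entry", i))
    }
  }
  set.seed(5)
  # conv weights of the first real-stream layer
  check(function(m, i, d) { m$stream_real[[1]]$params$W[i] <-
          m$stream_real[[1]]$params$W[i] + d; m },
        function(m) m$stream_real[[1]]$params$W,
        grads$real[[1]]$W, "conv W")
  # head linear weights
  check(function(m, i, d) { m$head[[1]]$params$W[i] <-
          m$head[[1]]$params$W[i] + d; m },
        function(m) m$head[[1]]$params$W,
        grads$head[[1]]$W, "head linear W")
  # batch-norm gamma of the final layer
  check(function(m, i, d) { m$head[[5]]$params$gamma[i] <-
          m$head[[5]]$params$gamma[i] + d; m },
        function(m) m$head[[5]]$params$gamma,
        grads$head[[5]]$gamma, "bn gamma")
  # spectrum-stream conv bias
  check(function(m, i, d) { m$stream_spec[[4]]$params$b[i] <-
          m$stream_spec[[4]]$params$b[i] + d; m },
        function(m) m$stream_spec[[4]]$params$b,
        grads$spec[[4]]$b, "conv b")
})

test_that("checkpoints round-trip through save/load", {
  model <- fixture_model()
  crops <- subset_crops(fixture_crops(), unique(fixture_crops()$parent_ids)[1])
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(embed_crops(model, crops, "eval")$vectors,
                   embed_crops(back, crops, "eval")$vectors)
  suppressWarnings(
    expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds"))))
})
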