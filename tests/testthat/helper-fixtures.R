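# Shared fixtures, memoized per test run. Everything is generated in code at
# test time; nothing binary ships with the package.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixtures)) assign(key, fn(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# desk-scale preprocessing: 64 px micrographs, 32 px crops, 32 px model input
tiny_preproc <- function() {
  preprocess_config(crop_size = 32L, crops_per_micrograph = 4L,
                    crop_layout = "grid", model_input_size = 32L)
}

# small labeled dataset on disk (64 px, 10 good / 8 bad)
fixture_dataset <- function() {
  memo("dataset", function() {
    dir <- file.path(tempdir(), "cryoscreen_fixture_ds")
    cfg <- synthetic_config(image_size = 64L, n_good = 10L, n_bad = 8L,
                            particle_density = 10, seed = 42L)
    manifest_path <- generate_dataset(cfg, dir)
    list(dir = dir, cfg = cfg, manifest_path = manifest_path,
         manifest = read_manifest(manifest_path))
  })
}

# the fixture dataset preprocessed into a crop_batch
fixture_crops <- function() {
  memo("crops", function() {
    ds <- fixture_dataset()
    preprocess_manifest(ds$manifest, tiny_preproc(), seed = 1L)
  })
}

# an untrained tiny model matched to the fixture crops
fixture_model <- function() {
  memo("model", function() build_model(model_config("tiny_cnn"), 32L, seed = 1L))
}

subset_crops <- function(crops, parent_ids) {
  cryoscreen:::subset_crop_batch(crops, crops$parent_ids %in% parent_ids)
}

# random embedding_set with two classes for mining / k-NN tests
random_embedding_set <- function(n_good, n_bad, dim = 4L) {
  n <- n_good + n_bad
  embedding_set(matrix(stats::rnorm(n * dim), n, dim),
                c(rep("good", n_good), rep("bad", n_bad)),
                paste0("m", seq_len(n)))
}

# brute-force O(S^4) 2-D DFT power spectrum with DC shifted to the center
dft_power_oracle <- function(crop, epsilon) {
  S <- nrow(crop)
  ps <- matrix(0, S, S)
  for (u in 0:(S - 1)) {
    for (v in 0:(S - 1)) {
      acc <- 0 + 0i
      for (y in 0:(S - 1)) {
        for (x in 0:(S - 1)) {
          acc <- acc + crop[y + 1, x + 1] *
            exp(-2i * pi * (u * y / S + v * x / S))
        }
      }
      ps[u + 1, v + 1] <- Mod(acc)^2
    }
  }
  c_ <- floor(S / 2)
  shift <- function(i, S) ((i - 1 - c_) %% S) + 1
  log(epsilon + ps)[shift(seq_len(S), S), shift(seq_len(S), S)]
}

# brute-force O(n^2) average precision with tied-score blocks
ap_oracle <- function(scores, labels, positive = "good") {
  y <- labels == positive
  P <- sum(y)
  uscores <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_tp <- 0
  for (s in uscores) {
    included <- scores >= s          # whole tied block included
    tp <- sum(y & included)
    prec <- tp / sum(included)
    ap <- ap + (tp - prev_tp) / P * prec
    prev_tp <- tp
  }
  ap
}

# brute-force batch-hard mining by exhaustive distance search
mine_oracle <- function(es) {
  X <- es$vectors
  lab <- es$labels
  N <- nrow(X)
  if (length(unique(lab)) < 2) {
    return(matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("anchor", "positive", "negative"))))
  }
  d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
  out <- NULL
  for (i in seq_len(N)) {
    same <- setdiff(which(lab == lab[i]), i)
    if (!length(same)) next
    other <- which(lab != lab[i])
    dpos <- vapply(same, d2, numeric(1), i = i)
    dneg <- vapply(other, d2, numeric(1), i = i)
    out <- rbind(out, c(i, same[which.max(dpos)], other[which.min(dneg)]))
  }
  if (is.null(out)) out <- matrix(integer(0), 0, 3)
  colnames(out) <- c("anchor", "positive", "negative")
  out
}
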