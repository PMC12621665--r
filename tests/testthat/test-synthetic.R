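# Synthetic micrograph generator: determinism, defect signatures, dataset
# writing, and the class-separability guarantee the few-shot tests rely on.

test_that("generators are deterministic in (seed, kind, index)", {
  cfg <- synthetic_config(image_size = 64L, seed = 11L)
  expect_identical(generate_good(cfg, 3)$pixels, generate_good(cfg, 3)$pixels)
  expect_false(identical(generate_good(cfg, 3)$pixels,
                         generate_good(cfg, 4)$pixels))
  expect_identical(generate_bad(cfg, "drift", 0)$pixels,
                   generate_bad(cfg, "drift", 0)$pixels)
  expect_false(identical(generate_bad(cfg, "drift", 0)$pixels,
                         generate_bad(cfg, "contamination", 0)$pixels))
  expect_error(generate_bad(cfg, "vignetting", 0),
               class = "cryoscreen_validation_error")
})

test_that("particle-free good micrographs have near-zero spatial mean", {
  # mean of iid noise has sd = noise_sd / image_size; low-pass keeps DC gain 1
  cfg <- synthetic_config(image_size = 128L, particle_density = 0, seed = 5L)
  for (i in 0:4) {
    m <- generate_good(cfg, i)
    expect_lt(abs(mean(m$pixels)), 3 * cfg$noise_sd / cfg$image_size)
  }
})

test_that("crystalline-ice lattice produces sharp spectral peaks", {
  cfg <- synthetic_config(image_size = 128L, seed = 7L)
  m <- generate_bad(cfg, "ice_crystallinity", 0)
  ps <- power_spectrum(m$pixels, 1)
  n <- cfg$image_size; ctr <- n %/% 2 + 1
  # strongest off-DC bin vs the median of its surrounding frequency ring
  off <- ps; off[ctr + (-2:2), ctr + (-2:2)] <- -Inf
  peak <- which(off == max(off), arr.ind = TRUE)[1, ]
  r <- sqrt(sum((peak - ctr)^2))
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  ring <- abs(sqrt((yy - ctr)^2 + (xx - ctr)^2) - r) < 2
  ring[peak[1], peak[2]] <- FALSE
  expect_gt(ps[peak[1], peak[2]] - median(ps[ring]), 5)
})

test_that("drift blur makes the spectrum strongly anisotropic", {
  cfg <- synthetic_config(image_size = 128L, seed = 7L)
  sector_energy <- function(px) {
    ps <- power_spectrum(px, 1)
    n <- nrow(ps); ctr <- n %/% 2 + 1
    yy <- matrix(seq_len(n), n, n) - ctr; xx <- t(matrix(seq_len(n), n, n)) - ctr
    r <- sqrt(yy^2 + xx^2)
    band <- r > n / 8 & r < n / 4
    ang <- atan2(yy, xx) %% pi
    sectors <- floor(ang / (pi / 8))
    tapply(ps[band], sectors[band], mean)
  }
  for (i in 0:2) {
    se_bad <- sector_energy(generate_bad(cfg, "drift", i)$pixels)
    se_good <- sector_energy(generate_good(cfg, i)$pixels)
    expect_gt(max(se_bad) - min(se_bad), 2)     # log-units: strong anisotropy
    expect_lt(max(se_good) - min(se_good), 1)   # isotropic background
  }
})

test_that("generate_dataset writes a consistent, reproducible manifest", {
  cfg <- synthetic_config(image_size = 64L, n_good = 10L, n_bad = 10L, seed = 3L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- generate_dataset(cfg, d1)
  p2 <- generate_dataset(cfg, d2)
  man <- read_manifest(p1)
  expect_equal(nrow(man), 20)
  expect_equal(sum(man$label == "good"), 10)
  expect_equal(sum(man$label == "bad"), 10)
  expect_identical(readLines(p1), readLines(p2))  # byte-identical ordering

  # label purity via the provenance sidecar
  prov <- read.csv(file.path(d1, "provenance.csv"), stringsAsFactors = FALSE)
  merged <- merge(man, prov, by = "micrograph_id")
  expect_true(all((merged$generator == "generate_good") ==
                    (merged$label == "good")))

  # every generated grid round-trips through MRC unchanged
  for (i in c(1, 11)) {
    m <- read_micrograph(man$path[i], man$label[i], man$micrograph_id[i])
    src <- if (man$label[i] == "good") {
      generate_good(cfg, as.integer(sub(".*_", "", man$micrograph_id[i])))
    } else {
      kind <- sub("^bad_(.*)_[0-9]+$", "\\1", man$micrograph_id[i])
      generate_bad(cfg, kind, as.integer(sub(".*_", "", man$micrograph_id[i])))
    }
    expect_identical(m$pixels, src$pixels)
  }
})

test_that("defect classes are separable by a simple spectral statistic", {
  # Fisher score of a spectral-residual statistic between 50 good/bad pairs;
  # > 1 guarantees the downstream few-shot problems are well-posed
  cfg <- synthetic_config(image_size = 64L, seed = 13L)
  spec_stat <- function(px) {
    ps <- power_spectrum(px, 1)
    n <- nrow(ps); ctr <- n %/% 2 + 1
    yy <- matrix(seq_len(n), n, n) - ctr; xx <- t(matrix(seq_len(n), n, n)) - ctr
    r <- round(sqrt(yy^2 + xx^2))
    radial <- tapply(ps, r, median)
    resid <- ps - matrix(radial[as.character(r)], n, n)
    # peak excess over the isotropic profile + low-frequency excess: the
    # former catches lattices/drift/edges, the latter contamination blobs
    max(resid) + mean(ps[r >= 1 & r <= 4]) - mean(ps[r > 8 & r <= 16])
  }
  kinds <- cryoscreen:::with_seed(99,
    sample(c("ice_crystallinity", "contamination", "drift", "support_film"),
           50, replace = TRUE))
  s_good <- vapply(0:49, function(i) spec_stat(generate_good(cfg, i)$pixels),
                   numeric(1))
  s_bad <- vapply(seq_along(kinds),
                  function(i) spec_stat(generate_bad(cfg, kinds[i], i - 1)$pixels),
                  numeric(1))
  fisher <- (mean(s_good) - mean(s_bad))^2 / (var(s_good) + var(s_bad))
  expect_gt(fisher, 1)
})
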