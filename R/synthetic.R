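# Seeded synthetic micrograph simulator. The generators are analytic
# stand-ins for the common cryo-EM defect taxonomy -- crystalline ice,
# contamination, stage drift and support-film edges -- not physical
# simulation: each defect is an additive or convolutional operator with a
# controllable amplitude so downstream separability is a stated property of
# the generated world, not an accident.

DEFECT_KINDS <- c("ice_crystallinity", "contamination", "drift", "support_film")

#' Synthetic dataset configuration
#'
#' @param image_size side length of generated square micrographs (>= 64).
#' @param n_good,n_bad class counts.
#' @param defect_mix named probabilities over the four defect kinds
#'   (`ice_crystallinity`, `contamination`, `drift`, `support_film`); must sum
#'   to 1.
#' @param noise_sd standard deviation of the Gaussian shot-noise background.
#' @param particle_density expected number of particles per 256 x 256 pixel
#'   area (Poisson-distributed count).
#' @param amplitude_sigma defect amplitude in units of `noise_sd`; the
#'   default 3 gives clearly separable but noise-embedded defects.
#' @param seed base seed; every micrograph's random stream is derived from
#'   (seed, label, kind, index) so datasets are reproducible and extensible.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(image_size = 256L, n_good = 20L, n_bad = 20L,
                             defect_mix = c(ice_crystallinity = 0.25,
                                            contamination = 0.25,
                                            drift = 0.25,
                                            support_film = 0.25),
                             noise_sd = 1, particle_density = 30,
                             amplitude_sigma = 3, seed = 0L) {
  assert_that(is_count(image_size) && image_size >= 64, "image_size must be >= 64")
  assert_that(is_count(n_good) && n_good >= 0 && is_count(n_bad) && n_bad >= 0,
              "class counts must be non-negative integers")
  assert_that(n_good + n_bad >= 2, "need at least 2 micrographs in total")
  assert_that(all(sort(names(defect_mix)) == sort(DEFECT_KINDS)),
              "defect_mix must name exactly the four defect kinds")
  assert_that(abs(sum(defect_mix) - 1) <= 1e-9, "defect_mix must sum to 1")
  assert_that(all(defect_mix >= 0), "defect_mix must be non-negative")
  assert_that(is.numeric(noise_sd) && noise_sd > 0, "noise_sd must be > 0")
  assert_that(is.numeric(particle_density) && particle_density >= 0,
              "particle_density must be >= 0")
  assert_that(is.numeric(amplitude_sigma) && amplitude_sigma > 0,
              "amplitude_sigma must be > 0")
  structure(list(image_size = as.integer(image_size),
                 n_good = as.integer(n_good), n_bad = as.integer(n_bad),
                 defect_mix = defect_mix[DEFECT_KINDS], noise_sd = noise_sd,
                 particle_density = particle_density,
                 amplitude_sigma = amplitude_sigma, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Gaussian background noise with a mild isotropic low-pass envelope
# (unit DC gain, so the spatial mean is untouched) plus soft dark discs.
good_field <- function(cfg) {
  n <- cfg$image_size
  noise <- matrix(stats::rnorm(n * n, sd = cfg$noise_sd), n, n)
  # low-pass in Fourier space: gaussian envelope, cutoff ~ Nyquist/2
  f <- c(0:(floor(n / 2)), -((ceiling(n / 2) - 1):1)) / n
  r2 <- outer(f^2, f^2, `+`)
  env <- exp(-r2 / (2 * 0.25^2))
  filtered <- Re(stats::fft(stats::fft(noise) * env, inverse = TRUE)) / (n * n)
  # renormalize so the filtered noise keeps sd = noise_sd (DC gain stays 1)
  gain <- sqrt(mean(env^2))
  field <- (filtered - mean(filtered)) / gain + mean(filtered)
  k <- stats::rpois(1, cfg$particle_density * (n / 256)^2)
  if (k > 0) {
    radius <- n / 32
    cy <- stats::runif(k, 1, n); cx <- stats::runif(k, 1, n)
    yy <- seq_len(n)
    for (p in seq_len(k)) {
      d2 <- outer((yy - cy[p])^2, (yy - cx[p])^2, `+`)
      field <- field - 2 * cfg$noise_sd * exp(-d2 / (2 * radius^2))
    }
  }
  field
}

#' Generate one "good" synthetic micrograph
#'
#' Filtered Gaussian background plus randomly placed soft dark discs standing
#' in for particles. Deterministic given `(cfg$seed, index)`.
#'
#' @param cfg a [synthetic_config].
#' @param index non-negative integer identifying the micrograph.
#' @return a [micrograph] with label "good".
#' @export
generate_good <- function(cfg, index) {
  assert_that(is_count(index) && index >= 0, "index must be a non-negative integer")
  px <- with_seed(mix_seed(cfg$seed, "good", index), good_field(cfg))
  micrograph(id = sprintf("good_%04d", index), pixels = snap_float32(px),
             label = "good")
}

#' Generate one "bad" synthetic micrograph
#'
#' Starts from the corresponding good field and applies one defect operator:
#' \describe{
#'   \item{ice_crystallinity}{adds a two-frequency sinusoidal lattice
#'     (non-collinear wave vectors) producing sharp Bragg-like peaks in the
#'     power spectrum.}
#'   \item{contamination}{superposes one or more large dark soft-edged
#'     ellipses covering at least 10\% of the field.}
#'   \item{drift}{convolves with a line kernel of length `image_size / 8` at
#'     a random angle, giving a strongly anisotropic spectrum.}
#'   \item{support_film}{adds a high-contrast straight intensity step across
#'     the field.}
#' }
#' All amplitudes are `amplitude_sigma * noise_sd`. Deterministic given
#' `(cfg$seed, kind, index)`.
#'
#' @param cfg a [synthetic_config].
#' @param kind one of the four defect kinds.
#' @param index non-negative integer.
#' @return a [micrograph] with label "bad".
#' @export
generate_bad <- function(cfg, kind, index) {
  assert_that(is_count(index) && index >= 0, "index must be a non-negative integer")
  assert_that(is.character(kind) && length(kind) == 1L && kind %in% DEFECT_KINDS,
              "unknown defect kind: ", paste(kind, collapse = ","))
  n <- cfg$image_size
  amp <- cfg$amplitude_sigma * cfg$noise_sd
  px <- with_seed(mix_seed(cfg$seed, "bad", kind, index), {
    field <- good_field(cfg)
    yy <- seq_len(n) - 1
    switch(kind,
      ice_crystallinity = {
        # two non-collinear lattice frequencies, away from DC and Nyquist
        k1 <- sample(8:(n / 4), 2)
        k2 <- rev(k1) * c(1, -1)
        phase <- stats::runif(2, 0, 2 * pi)
        xmat <- matrix(yy, n, n, byrow = TRUE); ymat <- matrix(yy, n, n)
        field + amp * cos(2 * pi * (k1[1] * xmat + k1[2] * ymat) / n + phase[1]) +
          amp * cos(2 * pi * (k2[1] * xmat + k2[2] * ymat) / n + phase[2])
      },
      contamination = {
        # >= 10% coverage: semi-axes with pi*a*b >= 0.1 n^2
        a <- stats::runif(1, 0.25, 0.4) * n
        b <- pmax(0.1 * n^2 / (pi * a), 0.15 * n)
        cy <- stats::runif(1, 0.3, 0.7) * n; cx <- stats::runif(1, 0.3, 0.7) * n
        th <- stats::runif(1, 0, pi)
        xmat <- matrix(yy, n, n, byrow = TRUE); ymat <- matrix(yy, n, n)
        u <- (xmat - cx) * cos(th) + (ymat - cy) * sin(th)
        v <- -(xmat - cx) * sin(th) + (ymat - cy) * cos(th)
        d <- (u / a)^2 + (v / b)^2
        mask <- 1 / (1 + exp((d - 1) * 20))  # soft edge
        field - 2 * amp * mask
      },
      drift = {
        L <- max(ceiling(n / 8), ceiling(n / 16))
        th <- stats::runif(1, 0, pi)
        # line kernel as an image, applied by FFT convolution
        tpos <- seq(-(L - 1) / 2, (L - 1) / 2, length.out = L)
        ky <- round(tpos * sin(th)); kx <- round(tpos * cos(th))
        kern <- matrix(0, n, n)
        iy <- ((ky %% n) + n) %% n + 1; ix <- ((kx %% n) + n) %% n + 1
        for (t in seq_len(L)) kern[iy[t], ix[t]] <- kern[iy[t], ix[t]] + 1
        kern <- kern / sum(kern)
        blurred <- Re(stats::fft(stats::fft(field) * stats::fft(kern),
                                 inverse = TRUE)) / (n * n)
        # restore contrast scale so the blur signature is spectral shape
        blurred / stats::sd(blurred) * stats::sd(field)
      },
      support_film = {
        th <- stats::runif(1, 0, pi)
        off <- stats::runif(1, 0.35, 0.65) * n
        xmat <- matrix(yy, n, n, byrow = TRUE); ymat <- matrix(yy, n, n)
        proj <- xmat * cos(th) + ymat * sin(th)
        step <- 1 / (1 + exp(-(proj - off) / 1.5))  # near-sharp edge
        field + amp * (2 * step - 1)
      })
  })
  micrograph(id = sprintf("bad_%s_%04d", kind, index),
             pixels = snap_float32(px), label = "bad")
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_good + n_bad` MRC2014 files plus a manifest CSV (split column
#' empty; fill it with [make_splits]). Defect kinds are drawn from
#' `defect_mix` under the config seed. A sidecar `provenance.csv` records
#' which generator produced each file.
#'
#' @param cfg a [synthetic_config].
#' @param out_dir output directory (created if missing).
#' @return path to the manifest CSV, invisibly.
#' @export
generate_dataset <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_format("cannot create output directory: ", out_dir)
  kinds <- with_seed(mix_seed(cfg$seed, "kinds"),
                     sample(DEFECT_KINDS, cfg$n_bad, replace = TRUE,
                            prob = cfg$defect_mix))
  rows <- list(); prov <- list()
  emit <- function(m, generator) {
    fn <- paste0(m$id, ".mrc")
    write_micrograph(m, file.path(out_dir, fn))
    # label purity check: generator route must match the label written
    stopifnot(identical(generator == "generate_good", m$label == "good"))
    rows[[length(rows) + 1L]] <<- data.frame(
      micrograph_id = m$id, path = fn, label = m$label, split = "",
      stringsAsFactors = FALSE)
    prov[[length(prov) + 1L]] <<- data.frame(
      micrograph_id = m$id, generator = generator, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$n_good)) emit(generate_good(cfg, i - 1L), "generate_good")
  for (i in seq_len(cfg$n_bad)) {
    emit(generate_bad(cfg, kinds[i], i - 1L), "generate_bad")
  }
  manifest <- do.call(rbind, rows)
  path <- file.path(out_dir, "manifest.csv")
  write_manifest(manifest, path)
  utils::write.csv(do.call(rbind, prov), file.path(out_dir, "provenance.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
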