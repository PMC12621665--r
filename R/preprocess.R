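# Preprocessing: intensity normalization, crop extraction, centered
# log-scaled power spectra, display binning and model-input resizing.

#' Preprocessing configuration
#'
#' @param crop_size side length S of square real-space crops, in pixels.
#' @param crops_per_micrograph number of crops C extracted per micrograph.
#'   The default of 4 matches the crop-to-micrograph count ratio used during
#'   evaluation (four crops per exposure).
#' @param crop_layout "grid" tiles a centered ceiling(sqrt(C)) lattice of
#'   non-overlapping (where possible) windows; "random" samples top-left
#'   corners uniformly under a caller-supplied seed.
#' @param clip_sigma hot-pixel guard: values further than `clip_sigma`
#'   standard deviations from the mean are clipped before standardization.
#' @param spectrum_epsilon epsilon inside `log(epsilon + |F|^2)`.
#' @param model_input_size side length the network sees; crops and spectra are
#'   bilinearly resized to this size.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(crop_size = 512L, crops_per_micrograph = 4L,
                              crop_layout = c("grid", "random"),
                              clip_sigma = 5, spectrum_epsilon = 1,
                              model_input_size = 224L) {
  crop_layout <- match.arg(crop_layout)
  assert_that(is_count(crop_size) && crop_size >= 2, "crop_size must be >= 2")
  assert_that(is_count(crops_per_micrograph) && crops_per_micrograph >= 1,
              "crops_per_micrograph must be >= 1")
  assert_that(is.numeric(clip_sigma) && clip_sigma > 0, "clip_sigma must be > 0")
  assert_that(is.numeric(spectrum_epsilon) && spectrum_epsilon > 0,
              "spectrum_epsilon must be > 0")
  assert_that(is_count(model_input_size) && model_input_size >= 32,
              "model_input_size must be >= 32")
  structure(list(crop_size = as.integer(crop_size),
                 crops_per_micrograph = as.integer(crops_per_micrograph),
                 crop_layout = crop_layout, clip_sigma = clip_sigma,
                 spectrum_epsilon = spectrum_epsilon,
                 model_input_size = as.integer(model_input_size)),
            class = "preprocess_config")
}

#' Standardize micrograph intensities with a hot-pixel guard
#'
#' Values beyond `clip_sigma` standard deviations from the mean are clipped,
#' then the grid is standardized to mean 0 and standard deviation 1. A
#' zero-variance grid maps to all zeros.
#'
#' @param m a [micrograph] or a numeric matrix.
#' @param clip_sigma positive clipping threshold in standard deviations.
#' @return same type as the input, with standardized pixels.
#' @export
normalize_intensities <- function(m, clip_sigma = 5) {
  assert_that(is.numeric(clip_sigma) && clip_sigma > 0, "clip_sigma must be > 0")
  px <- if (inherits(m, "micrograph")) m$pixels else m
  assert_that(is.matrix(px) && is.numeric(px), "pixels must be a numeric matrix")
  assert_that(all(is.finite(px)), "pixels must be finite")
  out <- standardize_grid(px, clip_sigma)
  if (inherits(m, "micrograph")) {
    m$pixels <- out
    m
  } else out
}

standardize_grid <- function(px, clip_sigma = NULL) {
  s <- stats::sd(as.vector(px))
  if (!is.finite(s) || s == 0) return(array(0, dim = dim(px)))
  if (!is.null(clip_sigma)) {
    mu <- mean(px)
    px <- pmin(pmax(px, mu - clip_sigma * s), mu + clip_sigma * s)
    s <- stats::sd(as.vector(px))
    if (s == 0) return(array(0, dim = dim(px)))
  }
  (px - mean(px)) / s
}

#' Centered log-scaled power spectrum of a square crop
#'
#' Computes `log(epsilon + |DFT(crop)|^2)` and shifts the zero-frequency bin
#' to the center pixel (0-based index `floor(S/2)` in both dimensions).
#'
#' @param crop finite square numeric matrix.
#' @param epsilon positive stabilizer inside the log.
#' @return S x S matrix of centered log power.
#' @export
power_spectrum <- function(crop, epsilon = 1) {
  assert_that(is.matrix(crop) && is.numeric(crop), "crop must be a numeric matrix")
  assert_that(nrow(crop) == ncol(crop),
              "crop must be square (got ", nrow(crop), " x ", ncol(crop), ")")
  assert_that(all(is.finite(crop)), "crop must be finite")
  assert_that(is.numeric(epsilon) && epsilon > 0, "epsilon must be > 0")
  p <- Mod(stats::fft(crop))^2
  fftshift2(log(epsilon + p))
}

# Move the DC bin (index 1,1) to 1-based index (floor(S/2)+1, floor(S/2)+1).
fftshift2 <- function(x) {
  S1 <- nrow(x); S2 <- ncol(x)
  i <- ((seq_len(S1) - 1 - floor(S1 / 2)) %% S1) + 1L
  j <- ((seq_len(S2) - 1 - floor(S2 / 2)) %% S2) + 1L
  # shifted[u, v] = x[((u - c) mod S) + 1, ...]
  x[i, j, drop = FALSE]
}

#' Extract real-space crops and their power spectra from a micrograph
#'
#' Grid layout places a centered `ceiling(sqrt(C))`-by-`ceiling(sqrt(C))`
#' lattice of S x S windows (non-overlapping whenever the lattice fits) and
#' takes the first C cells in row-major order; random layout samples top-left
#' corners uniformly. Windows use 0-based half-open pixel ranges. Each crop's
#' spectrum is computed from the raw crop before any resizing.
#'
#' @param m a [micrograph].
#' @param cfg a [preprocess_config].
#' @param seed seed for the random layout (ignored for grid).
#' @return list of `crop_pair` objects, each with fields `parent_id`,
#'   `crop_index` (0-based), `real_crop`, `spectrum`, `label`.
#' @export
extract_crops <- function(m, cfg = preprocess_config(), seed = 0L) {
  assert_that(inherits(m, "micrograph"), "m must be a micrograph")
  H <- nrow(m$pixels); W <- ncol(m$pixels)
  S <- cfg$crop_size; C <- cfg$crops_per_micrograph
  assert_that(S <= min(H, W),
              "crop_size ", S, " exceeds micrograph extent ", min(H, W))
  corners <- if (cfg$crop_layout == "grid") {
    grid_corners(H, W, S, C)
  } else {
    with_seed(seed, cbind(sample.int(H - S + 1L, C, replace = TRUE) - 1L,
                          sample.int(W - S + 1L, C, replace = TRUE) - 1L))
  }
  lapply(seq_len(C), function(k) {
    r0 <- corners[k, 1]; c0 <- corners[k, 2]
    real_crop <- m$pixels[(r0 + 1):(r0 + S), (c0 + 1):(c0 + S), drop = FALSE]
    structure(list(parent_id = m$id, crop_index = k - 1L,
                   real_crop = real_crop,
                   spectrum = power_spectrum(real_crop, cfg$spectrum_epsilon),
                   label = m$label),
              class = "crop_pair")
  })
}

# 0-based top-left corners (row, col) for the centered grid layout.
grid_corners <- function(H, W, S, C) {
  g <- ceiling(sqrt(C))
  starts_1d <- function(extent) {
    if (g * S <= extent) {
      off <- floor((extent - g * S) / 2)
      off + S * (0:(g - 1))
    } else if (g == 1L) {
      floor((extent - S) / 2)
    } else {
      # lattice wider than the image: spread evenly, overlapping as needed
      round((0:(g - 1)) * (extent - S) / (g - 1))
    }
  }
  rows <- starts_1d(H); cols <- starts_1d(W)
  all_cells <- cbind(rep(rows, each = g), rep(cols, times = g))  # row-major
  all_cells[seq_len(C), , drop = FALSE]
}

#' Block-mean binning of a micrograph (display utility)
#'
#' Each output pixel is the mean of its `factor` x `factor` block. Binning is
#' a display aid only; the model consumes unbinned data.
#'
#' @param m a [micrograph] or numeric matrix.
#' @param factor integer binning factor dividing both dimensions.
#' @return same type as input, binned.
#' @export
bin_image <- function(m, factor) {
  px <- if (inherits(m, "micrograph")) m$pixels else m
  assert_that(is_count(factor) && factor >= 1, "factor must be a positive integer")
  H <- nrow(px); W <- ncol(px)
  assert_that(H %% factor == 0 && W %% factor == 0,
              "factor ", factor, " must divide both dimensions (", H, " x ", W, ")")
  if (factor > 1) {
    a <- array(px, dim = c(factor, H / factor, factor, W / factor))
    px <- apply(a, c(2, 4), mean)
  }
  if (inherits(m, "micrograph")) {
    m$pixels <- px
    m
  } else px
}

#' Bilinear resize of a square grid to the model input size
#'
#' Endpoint-aligned bilinear interpolation; a no-op when the grid is already
#' target-sized.
#'
#' @param grid numeric matrix.
#' @param target output side length (>= 32 enforced at the config level, any
#'   positive size accepted here).
#' @return target x target numeric matrix.
#' @export
resize_for_model <- function(grid, target) {
  assert_that(is.matrix(grid) && is.numeric(grid), "grid must be a numeric matrix")
  assert_that(is_count(target) && target >= 1, "target must be a positive integer")
  H <- nrow(grid); W <- ncol(grid)
  if (H == target && W == target) return(grid)
  map_axis <- function(n_src, n_dst) {
    if (n_dst == 1L) return(list(lo = 1L, hi = 1L, w = 0))
    pos <- (seq_len(n_dst) - 1) * (n_src - 1) / (n_dst - 1)  # endpoint-aligned
    lo <- pmin(floor(pos) + 1L, n_src)
    hi <- pmin(lo + 1L, n_src)
    list(lo = lo, hi = hi, w = pos - (lo - 1))
  }
  ry <- map_axis(H, target); rx <- map_axis(W, target)
  top <- grid[ry$lo, rx$lo, drop = FALSE] * (1 - rx$w)[col(matrix(0, target, target))] +
    grid[ry$lo, rx$hi, drop = FALSE] * rx$w[col(matrix(0, target, target))]
  bot <- grid[ry$hi, rx$lo, drop = FALSE] * (1 - rx$w)[col(matrix(0, target, target))] +
    grid[ry$hi, rx$hi, drop = FALSE] * rx$w[col(matrix(0, target, target))]
  top * (1 - ry$w) + bot * ry$w
}

#' Prepare crop pairs as standardized model inputs
#'
#' Resizes real crops and spectra to `cfg$model_input_size` and standardizes
#' each channel to mean 0, sd 1 (real crops with the hot-pixel clip, spectra
#' plain). Returns a `crop_batch`: two arrays of dim (size, size, N) plus
#' aligned labels, parent ids and crop indices.
#'
#' @param crop_pairs list of `crop_pair` objects.
#' @param cfg a [preprocess_config].
#' @return a `crop_batch` list.
#' @export
prepare_model_inputs <- function(crop_pairs, cfg = preprocess_config()) {
  assert_that(length(crop_pairs) > 0, "no crops given")
  sz <- cfg$model_input_size
  N <- length(crop_pairs)
  real <- array(0, dim = c(sz, sz, N))
  spec <- array(0, dim = c(sz, sz, N))
  for (i in seq_len(N)) {
    cp <- crop_pairs[[i]]
    real[, , i] <- standardize_grid(resize_for_model(cp$real_crop, sz),
                                    cfg$clip_sigma)
    spec[, , i] <- standardize_grid(resize_for_model(cp$spectrum, sz))
  }
  structure(list(real = real, spec = spec,
                 labels = vapply(crop_pairs, `[[`, "", "label"),
                 parent_ids = vapply(crop_pairs, `[[`, "", "parent_id"),
                 crop_indices = vapply(crop_pairs, `[[`, 0L, "crop_index")),
            class = "crop_batch")
}

#' Preprocess every micrograph in a manifest
#'
#' Reads each file, normalizes intensities, extracts crops and prepares model
#' inputs. Returns one `crop_batch` covering all micrographs.
#'
#' @param manifest data.frame as returned by [read_manifest], or a path.
#' @param cfg a [preprocess_config].
#' @param seed seed for random crop layout.
#' @return a `crop_batch`.
#' @export
preprocess_manifest <- function(manifest, cfg = preprocess_config(), seed = 0L) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  crops <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- read_micrograph(manifest$path[i], label = manifest$label[i],
                         id = manifest$micrograph_id[i])
    m <- normalize_intensities(m, cfg$clip_sigma)
    crops <- c(crops, extract_crops(m, cfg, seed = mix_seed(seed, m$id)))
  }
  prepare_model_inputs(crops, cfg)
}
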