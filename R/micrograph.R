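#' Construct a Micrograph object
#'
#' A micrograph is a single-channel intensity grid plus identity, quality
#' label and provenance. Pixels are stored as an H x W numeric matrix with
#' row = y (0-based pixel (x, y) lives at `pixels[y + 1, x + 1]`).
#'
#' @param id unique micrograph identifier.
#' @param pixels numeric H x W matrix, H and W at least 64, all finite.
#' @param label one of "good", "bad", "unknown".
#' @param source_path originating file path ("" for in-memory grids).
#' @param pixel_size optional pixel size in Angstrom per pixel (metadata only).
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(id, pixels, label = "unknown", source_path = "",
                       pixel_size = NULL) {
  assert_that(is.character(id) && length(id) == 1L && nzchar(id),
              "id must be a non-empty string")
  assert_that(is.matrix(pixels) && is.numeric(pixels),
              "pixels must be a numeric matrix")
  assert_that(nrow(pixels) >= 64L && ncol(pixels) >= 64L,
              "micrograph must be at least 64 x 64 (got ",
              nrow(pixels), " x ", ncol(pixels), ")")
  assert_that(all(is.finite(pixels)), "pixels must be finite")
  label <- match.arg(label, c("good", "bad", "unknown"))
  structure(list(id = id, pixels = pixels, label = label,
                 source_path = source_path, pixel_size = pixel_size),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s'> %d x %d, label = %s\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$label))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a micrograph from MRC2014 or single-channel TIFF
#'
#' The format is chosen by file extension (`.mrc`/`.mrcs` vs
#' `.tif`/`.tiff`); anything else is tried as MRC first, then TIFF.
#' Multi-frame inputs are rejected.
#'
#' @param path file path.
#' @param label quality label to attach ("good", "bad" or "unknown").
#' @param id micrograph identifier; defaults to the file stem.
#' @return a [micrograph] object.
#' @export
read_micrograph <- function(path, label = "unknown",
                            id = tools::file_path_sans_ext(basename(path))) {
  ext <- tolower(tools::file_ext(path))
  pixels <- if (ext %in% c("mrc", "mrcs", "map")) {
    read_mrc(path)
  } else if (ext %in% c("tif", "tiff")) {
    read_tiff(path)
  } else {
    tryCatch(read_mrc(path), error = function(e) read_tiff(path))
  }
  micrograph(id = id, pixels = pixels, label = label, source_path = path)
}

#' Write a micrograph to an MRC2014 file
#'
#' @param m a [micrograph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(m, path) {
  assert_that(inherits(m, "micrograph"), "m must be a micrograph")
  write_mrc(m$pixels, path, pixel_size = m$pixel_size %||% 1)
}

#' Read a micrograph manifest CSV
#'
#' The manifest format is `micrograph_id,path,label,split` with label in
#' {good, bad} and split in {train, val, test} (possibly empty before
#' splitting). Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns micrograph_id, path, label, split.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("micrograph_id", "path", "label", "split")
  assert_that(all(need %in% names(df)),
              "manifest must have columns ", paste(need, collapse = ", "))
  df <- df[, need]
  assert_that(!anyDuplicated(df$micrograph_id),
              "duplicate micrograph_id in manifest")
  assert_that(all(df$label %in% c("good", "bad")),
              "manifest labels must be 'good' or 'bad'")
  assert_that(all(df$split %in% c("", "train", "val", "test")),
              "manifest split must be train/val/test or empty")
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

#' Write a micrograph manifest CSV
#'
#' @param df data.frame with columns micrograph_id, path, label, split.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  need <- c("micrograph_id", "path", "label", "split")
  assert_that(all(need %in% names(df)),
              "manifest must have columns ", paste(need, collapse = ", "))
  utils::write.csv(df[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
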