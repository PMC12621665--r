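#' @keywords internal
#' @useDynLib cryoscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Internal helpers: argument checking, seeded RNG scoping, seed derivation.

stop_validation <- function(...) {
  stop(structure(class = c("cryoscreen_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("cryoscreen_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_validation(...)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit seed derivation from a base seed plus stream labels.
# Splitmix-style integer mixing done in double precision (exact below 2^53).
mix_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    # multipliers stay below 2^22 so h * mult < 2^53 is exact in doubles
    h <- (h * 1000003 + v + 12345) %% 2147483647
    h <- (h * 69069 + 362437) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

# djb2-style rolling hash of a character string (provenance stamps, CLI).
text_hash <- function(txt) {
  bytes <- utf8ToInt(paste(txt, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

# Snap doubles to the nearest float32-representable value (MRC mode 2 storage).
snap_float32 <- function(x) {
  d <- dim(x)
  out <- readBin(writeBin(as.vector(x), raw(), size = 4L), "double",
                 n = length(x), size = 4L)
  dim(out) <- d
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
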