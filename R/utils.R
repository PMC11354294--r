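# Internal helpers: seeded evaluation without touching the caller's RNG
# stream, and deterministic child-seed derivation for pipeline stages.

withSeed <- function(seed, expr) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a deterministic child seed
#'
#' Hashes a master seed together with any number of string/numeric tags
#' (group, quadrant, location, replicate, stage name ...) into a 31-bit
#' integer, so each pipeline stage and image gets an independent,
#' reproducible RNG stream.
#'
#' @param master integer master seed.
#' @param ... tags (coerced to character) identifying the consumer.
#' @return integer in [1, 2^31 - 2].
#' @examples
#' deriveSeed(1, "control", "ST", 1, 1)
#' @export
deriveSeed <- function(master, ...) {
  tags <- paste(vapply(list(...), as.character, character(1)),
                collapse = "\r")
  bytes <- utf8ToInt(tags)
  h <- as.numeric(master) %% 2147483647
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# pixel-centre coordinates (um) for 1-based matrix indices
pxCentre <- function(idx, pixelSizeUm) (idx - 0.5) * pixelSizeUm

stopifnotScalarPositive <- function(x, what) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
}
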