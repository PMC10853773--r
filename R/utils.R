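#' @importFrom methods new validObject is slot setValidity show
#' @importFrom stats cutree dist hclust runif
#' @importFrom utils read.delim write.table head tail
NULL

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Characters tolerated in MSA inputs besides the 20 residues.
MSA_EXTRA <- c("X", "-", ".")

#' Evaluate an expression under a reproducible, isolated RNG state
#'
#' Runs `expr` with the RNG seeded from `seed` (optionally offset by a
#' stream number so independent components draw from independent streams),
#' then restores the caller's RNG state.  Used throughout the synthetic-data
#' generators so that one global seed fans out deterministically.
#'
#' @param seed integer scalar master seed.
#' @param stream non-negative integer stream offset.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withStream <- function(seed, stream, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + 7919L * as.integer(stream)) %% 2147483629L)
  expr
}

# stop() with a consistent prefix naming the offending element
bail <- function(...) stop(..., call. = FALSE)

# half-up rounding at integer precision (base round() is banker's)
roundHalfUp <- function(x) floor(x + 0.5)
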