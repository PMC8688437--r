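#' @importFrom rlang abort warn .data
#' @importFrom dplyr %>%
NULL

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All generators route their randomness here so a
# single integer makes any stage bit-reproducible.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a global seed by a fixed offset, kept inside the
# 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

# round-half-up, fixed (rather than banker's rounding) for bit-reproducible
# pseudo-counts
round_half_up <- function(x) floor(x + 0.5)

stopifnot_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTacgt", "TGCAtgca", x))
}
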