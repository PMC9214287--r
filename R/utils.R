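# Seed plumbing shared by the simulator and the experiment harness.

# Seed the global RNG when a seed is given; a NULL seed leaves the stream
# alone so that callers can chain draws inside a larger seeded computation.
local_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Derive independent replicate seeds from a master seed
#'
#' Stable substream derivation used by the replicate harness: the master
#' seed initialises the generator once and `n` distinct 31-bit integers are
#' drawn without replacement. The same `(master, n)` pair always yields the
#' same seed vector, and the caller's RNG state is left untouched.
#'
#' @param master Integer master seed.
#' @param n Number of replicate seeds.
#' @return Integer vector of length `n`.
#' @examples
#' derive_seeds(42, 3)
#' @export
derive_seeds <- function(master, n) {
  stopifnot(n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
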