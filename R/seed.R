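#' Derive a deterministic sub-stream seed from a global seed and a label
#'
#' A single global integer seed fans out to independent per-operation seeds
#' keyed by a fixed character label, so that adding one randomised operation
#' to a pipeline does not perturb the draws of any other. The mapping is a
#' simple polynomial string hash folded into the global seed modulo
#' 2^31 - 1, keeping results inside R's integer range.
#'
#' @param seed Global integer seed.
#' @param label Character scalar naming the consumer (e.g. `"liability"`).
#' @return An integer seed suitable for [set.seed()].
#' @examples
#' substream_seed(42L, "liability")
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L, nzchar(label))
  m <- 2147483647 # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  as.integer((abs(as.numeric(seed)) + h) %% m)
}

# internal: run expr with the RNG seeded from (seed, label), restoring the
# caller's RNG state afterwards
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}
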