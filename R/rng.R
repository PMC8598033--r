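#' Derive a deterministic sub-stream seed from a global seed
#'
#' Stages of the pipeline (simulation, splitting, boosting restarts, k-means
#' restarts, ...) each draw their own seed from the single user-facing seed
#' so that stages can be re-run in isolation and adding randomness to one
#' stage never perturbs another. The derivation is a small multiplicative
#' hash of the stage name and index, folded into [0, 2^31 - 2].
#'
#' @param seed integer global seed.
#' @param stage character scalar naming the sub-stream.
#' @param index optional integer (e.g. repeat number), default 0.
#' @return a single integer seed, always < 2^31.
#' @export
substream_seed <- function(seed, stage, index = 0L) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(stage) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  s <- (as.double(seed) %% 2147483629) * 48271 + h * 69621 + as.double(index)
  as.integer(s %% 2147483629) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
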