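# Internal helpers shared across the pipeline.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive n child seeds from a master seed (all < 2^31)
#' @noRd
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

#' Row-wise argmax with ties broken to the lowest index
#' @noRd
argmax_rows <- function(m) {
  apply(m, 1L, which.max)
}

#' Row-wise argmin with ties broken to the lowest index
#' @noRd
argmin_rows <- function(m) {
  apply(m, 1L, which.min)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a stage label so pipeline errors are attributable
#' @noRd
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
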