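# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never disturb user RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage seed from a run seed
#'
#' A single run seed fans out deterministically to per-stage seeds so that
#' partial re-runs of a pipeline reuse exactly the seeds of the full run.
#' The derivation is `(seed * 69069 + stage * 1013904223) mod (2^31 - 1)`,
#' kept strictly positive and below 2^31.
#'
#' @param seed Integer run seed.
#' @param stage Integer stage index (>= 0).
#' @return A positive integer seed.
#' @export
fan_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(stage))
  m <- 2147483647
  s <- (abs(seed) %% m) * 69069 + (abs(stage) %% m) * 1013904223
  as.integer(s %% m + 1)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same units;
#' 1 means identical partitions up to label permutation.
#'
#' @param a,b Label vectors of equal length.
#' @return A number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_funsig <- function(msg, class) {
  stop(structure(class = c(class, "funsig_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
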