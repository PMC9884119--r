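#' Run code with a temporary RNG state
#'
#' Seeds the generator for the duration of `code` and restores whatever
#' `.Random.seed` was in place before, so package functions never perturb the
#' caller's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @details The seed is passed through a multiplicative hash before
#'   `set.seed()`: nearby integer seeds hand the Mersenne-Twister highly
#'   correlated initial states, which would couple draws across cohort
#'   members and simulation replicates.
with_seed <- function(seed, code) {
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
  set.seed(scramble_seed(seed))
  force(code)
}

scramble_seed <- function(seed) {
  as.integer((abs(as.numeric(seed)) * 2654435761) %% 2147483647)
}

#' Derive a per-item sub-seed from a master seed
#'
#' Deterministic mixing of `(seed, index)` into a 31-bit integer, so cohort
#' members get independent, reproducible streams without global-state
#' coupling.
#'
#' @param seed Master integer seed.
#' @param index Item index (1-based).
#' @return Integer in `[0, 2^31)`.
#' @keywords internal
sub_seed <- function(seed, index) {
  # Knuth multiplicative hash on the index, xor-folded with the seed.
  # All arithmetic stays below 2^53 so doubles are exact.
  h <- (index * 2654435761) %% 2147483647
  as.integer(bitwXor(as.integer(seed %% 2147483647L), as.integer(h)))
}

#' Clip values to a range
#' @keywords internal
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Developmental stages recognised by the package
#' @return Character vector of valid stage labels.
#' @export
stage_levels <- function() c("E3.5", "E4.5", "diapause")

check_stage <- function(stage) {
  if (!(is.character(stage) && length(stage) == 1L && stage %in% stage_levels())) {
    stop("unknown stage: ", paste(stage, collapse = ","),
         " (expected one of ", paste(stage_levels(), collapse = ", "), ")",
         call. = FALSE)
  }
  stage
}
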