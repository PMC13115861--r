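#' Round half away from zero at a fixed number of decimals
#'
#' Plain "schoolbook" rounding, used for all reported percentages and fold
#' enrichments so that printed summaries do not depend on banker's rounding.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Evaluate an expression under a local, seeded RNG state
#'
#' Sets the Mersenne-Twister seed for the duration of `expr` and restores the
#' caller's RNG state afterwards, so seeded operations never perturb the
#' global random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# Deterministic per-iteration substream seeds derived from a master seed, so
# permutation results do not depend on iteration scheduling.
iteration_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

#' Format a count as a percentage of a denominator
#'
#' Percentages are rounded half-up at the requested precision; a zero
#' denominator yields NA (omitted from summaries).
#'
#' @param numerator,denominator counts
#' @param digits decimal places (default 1)
#' @return numeric percentage, or NA if the denominator is zero
#' @export
summarize_percentage <- function(numerator, denominator, digits = 1) {
  if (length(denominator) != length(numerator)) {
    stop("numerator and denominator lengths differ")
  }
  out <- ifelse(denominator > 0,
                round_half_up(100 * numerator / denominator, digits),
                NA_real_)
  out
}
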