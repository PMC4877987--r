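#' Round half away from zero
#'
#' Reported percentages (completeness, redundancy, abundance, activity) are
#' rounded half away from zero, matching the convention of the quality tables
#' this package reproduces, rather than the IEEE round-half-even used by
#' [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(100 * 106 / 107)  # 99.1
#' round_half_up(0.25, 1)         # 0.3
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # nudge by a relative epsilon so values that are exactly .x5 in decimal but
  # stored fractionally below it (e.g. 3.77358...) are unaffected while true
  # ties round away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards,
# so generator operations are pure functions of (inputs, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Length-weighted median: smallest x whose cumulative weight reaches half the
# total. Used for the bin coverage centre during paired-end rescue.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  x[which(cw >= sum(w) / 2)[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_fraction <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) {
    stop(sprintf("`%s` must be a single fraction %s", name,
                 if (open) "in (0, 1)" else "in [0, 1]"), call. = FALSE)
  }
  invisible(x)
}
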