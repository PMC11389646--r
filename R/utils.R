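#' Round half away from zero
#'
#' Rounding used at every display/serialization boundary in the package.
#' Base [round()] rounds half to even ("banker's rounding"); consensus
#' reporting conventions (and the published tables this package mirrors)
#' round half up, so 93.335 prints as 93.34, not 93.33.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` decimals.
#' @examples
#' round_half_up(2.5)      # 3, where round(2.5) == 2
#' round_half_up(93.335, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # tiny epsilon absorbs representation error in values that are exactly
  # .5 in decimal but stored just below it in binary
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with a call-free, formatted message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scores_1_9 <- function(scores, what = "rating") {
  if (length(scores) == 0L) fail("no %ss supplied", what)
  if (anyNA(scores)) fail("missing %s value", what)
  bad <- which(scores != floor(scores) | scores < 1 | scores > 9)
  if (length(bad)) {
    fail("%s at position %d is %s; must be an integer in 1..9",
         what, bad[1L], format(scores[bad[1L]]))
  }
  invisible(as.integer(scores))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
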