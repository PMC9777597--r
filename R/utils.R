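#' Round half away from zero
#'
#' Decimal rounding in which ties (a trailing 5 at the last kept digit) are
#' rounded away from zero, the convention used in dairy-recording reports.
#' Base \code{round()} rounds ties to even, which disagrees with printed
#' frequency tables for values such as 0.865.
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded to \code{digits} places.
#' @examples
#' roundHalfUp(0.865, 2)  # 0.87 (round() gives 0.86)
#' @export
roundHalfUp <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

## deterministic per-stage child seeds from one master seed (kept < 2^31)
childSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + stage * 7919L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
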