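#' Round half away from zero
#'
#' Presentation rounding used for all reported percentages and fold values:
#' exact halves round up in magnitude (so 57.115 -> 57.12), unlike base
#' [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Percentage of a whole
#'
#' @param part,whole numeric; `whole` must be positive for a defined result.
#' @return `100 * part / whole` at full precision (`NaN` when `whole` is 0).
#' @export
pct_of <- function(part, whole) 100 * part / whole

#' Canonical unordered-pair key
#'
#' Identity of an unordered disease pair: the two codes joined with `"|"`,
#' smaller code first, so `pair_key(x, y) == pair_key(y, x)`. Used to
#' compare edge sets across networks.
#'
#' @param x,y character vectors of equal length.
#' @return character vector of pair keys.
#' @export
pair_key <- function(x, y) {
  paste(pmin(x, y), pmax(x, y), sep = "|")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
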