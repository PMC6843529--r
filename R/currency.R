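#' Round a euro amount half-up to the cent
#'
#' Commercial (half-up) rounding, applied at every boundary the costing rules
#' define: per-day drug rates, per-course totals, monthly revenues. Base R's
#' \code{round()} rounds half to even, which does not reproduce printed fee
#' and price tables; half-up does. A small epsilon guards against binary
#' floating-point representation error (e.g. a value stored as 34.41499999...
#' that is exactly 34.415 in decimal).
#'
#' @param x numeric vector of euro amounts.
#' @param digits number of decimal places (default 2, i.e. cents).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_cents(271.46 / 100)        # 2.71
#' round_cents(489.19 / 90 * 2)     # 10.87
#' @export
round_cents <- function(x, digits = 2) {
  stopifnot(is.numeric(x))
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-7) / p
}

#' Parse euro amounts from catalogue text
#'
#' Strips currency signs, whitespace and thousands separators ("10,551.6"),
#' then converts to numeric. Decimal separator is ".".
#'
#' @param x character vector.
#' @return numeric vector; `NA` where the cleaned string is not a number.
#' @keywords internal
parse_euro <- function(x) {
  cleaned <- gsub("[€[:space:],]", "", as.character(x))
  cleaned[cleaned == ""] <- NA_character_
  suppressWarnings(as.numeric(cleaned))
}
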