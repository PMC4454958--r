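#' Round half away from zero at a fixed number of decimals
#'
#' Regulatory risk tables are printed under commercial ("half-up") rounding,
#' not the IEC 60559 banker's rounding used by [base::round()]. All reported
#' values in this package go through this function so that printed
#' intermediates (IUR, CF, UR_work, RfC_work, ECR, HQ) reproduce the
#' published convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (may be negative).
#' @return `x` rounded half away from zero at `digits` decimals.
#' @examples
#' round_half_up(0.525, 2)   # 0.53
#' round_half_up(2.35, 1)    # 2.4
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # small guard against representation error (e.g. 0.525 * 100 = 52.499999...)
  z <- abs(x) * p
  z <- floor(z + 0.5 + 1e-9)
  sign(x) * z / p
}

#' Round half away from zero to a number of significant figures
#'
#' @param x numeric vector (any sign; zeros pass through).
#' @param digits significant figures to keep.
#' @return rounded vector.
#' @examples
#' signif_half_up(4.91346, 2)    # 4.9
#' signif_half_up(2.342857e-3, 2) # 2.3e-3
#' @export
signif_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 1)
  out <- x
  nz <- is.finite(x) & x != 0
  if (any(nz)) {
    e <- floor(log10(abs(x[nz])))
    p <- 10^(digits - 1 - e)
    out[nz] <- sign(x[nz]) * floor(abs(x[nz]) * p + 0.5 + 1e-9) / p
  }
  out
}
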