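#' Round half away from zero
#'
#' Rounding as printed in field tables (0.5 always rounds up in magnitude),
#' unlike [base::round()]'s round-half-even. A small epsilon guards against
#' values such as 24.325 being represented just below the half boundary.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  z <- abs(x) * p + 0.5 + sqrt(.Machine$double.eps)
  sign(x) * trunc(z) / p
}

# stop() with call.=FALSE everywhere
abort <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
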