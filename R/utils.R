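# Trapezoidal integral of y over x (both numeric, same length).
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Feed-rate unit conversions
#'
#' User-facing configuration uses mL/min (the usual pump scale); all internal
#' balances use L/h. 1 mL/min = 0.06 L/h.
#' @param x Feed rate(s).
#' @return Converted feed rate(s).
#' @export
mL_min_to_L_h <- function(x) x * 0.06

#' @rdname mL_min_to_L_h
#' @export
L_h_to_mL_min <- function(x) x / 0.06
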