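#' Round half away from zero
#'
#' Report tables round percentage shares half-up to integers (so 52.5 -> 53),
#' unlike base [round()], which rounds half to even.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0)
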