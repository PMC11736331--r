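#' Round half away from zero
#'
#' Report-time rounding used for all printed tables. Base `round()` rounds
#' half to even; published AMC tables round half up, so 0.005 -> 0.01.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (>= 0).
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  stopifnot(is.numeric(x), digits >= 0)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

abort_domain <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "vetamc_domain_error")
}

abort_schema <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "vetamc_schema_error")
}

abort_resolution <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "vetamc_resolution_error")
}

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 1 & x == floor(x)
}
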