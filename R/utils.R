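#' @useDynLib hpadyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor fft median prcomp quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can distinguish contract violations
hpa_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("hpadyn_", class), "hpadyn_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# run expr with a private RNG stream; never touches the caller's RNG state
with_seed <- function(seed, expr) {
  stopifnot(is_scalar_number(seed))
  withr::with_seed(as.integer(seed), expr)
}
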