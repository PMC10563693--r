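#' @useDynLib mircos, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor lm coef prcomp predict rnorm runif sd var quantile
#' @importFrom utils read.csv write.csv head tail
NULL

# Classed error helper so callers can condition on failure modes rather than
# matching message text.
stop_mircos <- function(class, ..., call. = FALSE) {
  msg <- paste0(...)
  cond <- structure(
    class = c(class, "mircos_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic seed fan-out: one experiment seed yields independent,
# reproducible stage seeds (kept below 2^31 - 1).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 2654435761) %% 2147483647)
}
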