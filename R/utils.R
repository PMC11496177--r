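# Internal helpers: seed streams, validation, logging.

#' Derive a child seed from a root seed
#'
#' All stochastic components (bootstraps, MR-PRESSO simulations, the data
#' generator) take an explicit seed. Pipeline stages derive their seeds from a
#' single root seed with this deterministic splitter, so one integer reproduces
#' an entire run. Seeds stay below 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stream character label naming the consumer (e.g. "bootstrap").
#' @param index optional integer distinguishing repeated uses of one stream.
#' @return a single integer seed.
#' @keywords internal
split_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 1009 + index * 7919) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(cond, msg, class = "mrmediate_error") {
  if (!isTRUE(cond)) {
    stop(structure(
      class = c(class, "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  invisible(TRUE)
}

insufficient_instruments <- function(msg, counts = NULL) {
  stop(structure(
    class = c("mrmediate_insufficient_instruments", "mrmediate_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), counts = counts)
  ))
}

log_note <- function(fmt, ...) {
  message(sprintf(fmt, ...))
}
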