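# Classed conditions so callers can distinguish failure modes programmatically.
# Every error carries class c(<specific>, "toxiquant_error", "error", "condition").

tq_error <- function(message, class, call = sys.call(-1), ...) {
  stop(errorCondition(message, ..., class = c(class, "toxiquant_error")))
}

tq_warn <- function(message, class, ...) {
  warning(warningCondition(message, ..., class = c(class, "toxiquant_warning")))
}

# shorthand used throughout: stop with a usage error unless `cond` holds
tq_check <- function(cond, message, class = "tq_usage_error") {
  if (!isTRUE(cond)) tq_error(message, class)
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
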