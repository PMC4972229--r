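# internal helpers shared across modules

# validation errors get their own condition class so the CLI can map them
# to exit code 2 while genuine runtime failures map to 3
stop_validation <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(errorCondition(msg, class = c("dsc_validation", "error", "condition")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic, locale-independent ordering of site identifiers; the
# package's universal tie-break rule is ascending lexicographic site ID
id_order <- function(ids, scores = NULL) {
  if (is.null(scores)) order(ids, method = "radix")
  else order(-scores, ids, method = "radix")
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == as.integer(x)
}

# small-integer seed arithmetic that never leaves 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483629)
}
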