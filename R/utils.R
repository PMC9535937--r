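#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit sub-seed from a top-level seed and a string salt.
# Keeps every derived seed strictly below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (2^31 - 1))
}

assert_finite_nonneg <- function(x, what) {
  if (any(!is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(x < 0)) stop(what, " contains negative values", call. = FALSE)
  invisible(x)
}

# Messages used for dropped/flagged record counts; silenced under
# suppressMessages() but visible in CLI logs.
log_count <- function(n, what) {
  if (n > 0) message(sprintf("[lurtransfer] %d %s", n, what))
  invisible(n)
}
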