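# internal helpers shared across modules

declm_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "declm_error"), ...)
}

# derive a child seed from a base seed; kept below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 2654435761) %% 2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    declm_abort(sprintf("`%s` must be a single finite number.", name),
                "declm_invalid_argument")
  }
  invisible(x)
}
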