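# internal helpers: logging and deterministic seed derivation

specMessage <- function(...) {
  message("[specBLUP] ", sprintf(...))
}

# Deterministic 31-bit sub-seed from a master seed and a character tag.
# Simple polynomial rolling hash; stable across platforms and call order.
mixSeed <- function(masterSeed, ...) {
  tag <- paste(c(...), collapse = "|")
  h <- as.double(masterSeed %% 2147483647L)
  for (cc in utf8ToInt(tag)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
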