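# Internal helpers shared across modules.

#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

# Deterministic per-unit seed fan-out: one global seed yields an independent
# substream seed for each unit (user, restart, replicate) so per-unit output
# is stable under reordering of the surrounding loop. Kept below 2^31.
fan_out_seed <- function(seed, index) {
  (as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647
}

# FNV-1a 32-bit hash of a character scalar, hex-encoded. Used to stamp
# pipeline outputs with the configuration that produced them.
fnv1a_hash <- function(x) {
  # 32-bit ops done in doubles via 16-bit halves: values can exceed both the
  # integer range (bitwXor) and 2^53 (naive modular multiply)
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  }
  mul32 <- function(a, b) {
    (((a %/% 65536) * b) %% 65536 * 65536 + (a %% 65536) * b) %% 4294967296
  }
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- mul32(xor32(h, b), 16777619)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
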