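#' Digest of a configuration object
#'
#' 32-bit FNV-1a hash over the canonical deparse of a configuration list,
#' used to stamp output files so runs can be matched to their settings.
#'
#' @param x any R object.
#' @return 8-character lowercase hex string.
#' @export
config_digest <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte (b < 256); keep h a double, it can
    # exceed the integer range
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # h * 16777619 mod 2^32, split as h*(2^24 + 403) to stay exact in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  # h can exceed the integer range; format the two 16-bit halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
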