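`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of an R object's canonical JSON form; reproducible
# across sessions and platforms (used for run-metadata provenance).
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lb <- h %% 256
    h <- h - lb + bitwXor(as.integer(lb), as.integer(b %% 256))
    # 32-bit modular multiply in two 16-bit halves (doubles stay < 2^53)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  hi <- (h - h %% 65536) / 65536
  sprintf("%04x%04x", as.integer(hi), as.integer(h %% 65536))
}
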