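# internal helpers

# FNV-1a 32-bit hash of a character vector, as 8-char hex; used for
# integrity fingerprints of vocabularies and corpora (not cryptographic).
.fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = ""))) %% 256
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit multiply by the FNV prime, split to stay within double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (h0 * 16777619 + ((h1 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assertCount <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x != round(x)) {
    .stopf("configuration error: %s must be a positive integer (got %s)",
           what, paste(x, collapse = ","))
  }
  as.integer(x)
}

# seed-scoped RNG: runs expr with the given seed without disturbing the
# caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a child seed (< 2^31) from a base seed and a stream label
.childSeed <- function(seed, stream) {
  h <- strtoi(substr(.fnv1a32(paste0(stream, ":", seed)), 1, 7), 16L)
  ((as.integer(seed) %% 1000003L) * 1007L + h %% 1000003L) %% 2147483647L
}

.emptyFeatureInfo <- function() {
  data.frame(feature_id = character(), source_set = character(),
             window_tag = character(), name = character(),
             stringsAsFactors = FALSE)
}
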