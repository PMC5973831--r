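# Internal helpers: seed sub-streams, rounding, small hashing.

# Derive a deterministic 32-bit sub-seed from a master seed and a component
# name, so independent generator components can be re-drawn separately.
.subSeed <- function(seed, component) {
  h <- 0
  for (ch in utf8ToInt(as.character(component)))
    h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 65521 * 7919 + h * 104729 + 17) %%
               2147483647)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Round half away from zero (donation bar has 1-euro steps; ties go to the
# larger donation magnitude, unlike banker's rounding in base round()).
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# FNV-1a 32-bit hash of an R object's serialization; used for provenance
# stamps in reports (no cryptographic strength needed, only stability).
.fnv1a <- function(object) {
  bytes <- as.integer(serialize(object, NULL, version = 2L))
  # skip the serialization header (R version stamp) so the hash depends on
  # content only
  bytes <- bytes[-seq_len(14L)]
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply mod 2^32 in two 16-bit halves to stay inside double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

.stopIf <- function(cond, ...) if (cond) stop(..., call. = FALSE)
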