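# Deterministic bigram hashing for Bloom-filter encoding.
#
# Bit positions come from double hashing: position_i = (H1 + i * H2) mod m.
# H1 and H2 are FNV-1a 32-bit digests of the bigram's bytes under two
# different offset bases, so the scheme is seedless and identical across
# platforms and sessions. All arithmetic is done in doubles because R has
# no unsigned 32-bit integer type; intermediates stay below 2^53.

.fnv_prime <- 16777619
.fnv_basis_h1 <- 2166136261
.fnv_basis_h2 <- 5381

fnv1a32 <- function(bytes, basis) {
  h <- basis
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * .fnv_prime) %% 65536) * 65536 + lo * .fnv_prime) %% 4294967296
  }
  h
}

# Cache of H1/H2 values per bigram. Harmonized strings only contain
# A-Z, 0-9 and space, so the full alphabet (37^2 bigrams) is precomputed
# on first use; anything else is added on demand.
.bloom_env <- new.env(parent = emptyenv())

.init_bigram_tables <- function() {
  chars <- c(LETTERS, as.character(0:9), " ")
  grams <- as.vector(outer(chars, chars, function(a, b) paste0(b, a)))
  codes <- vapply(grams, utf8ToInt, integer(2))
  .bloom_env$keys <- grams
  .bloom_env$h1 <- apply(codes, 2, fnv1a32, basis = .fnv_basis_h1)
  .bloom_env$h2 <- apply(codes, 2, fnv1a32, basis = .fnv_basis_h2)
  invisible(NULL)
}

.ensure_bigrams <- function(grams) {
  if (is.null(.bloom_env$keys)) .init_bigram_tables()
  new <- setdiff(unique(grams), .bloom_env$keys)
  if (length(new)) {
    codes <- lapply(new, utf8ToInt)
    .bloom_env$keys <- c(.bloom_env$keys, new)
    .bloom_env$h1 <- c(.bloom_env$h1,
                       vapply(codes, fnv1a32, numeric(1), basis = .fnv_basis_h1))
    .bloom_env$h2 <- c(.bloom_env$h2,
                       vapply(codes, fnv1a32, numeric(1), basis = .fnv_basis_h2))
  }
  invisible(NULL)
}

# Returns list(h1=, h2=) of numeric hash values aligned with `grams`.
bigram_hash_values <- function(grams) {
  .ensure_bigrams(grams)
  idx <- match(grams, .bloom_env$keys)
  list(h1 = .bloom_env$h1[idx], h2 = .bloom_env$h2[idx])
}
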