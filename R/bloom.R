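#' Bloom-filter encoding settings
#'
#' Per-attribute bit budgets and the number of hash functions. The default
#' composite filter is 180 bits: name and mother's name 50 bits each, date
#' of birth 40, municipality code and gender 20 each, encoded with two hash
#' functions. The budgets double as the attribute weights of the hybrid
#' comparison scheme.
#'
#' @param segment_bits named integer vector of bit budgets, one entry per
#'   linkage attribute, in the fixed attribute order.
#' @param num_hashes number of hash functions (positions per bigram).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(segment_bits = c(name = 50, mother_name = 50,
                                           date_of_birth = 40,
                                           municipality_code = 20,
                                           gender = 20),
                          num_hashes = 2L) {
  attrs <- linkage_attributes()
  if (!identical(names(segment_bits), attrs)) {
    stop("segment_bits must be named exactly: ", paste(attrs, collapse = ", "))
  }
  segment_bits <- as.integer(segment_bits)
  names(segment_bits) <- attrs
  if (any(segment_bits < 1L)) stop("all segment lengths must be >= 1 bit")
  num_hashes <- as.integer(num_hashes)
  if (num_hashes < 1L) stop("num_hashes must be >= 1")
  structure(list(segment_bits = segment_bits, num_hashes = num_hashes),
            class = "filter_config")
}

# Column ranges of each attribute's segment inside the composite.
segment_ranges <- function(config) {
  ends <- cumsum(config$segment_bits)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
}

#' Character bigrams of a harmonized string
#'
#' The string is padded with one leading and one trailing space, then every
#' pair of consecutive characters is returned (so `"ANA"` gives `" A"`,
#' `"AN"`, `"NA"`, `"A "`). A missing value yields an empty list; duplicates
#' are retained here and deduplicated at filter-insertion time.
#'
#' @param s a single harmonized string.
#' @return character vector of length `nchar(s) + 1` (0 if missing).
#' @export
bigrams <- function(s) {
  if (length(s) != 1L) stop("bigrams() takes a single string")
  if (is.na(s) || !nzchar(s)) return(character(0))
  p <- paste0(" ", s, " ")
  n <- nchar(p)
  substring(p, seq_len(n - 1L), seq_len(n - 1L) + 1L)
}

#' Encode one attribute value into a Bloom-filter segment
#'
#' Each distinct bigram g sets positions `(H1(g) + i * H2(g)) mod m` for
#' `i = 0..num_hashes-1`. Encoding is deterministic and seedless: equal
#' harmonized values always produce bit-identical segments. A missing value
#' encodes as the all-zero segment.
#'
#' @param s a single harmonized string.
#' @param length_bits segment length m.
#' @param num_hashes number of hash functions.
#' @return integer vector of 0/1 of length `length_bits`.
#' @export
encode_field <- function(s, length_bits, num_hashes = 2L) {
  if (length_bits < 1L) stop("length_bits must be >= 1")
  if (num_hashes < 1L) stop("num_hashes must be >= 1")
  bits <- integer(length_bits)
  gs <- unique(bigrams(s))
  if (!length(gs)) return(bits)
  hv <- bigram_hash_values(gs)
  for (i in seq_len(num_hashes) - 1L) {
    bits[(hv$h1 + i * hv$h2) %% length_bits + 1L] <- 1L
  }
  bits
}

# Vectorized encoder for one attribute column: n strings -> n x m matrix.
# Duplicate bigrams set the same bits, so no explicit deduplication needed.
encode_column <- function(xs, length_bits, num_hashes = 2L) {
  xs <- as.character(xs)
  xs[is.na(xs)] <- ""
  n <- length(xs)
  M <- matrix(0L, nrow = n, ncol = length_bits)
  keep <- nzchar(xs)
  if (!any(keep)) return(M)
  padded <- paste0(" ", xs[keep], " ")
  nb <- nchar(padded) - 1L
  row <- rep(which(keep), nb)
  start <- sequence(nb)
  grams <- substring(rep(padded, nb), start, start + 1L)
  hv <- bigram_hash_values(grams)
  for (i in seq_len(num_hashes) - 1L) {
    pos <- (hv$h1 + i * hv$h2) %% length_bits
    M[cbind(row, pos + 1L)] <- 1L
  }
  M
}

#' Encode harmonized records into composite Bloom filters
#'
#' Concatenates the five per-attribute segments in fixed order (name,
#' mother_name, date_of_birth, municipality_code, gender) into one bit row
#' per record; 180 bits under the default configuration. Dates and
#' municipality codes are bigram-encoded as digit strings; gender as its
#' single-character code (whose padding yields two bigrams).
#'
#' @param harmonized output of [harmonize_records()].
#' @param config a [filter_config()].
#' @return integer 0/1 matrix, one row per record, `rownames` = record ids,
#'   with attributes `segments` (per-attribute column ranges) and `config`.
#' @export
encode_records <- function(harmonized, config = filter_config()) {
  attrs <- linkage_attributes()
  parts <- lapply(attrs, function(a) {
    encode_column(harmonized[[a]], config$segment_bits[[a]], config$num_hashes)
  })
  M <- do.call(cbind, parts)
  rownames(M) <- harmonized$record_id
  segs <- segment_ranges(config)
  names(segs) <- attrs
  attr(M, "segments") <- segs
  attr(M, "config") <- config
  M
}

#' @rdname encode_records
#' @param record one harmonized record (one-row data.frame or list).
#' @return `encode_record()` returns a single integer 0/1 vector with a
#'   `segments` attribute.
#' @export
encode_record <- function(record, config = filter_config()) {
  M <- encode_records(as.data.frame(record, stringsAsFactors = FALSE), config)
  out <- M[1L, ]
  attr(out, "segments") <- attr(M, "segments")
  out
}

#' Read and write the anonymized filter exchange format
#'
#' The dump is a CSV of `record_id` plus a 0/1 string (leftmost character =
#' bit 1 = first bit of the name segment). This is the anonymized form in
#' which filters can be exchanged between data holders.
#'
#' @param filters matrix from [encode_records()].
#' @param path file path.
#' @export
write_filters <- function(filters, path) {
  bits <- apply(filters, 1L, paste0, collapse = "")
  utils::write.csv(
    data.frame(record_id = rownames(filters), bits = bits,
               stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_filters
#' @param config the [filter_config()] the filters were built with.
#' @export
read_filters <- function(path, config = filter_config()) {
  df <- utils::read.csv(path, colClasses = "character")
  total <- sum(config$segment_bits)
  if (any(nchar(df$bits) != total)) {
    stop("bit strings do not match the configured filter width (", total, ")")
  }
  M <- t(vapply(strsplit(df$bits, "", fixed = TRUE),
                function(x) as.integer(x), integer(total)))
  rownames(M) <- df$record_id
  segs <- segment_ranges(config)
  names(segs) <- linkage_attributes()
  attr(M, "segments") <- segs
  attr(M, "config") <- config
  M
}
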