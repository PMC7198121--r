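# Candidate-pair generation via a disjunctive blocking predicate:
#   (name AND mother_name AND municipality_code)
#     OR (surname AND mother_surname AND year_of_birth)
# Two records co-block iff they agree exactly on every attribute of at
# least one clause; a clause with any missing attribute emits no key, so
# an error in one clause never prevents grouping through the other.

.clause_fields <- list(
  `1` = c("name", "mother_name", "municipality_code"),
  `2` = c("surname", "mother_surname", "year_of_birth")
)

# "\x1f" (unit separator) cannot occur in harmonized values, so joined
# keys are collision-free.
.join_key <- function(harmonized, fields) {
  do.call(paste, c(unname(harmonized[fields]), list(sep = "\x1f")))
}

#' Block keys of harmonized records
#'
#' Emits the clause-1 key iff name, mother's name and municipality code are
#' all non-missing, and the clause-2 key iff surname, mother's surname and
#' year of birth are all non-missing. A record satisfying neither clause
#' emits nothing and is unblockable.
#'
#' @param harmonized output of [harmonize_records()] (any number of rows).
#' @return data.frame with columns `record_id`, `clause_id` (1 or 2), `key`;
#'   zero to two rows per record.
#' @export
block_keys <- function(harmonized) {
  out <- lapply(c(1L, 2L), function(cl) {
    fields <- .clause_fields[[cl]]
    present <- Reduce(`&`, lapply(fields, function(f) nzchar(harmonized[[f]])))
    data.frame(record_id = harmonized$record_id[present],
               clause_id = rep(cl, sum(present)),
               key = .join_key(harmonized[present, , drop = FALSE], fields),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Record ids that emit no block key
#'
#' @inheritParams block_keys
#' @return character vector of unblockable record ids.
#' @export
unblockable_records <- function(harmonized) {
  keys <- block_keys(harmonized)
  setdiff(harmonized$record_id, keys$record_id)
}

#' Build candidate pairs from two harmonized files
#'
#' A pair is emitted iff the two records share at least one block key. The
#' result is deduplicated over clauses and sorted by `id_a`, then `id_b`;
#' `via` records which clause(s) co-blocked the pair (`"1"`, `"2"` or
#' `"1,2"`).
#'
#' @param harmonized_a,harmonized_b harmonized record tables for the two
#'   files.
#' @param block_cap optional maximum number of records (both files pooled)
#'   allowed in one block; oversized blocks are dropped with a warning.
#'   Default `Inf` (no cap).
#' @return data.frame with columns `id_a`, `id_b`, `via`.
#' @export
build_candidate_pairs <- function(harmonized_a, harmonized_b,
                                  block_cap = Inf) {
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      via = character(0), stringsAsFactors = FALSE)
  if (nrow(harmonized_a) == 0L || nrow(harmonized_b) == 0L) {
    warning("one of the input files has no records; no candidate pairs",
            call. = FALSE)
    return(empty)
  }
  ka <- block_keys(harmonized_a)
  kb <- block_keys(harmonized_b)
  pieces <- lapply(c(1L, 2L), function(cl) {
    a <- ka[ka$clause_id == cl, ]
    b <- kb[kb$clause_id == cl, ]
    if (!nrow(a) || !nrow(b)) return(NULL)
    if (is.finite(block_cap)) {
      sizes <- table(c(a$key, b$key))
      big <- names(sizes)[sizes > block_cap]
      if (length(big)) {
        warning(sprintf("clause %d: dropping %d oversized block(s) (cap %d)",
                        cl, length(big), block_cap), call. = FALSE)
        a <- a[!(a$key %in% big), ]
        b <- b[!(b$key %in% big), ]
      }
    }
    m <- merge(a[c("key", "record_id")], b[c("key", "record_id")],
               by = "key", suffixes = c("_a", "_b"))
    if (!nrow(m)) return(NULL)
    data.frame(id_a = m$record_id_a, id_b = m$record_id_b,
               clause_id = cl, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  if (is.null(all) || !nrow(all)) return(empty)
  key <- paste(all$id_a, all$id_b, sep = "\x1f")
  via <- vapply(split(all$clause_id, key),
                function(cl) paste(sort(unique(cl)), collapse = ","),
                character(1))
  first <- !duplicated(key)
  out <- data.frame(id_a = all$id_a[first], id_b = all$id_b[first],
                    via = unname(via[match(key[first], names(via))]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$id_a, out$id_b), ]
  rownames(out) <- NULL
  out
}

#' Dump block membership for audit
#'
#' @param harmonized harmonized record table.
#' @param file_label label of the source file (e.g. `"a"` or `"b"`).
#' @param path CSV path.
#' @export
write_block_dump <- function(harmonized, file_label, path) {
  keys <- block_keys(harmonized)
  keys$file <- file_label
  utils::write.csv(keys[c("clause_id", "key", "record_id", "file")],
                   path, row.names = FALSE)
  invisible(path)
}
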