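#' Harmonization settings
#'
#' Controls how raw attribute values are normalized before blocking and
#' encoding. The only tunable is the input date dialect: `"iso"` expects
#' dates shaped like `YYYY-MM-DD` (any non-digit separators are ignored),
#' `"dmy"` expects `DDMMYYYY` (again separators are ignored; the canonical
#' internal form `YYYYMMDD` is also accepted so harmonization stays
#' idempotent).
#'
#' @param date_dialect `"iso"` or `"dmy"`.
#' @return A list of class `harmonize_config`.
#' @export
harmonize_config <- function(date_dialect = c("iso", "dmy")) {
  structure(list(date_dialect = match.arg(date_dialect)),
            class = "harmonize_config")
}

#' The five linkage attributes
#'
#' Attribute order is fixed throughout the package: it determines the
#' segment order of the composite Bloom filter.
#' @export
linkage_attributes <- function() {
  c("name", "mother_name", "date_of_birth", "municipality_code", "gender")
}

# Missing values are carried as the empty string "" everywhere internally
# and written out as empty CSV cells.
missing_sentinel <- function() ""

#' Normalize free text to linkage form
#'
#' Uppercases, strips accents by Unicode transliteration to ASCII, replaces
#' every non-alphanumeric run by a single space and trims. Idempotent.
#'
#' @param x character vector.
#' @return character vector containing only `A-Z`, `0-9` and single internal
#'   spaces; empty string where the input was empty or `NA`.
#' @export
harmonize_text <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- toupper(x)
  x <- gsub("[^A-Z0-9]+", " ", x)
  trimws(x)
}

# Valid calendar date with a plausible birth year. Years outside
# [1850, 2100] are rejected so that the DDMMYYYY reading can never
# swallow a canonical YYYYMMDD string (its "year" would be the MMDD part).
.valid_ymd <- function(y, m, d) {
  yn <- suppressWarnings(as.integer(y))
  ok <- !is.na(yn) & yn >= 1850 & yn <= 2100
  date <- rep(as.Date(NA), length(y))
  if (any(ok)) {
    date[ok] <- as.Date(paste(y[ok], m[ok], d[ok], sep = "-"),
                        format = "%Y-%m-%d")
  }
  ok & !is.na(date)
}

#' Canonicalize dates of birth
#'
#' Non-digits are stripped, then the remaining digits are read under the
#' configured dialect. Unparseable values become the missing sentinel with
#' a warning (never an error): a corrupted date should not abort a linkage
#' run, it should just leave that attribute missing.
#'
#' @param x character vector of raw date strings.
#' @param dialect `"iso"` (year first) or `"dmy"` (day first, canonical
#'   `YYYYMMDD` accepted as fallback).
#' @return character vector of `YYYYMMDD` strings or `""`.
#' @export
harmonize_date <- function(x, dialect = c("iso", "dmy")) {
  dialect <- match.arg(dialect)
  x <- as.character(x)
  x[is.na(x)] <- ""
  digits <- gsub("[^0-9]", "", x)
  out <- rep(missing_sentinel(), length(x))
  eight <- nchar(digits) == 8
  if (any(eight)) {
    d8 <- digits[eight]
    if (dialect == "iso") {
      y <- substr(d8, 1, 4); m <- substr(d8, 5, 6); d <- substr(d8, 7, 8)
      ok <- .valid_ymd(y, m, d)
      out[eight][ok] <- paste0(y, m, d)[ok]
    } else {
      d <- substr(d8, 1, 2); m <- substr(d8, 3, 4); y <- substr(d8, 5, 8)
      ok_dmy <- .valid_ymd(y, m, d)
      y2 <- substr(d8, 1, 4); m2 <- substr(d8, 5, 6); d2 <- substr(d8, 7, 8)
      ok_can <- !ok_dmy & .valid_ymd(y2, m2, d2)
      out[eight][ok_dmy] <- paste0(y, m, d)[ok_dmy]
      out[eight][ok_can] <- d8[ok_can]
    }
  }
  bad <- nzchar(x) & !nzchar(out)
  if (any(bad)) {
    warning(sprintf("%d date value(s) unparseable under dialect '%s'; set to missing",
                    sum(bad), dialect), call. = FALSE)
  }
  out
}

#' Harmonize a table of person records
#'
#' Applies the full normalization to each linkage attribute and derives the
#' secondary blocking attributes: `surname` (last whitespace token of the
#' harmonized name), `mother_surname`, and `year_of_birth` (first four
#' characters of the canonical date). Missing values are the empty string;
#' `missing_flags()` recovers them as booleans.
#'
#' @param records data.frame with columns `record_id`, `name`,
#'   `mother_name`, `date_of_birth`, `gender`, `municipality_code`.
#' @param config a [harmonize_config()].
#' @return data.frame of harmonized records (one row per input row).
#' @export
harmonize_records <- function(records, config = harmonize_config()) {
  stopifnot(is.data.frame(records))
  required <- c("record_id", linkage_attributes())
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  id <- as.character(records$record_id)
  if (any(is.na(id) | !nzchar(id))) stop("record_id must be non-empty")
  if (anyDuplicated(id)) stop("record_id must be unique within a file")

  name <- harmonize_text(records$name)
  mother <- harmonize_text(records$mother_name)
  dob <- harmonize_date(records$date_of_birth, config$date_dialect)
  gender_full <- harmonize_text(records$gender)
  gender <- substr(gender_full, 1, 1)
  muni <- gsub("[^0-9]", "", ifelse(is.na(records$municipality_code), "",
                                    as.character(records$municipality_code)))

  data.frame(
    record_id = id,
    name = name,
    mother_name = mother,
    surname = last_token(name),
    mother_surname = last_token(mother),
    date_of_birth = dob,
    year_of_birth = ifelse(nzchar(dob), substr(dob, 1, 4), missing_sentinel()),
    gender = gender,
    municipality_code = muni,
    stringsAsFactors = FALSE
  )
}

#' @rdname harmonize_records
#' @param record a single raw record as a list or one-row data.frame.
#' @export
harmonize_record <- function(record, config = harmonize_config()) {
  harmonize_records(as.data.frame(record, stringsAsFactors = FALSE), config)
}

# Last whitespace-delimited token; "" stays "".
last_token <- function(x) {
  vapply(strsplit(x, " ", fixed = TRUE), function(t) {
    if (!length(t)) missing_sentinel() else t[[length(t)]]
  }, character(1))
}

#' Per-field missingness flags
#'
#' @param harmonized output of [harmonize_records()].
#' @return logical matrix, one column per linkage attribute.
#' @export
missing_flags <- function(harmonized) {
  attrs <- linkage_attributes()
  out <- vapply(attrs, function(a) !nzchar(harmonized[[a]]),
                logical(nrow(harmonized)))
  if (nrow(harmonized) == 1L) out <- matrix(out, nrow = 1,
                                            dimnames = list(NULL, attrs))
  out
}

#' Missingness report over the linkage attributes
#'
#' @param harmonized output of [harmonize_records()]; must be non-empty.
#' @return data.frame with one row per linkage attribute: `attribute`,
#'   `n_missing`, `pct_missing` (0-100).
#' @export
missingness_report <- function(harmonized) {
  if (!is.data.frame(harmonized) || nrow(harmonized) == 0L) {
    stop("no records: missingness report needs at least one record")
  }
  flags <- missing_flags(harmonized)
  n_missing <- colSums(flags)
  data.frame(
    attribute = linkage_attributes(),
    n_missing = as.integer(n_missing),
    pct_missing = 100 * n_missing / nrow(harmonized),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
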