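# Synthetic paired cohort files with a known gold standard.
#
# The generator emulates the shape of Brazilian cohort/registry extracts:
# multi-token accented names with the family surname last, a mother's full
# name sharing that surname, dates of birth, a 7-digit municipality code
# and a one-letter gender code. Records reappearing in the second file are
# re-rendered (fresh casing/spacing noise) and then corrupted under a
# configurable error model, so every pipeline stage can be tested without
# restricted person-level data.

#' Corruption model for the synthetic generator
#'
#' Per-record error probabilities applied to the second file's copy of each
#' overlapping record. Defaults emulate an administrative extract of
#' middling quality: a few percent of name fields carry one typo, around
#' two percent of values are missing, and token drops, date-digit errors,
#' gender flips and municipality changes are rarer.
#'
#' @param p_typo probability, per name field, of one character
#'   substitution/deletion/insertion.
#' @param p_token_drop probability of dropping one name token.
#' @param p_date_digit probability of one digit error in the date of birth.
#' @param p_missing per-field probability of the value being blanked.
#' @param p_gender_flip probability of the gender code flipping.
#' @param p_muni_change probability of the municipality code changing.
#' @param seed integer seed; identical seed and config give byte-identical
#'   output files.
#' @return list of class `corruption_config`.
#' @export
corruption_config <- function(p_typo = 0.05, p_token_drop = 0.01,
                              p_date_digit = 0.02, p_missing = 0.02,
                              p_gender_flip = 0.01, p_muni_change = 0.01,
                              seed = 1L) {
  probs <- c(p_typo = p_typo, p_token_drop = p_token_drop,
             p_date_digit = p_date_digit, p_missing = p_missing,
             p_gender_flip = p_gender_flip, p_muni_change = p_muni_change)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must be in [0, 1]")
  structure(c(as.list(probs), list(seed = as.integer(seed))),
            class = "corruption_config")
}

#' @rdname corruption_config
#' @export
no_corruption <- function(seed = 1L) {
  corruption_config(0, 0, 0, 0, 0, 0, seed = seed)
}

# One typo: substitution, deletion or insertion at a random position.
# The replacement alphabet includes accented letters so typos can inject
# non-ASCII noise that harmonization must absorb.
.typo_alphabet <- c(LETTERS, "Á", "É", "Ç", "Ã", "Õ")

.apply_typo <- function(s) {
  n <- nchar(s)
  if (n < 2L) return(s)
  pos <- sample.int(n, 1L)
  op <- sample(c("sub", "del", "ins"), 1L)
  ch <- sample(.typo_alphabet, 1L)
  switch(op,
         sub = paste0(substr(s, 1, pos - 1), ch, substr(s, pos + 1, n)),
         del = paste0(substr(s, 1, pos - 1), substr(s, pos + 1, n)),
         ins = paste0(substr(s, 1, pos), ch, substr(s, pos + 1, n)))
}

.drop_token <- function(s) {
  toks <- strsplit(trimws(s), " +")[[1]]
  if (length(toks) < 2L) return(s)
  paste(toks[-sample.int(length(toks), 1L)], collapse = " ")
}

.corrupt_date_digit <- function(s) {
  pos <- gregexpr("[0-9]", s)[[1]]
  if (pos[1] == -1) return(s)
  p <- sample(as.integer(pos), 1L)
  old <- substr(s, p, p)
  new <- sample(setdiff(as.character(0:9), old), 1L)
  paste0(substr(s, 1, p - 1), new, substr(s, p + 1, nchar(s)))
}

# Random raw rendering of a clean person: casing style, occasional double
# spaces and stray punctuation, so files look like real keyboard entry.
.render_name <- function(x) {
  style <- sample(3L, length(x), replace = TRUE)
  out <- x
  out[style == 2L] <- tolower(out[style == 2L])
  out[style == 3L] <- stringi::stri_trans_totitle(out[style == 3L])
  pad <- stats::runif(length(out)) < 0.08
  out[pad] <- paste0(" ", out[pad], " ")
  dots <- stats::runif(length(out)) < 0.04
  out[dots] <- paste0(out[dots], ".")
  dbl <- stats::runif(length(out)) < 0.08
  out[dbl] <- sub(" ", "  ", out[dbl])
  out
}

.render_date_iso <- function(ymd) {
  paste(substr(ymd, 1, 4), substr(ymd, 5, 6), substr(ymd, 7, 8), sep = "-")
}

.make_persons <- function(n, munis) {
  gender <- sample(c("M", "F"), n, replace = TRUE)
  given <- ifelse(gender == "M",
                  sample(.synth_given_male, n, replace = TRUE),
                  sample(.synth_given_female, n, replace = TRUE))
  middle <- sample(c(.synth_given_female, .synth_given_male), n, replace = TRUE)
  has_middle <- stats::runif(n) < 0.6
  surname <- sample(.synth_surnames, n, replace = TRUE)
  m_given <- sample(.synth_given_female, n, replace = TRUE)
  m_middle <- sample(.synth_given_female, n, replace = TRUE)
  m_has_middle <- stats::runif(n) < 0.5
  name <- paste(given, ifelse(has_middle, paste(middle, ""), ""), surname)
  name <- gsub(" +", " ", trimws(name))
  mother <- paste(m_given, ifelse(m_has_middle, paste(m_middle, ""), ""),
                  surname)
  mother <- gsub(" +", " ", trimws(mother))
  year <- sample(1940:2010, n, replace = TRUE)
  month <- sample.int(12L, n, replace = TRUE)
  day <- sample.int(28L, n, replace = TRUE)
  data.frame(
    name = name, mother_name = mother,
    dob = sprintf("%04d%02d%02d", year, month, day),
    gender = gender,
    municipality_code = sample(munis, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

.render_file <- function(persons, ids) {
  g <- persons$gender
  low <- stats::runif(length(g)) < 0.3
  g[low] <- tolower(g[low])
  data.frame(
    record_id = ids,
    name = .render_name(persons$name),
    mother_name = .render_name(persons$mother_name),
    date_of_birth = .render_date_iso(persons$dob),
    gender = g,
    municipality_code = persons$municipality_code,
    stringsAsFactors = FALSE
  )
}

.corrupt_file <- function(raw, cfg, munis) {
  n <- nrow(raw)
  hit <- function(p) stats::runif(n) < p
  for (field in c("name", "mother_name")) {
    t <- which(hit(cfg$p_typo))
    raw[[field]][t] <- vapply(raw[[field]][t], .apply_typo, character(1))
    d <- which(hit(cfg$p_token_drop))
    raw[[field]][d] <- vapply(raw[[field]][d], .drop_token, character(1))
  }
  dd <- which(hit(cfg$p_date_digit))
  raw$date_of_birth[dd] <- vapply(raw$date_of_birth[dd], .corrupt_date_digit,
                                  character(1))
  gf <- hit(cfg$p_gender_flip)
  raw$gender[gf] <- ifelse(toupper(raw$gender[gf]) == "M", "F", "M")
  mc <- which(hit(cfg$p_muni_change))
  raw$municipality_code[mc] <- sample(munis, length(mc), replace = TRUE)
  for (field in c("name", "mother_name", "date_of_birth", "gender",
                  "municipality_code")) {
    raw[[field]][hit(cfg$p_missing)] <- ""
  }
  raw
}

#' Generate a paired synthetic cohort with a gold standard
#'
#' File A holds `n` records. `round(overlap * n)` of those persons reappear
#' in file B under new record ids, re-rendered and corrupted per the
#' corruption model; file B additionally holds `n_noise` unrelated noise
#' persons. The gold standard lists the true A-B correspondences. Fully
#' deterministic for a fixed config.
#'
#' @param n number of records in file A.
#' @param overlap fraction of file-A persons that reappear in file B.
#' @param corruption a [corruption_config()].
#' @param n_noise number of non-matching noise records in file B (default
#'   20 percent of `n`).
#' @param out_dir optional directory; when given, writes `file_a.csv`,
#'   `file_b.csv` and `gold.csv`.
#' @return list with `file_a`, `file_b`, `gold` (data.frames) and the
#'   `corruption` config.
#' @export
generate_cohort <- function(n, overlap = 1,
                            corruption = corruption_config(),
                            n_noise = round(0.2 * n), out_dir = NULL) {
  if (n < 1L) stop("n must be >= 1")
  if (overlap < 0 || overlap > 1) stop("overlap must be in [0, 1]")
  if (n_noise < 0L) stop("n_noise must be >= 0")
  set.seed(corruption$seed)
  munis <- .synth_municipalities()
  persons <- .make_persons(n + n_noise, munis)

  ids_a <- sprintf("A%06d", seq_len(n))
  file_a <- .render_file(persons[seq_len(n), , drop = FALSE], ids_a)

  n_over <- round(overlap * n)
  over_idx <- sort(sample.int(n, n_over))
  b_persons <- rbind(persons[over_idx, , drop = FALSE],
                     persons[n + seq_len(n_noise), , drop = FALSE])
  ids_b <- sprintf("B%06d", seq_len(nrow(b_persons)))
  file_b <- .render_file(b_persons, ids_b)
  keep <- seq_len(n_over)
  file_b[keep, -1] <- .corrupt_file(file_b[keep, , drop = FALSE],
                                    corruption, munis)[, -1]
  gold <- data.frame(id_a = ids_a[over_idx], id_b = ids_b[keep],
                     stringsAsFactors = FALSE)
  shuffle <- sample.int(nrow(file_b))
  file_b <- file_b[shuffle, , drop = FALSE]
  rownames(file_b) <- NULL

  out <- list(file_a = file_a, file_b = file_b, gold = gold,
              corruption = corruption)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(file_a, file.path(out_dir, "file_a.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(file_b, file.path(out_dir, "file_b.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(gold, file.path(out_dir, "gold.csv"), row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  out
}
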