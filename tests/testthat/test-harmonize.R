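test_that("text normalization strips accents, case and punctuation", {
  h <- harmonize_record(list(
    record_id = "r1", name = "  José da  Silva! ",
    mother_name = "Maria Conceição-Silva", date_of_birth = "1999-02-13",
    gender = "f", municipality_code = "29.12345"))
  expect_equal(h$name, "JOSE DA SILVA")
  expect_equal(h$surname, "SILVA")
  expect_equal(h$mother_name, "MARIA CONCEICAO SILVA")
  expect_equal(h$mother_surname, "SILVA")
  expect_equal(h$date_of_birth, "19990213")
  expect_equal(h$year_of_birth, "1999")
  expect_equal(h$gender, "F")
  expect_equal(h$municipality_code, "2912345")
})

test_that("empty fields become the missing sentinel with flags set", {
  h <- harmonize_record(list(record_id = "r1", name = "Ana Souza",
                             mother_name = "", date_of_birth = "",
                             gender = NA, municipality_code = ""))
  expect_equal(h$mother_name, "")
  expect_equal(h$mother_surname, "")
  expect_equal(h$year_of_birth, "")
  flags <- missing_flags(h)
  expect_true(flags[1, "mother_name"])
  expect_true(flags[1, "gender"])
  expect_false(flags[1, "name"])
})

test_that("date parsing handles both dialects and degrades to missing", {
  expect_equal(harmonize_date("1999-02-13", "iso"), "19990213")
  expect_equal(harmonize_date("13/02/1999", "dmy"), "19990213")
  expect_equal(harmonize_date("25121990", "dmy"), "19901225")
  # canonical YYYYMMDD is accepted under dmy, so re-harmonization is stable
  expect_equal(harmonize_date("20120506", "dmy"), "20120506")
  expect_warning(out <- harmonize_date("1999-13-40", "iso"), "unparseable")
  expect_equal(out, "")
  expect_warning(out2 <- harmonize_date("notadate", "iso"), "unparseable")
  expect_equal(out2, "")
  expect_equal(harmonize_date("", "iso"), "")
})

test_that("harmonization is idempotent over noisy random strings", {
  set.seed(101)
  pool <- c(LETTERS, letters, "é", "ã", "ç", "Á", "-", ".", "!", " ", "0",
            "7", "  ")
  raw <- vapply(1:200, function(i) {
    paste(sample(pool, sample(3:25, 1), replace = TRUE), collapse = "")
  }, character(1))
  df <- data.frame(record_id = as.character(1:200), name = raw,
                   mother_name = rev(raw),
                   date_of_birth = sample(c("1999-02-13", "junk", ""), 200, TRUE),
                   gender = sample(c("M", "feminino", ""), 200, TRUE),
                   municipality_code = sample(c("29-12345", "abc", ""), 200, TRUE),
                   stringsAsFactors = FALSE)
  h1 <- suppressWarnings(harmonize_records(df))
  h2 <- suppressWarnings(harmonize_records(h1))
  expect_identical(h1, h2)
  # alphabet invariant
  expect_true(all(grepl("^$|^[A-Z0-9]+( [A-Z0-9]+)*$", h1$name)))
})

test_that("surname extraction: single token is its own surname, missing stays missing", {
  h <- harmonize_records(data.frame(
    record_id = c("1", "2"), name = c("Madonna", ""),
    mother_name = c("x", "y"), date_of_birth = "", gender = "",
    municipality_code = "", stringsAsFactors = FALSE))
  expect_equal(h$surname, c("MADONNA", ""))
})

test_that("record ids must be present and unique", {
  base <- data.frame(record_id = c("1", "1"), name = "a", mother_name = "b",
                     date_of_birth = "", gender = "", municipality_code = "",
                     stringsAsFactors = FALSE)
  expect_error(harmonize_records(base), "unique")
  base$record_id <- c("1", "")
  expect_error(harmonize_records(base), "non-empty")
  expect_error(harmonize_records(base[, -2]), "missing required column")
})

test_that("missingness report counts per-attribute percentages", {
  h <- harmonize_records(data.frame(
    record_id = as.character(1:4), name = "Ana Silva",
    mother_name = "Bia Silva", date_of_birth = "1980-01-02",
    gender = c("F", "F", "F", ""), municipality_code = "123",
    stringsAsFactors = FALSE))
  rep <- missingness_report(h)
  expect_equal(rep$pct_missing[rep$attribute == "gender"], 25.0)
  expect_equal(rep$pct_missing[rep$attribute == "name"], 0.0)
  all_missing <- harmonize_records(data.frame(
    record_id = "1", name = "", mother_name = "", date_of_birth = "",
    gender = "", municipality_code = "", stringsAsFactors = FALSE))
  expect_true(all(missingness_report(all_missing)$pct_missing == 100))
  expect_error(missingness_report(h[0, ]), "no records")
})
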