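test_that("dice matches hand-computed values and is symmetric", {
  f <- function(bits, n = 10) { v <- integer(n); v[bits + 1L] <- 1L; v }
  d <- dice(f(0:3), f(2:5))
  expect_equal(d$h, 2L)
  expect_equal(d$a, 4L)
  expect_equal(d$b, 4L)
  expect_equal(d$dice_raw, 0.5)
  expect_equal(d$dice_norm, 5000L)

  ident <- dice(f(0:3), f(0:3))
  expect_equal(ident$dice_raw, 1)
  expect_equal(ident$dice_norm, 10000L)

  disjoint <- dice(f(0:3), f(5:8))
  expect_equal(disjoint$dice_norm, 0L)

  expect_equal(dice(f(0:3), f(2:5))$dice_norm, dice(f(2:5), f(0:3))$dice_norm)
  expect_error(dice(f(0:3), f(0:3, n = 12)), "length")

  both_empty <- dice(integer(10), integer(10))
  expect_equal(both_empty$dice_norm, 0L)
  expect_true(both_empty$both_missing)
})

test_that("categories partition scores at the documented boundaries", {
  expect_equal(categorize(10000), "exact")
  expect_equal(categorize(9999), "strong")
  expect_equal(categorize(9000), "strong")
  expect_equal(categorize(8999), "weak")
  expect_equal(categorize(8000), "weak")
  expect_equal(categorize(7999), "unpaired")
  expect_equal(categorize(0), "unpaired")
  expect_error(categorize(10001), "10000")
  expect_error(categorize(-1), "10000")
  # exhaustive partition: exactly one category everywhere
  cats <- categorize(0:10000)
  expect_equal(unname(table(cats)[c("unpaired", "weak", "strong", "exact")]),
               c(8000L, 1000L, 1000L, 1L),
               ignore_attr = TRUE)
})

test_that("full comparison equals dice of the concatenated composite", {
  ha <- make_harmonized("a1")
  hb <- make_harmonized("b1", name = "JOSE DE SILVA", dob = "19850313")
  fa <- encode_records(ha); fb <- encode_records(hb)
  got <- compare_pairs(data.frame(id_a = "a1", id_b = "b1"), fa, fb,
                       mode = "full")
  expect_equal(got$score, dice(fa["a1", ], fb["b1", ])$dice_norm)
  ident <- compare_pairs(data.frame(id_a = "a1", id_b = "a1"), fa, fa,
                         mode = "full")
  expect_equal(ident$score, 10000L)
  expect_error(compare_pairs(data.frame(id_a = "zz", id_b = "b1"), fa, fb),
               "zz")
})

test_that("hybrid scoring follows the bit-budget weighted mean", {
  ha <- make_harmonized("a1")
  fa <- encode_records(ha)

  same <- compare_pairs(data.frame(id_a = "a1", id_b = "a1"), fa, fa)
  expect_equal(same$score, 10000L)
  expect_equal(same$name_category, "exact")
  expect_true(same$municipality_code_equal)

  # identical except gender: combined = round(10000 * 160/180) = 8889
  hb <- make_harmonized("b1", gender = "F")
  fb <- encode_records(hb)
  g <- compare_pairs(data.frame(id_a = "a1", id_b = "b1"), fa, fb)
  expect_equal(g$score, 8889L)
  expect_false(g$gender_equal)
  expect_equal(g$name_category, "exact")

  # generic weighted-mean oracle over corrupted synthetic pairs
  cc <- corruption_config(p_typo = 0.6, p_token_drop = 0.1,
                          p_date_digit = 0.3, p_missing = 0,
                          p_gender_flip = 0.2, p_muni_change = 0.2, seed = 5)
  syn <- generate_cohort(80, 1, cc, n_noise = 0)
  h1 <- harmonize_records(syn$file_a)
  h2 <- suppressWarnings(harmonize_records(syn$file_b))
  f1 <- encode_records(h1); f2 <- encode_records(h2)
  pairs <- data.frame(id_a = syn$gold$id_a, id_b = syn$gold$id_b)
  res <- compare_pairs(pairs, f1, f2)
  full_present <- !res$all_missing &
    !is.na(res$name_score) & !is.na(res$municipality_code_equal) &
    !is.na(res$gender_equal) & !is.na(res$date_of_birth_score)
  expected <- floor((res$name_score * 50 + res$mother_name_score * 50 +
                     res$date_of_birth_score * 40 +
                     ifelse(res$municipality_code_equal, 10000, 0) * 20 +
                     ifelse(res$gender_equal, 10000, 0) * 20) / 180 + 0.5)
  expect_equal(res$score[full_present], as.integer(expected[full_present]))
})

test_that("attributes missing on both sides are excluded from the mean", {
  ha <- make_harmonized("a1", gender = "")
  hb <- make_harmonized("b1", gender = "")
  fa <- encode_records(ha); fb <- encode_records(hb)
  r <- compare_pairs(data.frame(id_a = "a1", id_b = "b1"), fa, fb)
  expect_equal(r$score, 10000L)  # all comparable attributes identical
  expect_true(is.na(r$gender_equal))

  # one-sided missingness is disagreement, not absence
  hc <- make_harmonized("c1", gender = "M")
  fc <- encode_records(hc)
  r2 <- compare_pairs(data.frame(id_a = "c1", id_b = "b1"), fc, fb)
  expect_false(r2$gender_equal)
  expect_equal(r2$score, 8889L)
})

test_that("hybrid beats full scoring on most mildly corrupted true pairs", {
  cc <- corruption_config(p_typo = 1, p_token_drop = 0, p_date_digit = 0,
                          p_missing = 0, p_gender_flip = 0,
                          p_muni_change = 0, seed = 3)
  syn <- generate_cohort(1200, 1, cc, n_noise = 0)
  h1 <- harmonize_records(syn$file_a)
  h2 <- harmonize_records(syn$file_b)
  f1 <- encode_records(h1); f2 <- encode_records(h2)
  pairs <- data.frame(id_a = syn$gold$id_a, id_b = syn$gold$id_b)
  s_full <- compare_pairs(pairs, f1, f2, mode = "full")$score
  s_hyb <- compare_pairs(pairs, f1, f2, mode = "hybrid")$score
  expect_gt(mean(s_hyb > s_full), 0.5)
})
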