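test_that("cutoff boundaries: upper accepts, lower stays dubious", {
  expect_equal(classify_pair(9400), "match")
  expect_equal(classify_pair(10000), "match")
  expect_equal(classify_pair(9399), "dubious")
  expect_equal(classify_pair(9000), "dubious")
  expect_equal(classify_pair(8800), "dubious")
  expect_equal(classify_pair(8799), "non_match")
  expect_equal(classify_pair(8700), "non_match")
  expect_error(classify_pair(10500), "10000")
  expect_error(cutoff_config(upper = 8000, lower = 9000), "lower < upper")
})

test_that("second round narrows the band symmetrically", {
  dub <- data.frame(id_a = c("a1", "a2", "a3"), id_b = c("b1", "b2", "b3"),
                    score = c(9350L, 8850L, 9100L), label = "dubious",
                    round = 1L, stringsAsFactors = FALSE)
  out <- second_round(dub, cutoff_config())
  expect_equal(out$label, c("match", "non_match", "dubious"))
  expect_equal(out$round, c(2L, 2L, 1L))
  expect_error(second_round(transform(dub, label = "match")), "dubious")
})

test_that("band inversion stops iteration with a warning", {
  dub <- data.frame(id_a = "a", id_b = "b", score = 9000L,
                    label = "dubious", round = 1L, stringsAsFactors = FALSE)
  cfg <- cutoff_config(upper = 9100, lower = 9000, shift_step = 100,
                       max_rounds = 3)
  expect_warning(out <- second_round(dub, cfg), "invert")
  expect_equal(out$label, "dubious")  # shifting would cross the band, so no relabel

})

test_that("classification partitions every score exactly once", {
  scores <- data.frame(id_a = as.character(0:10000), id_b = "b",
                       score = 0:10000, stringsAsFactors = FALSE)
  dec <- classify_all(scores, cutoff_config(max_rounds = 1))
  expect_equal(nrow(dec), 10001L)
  expect_true(all(dec$label %in% c("match", "non_match", "dubious")))
  expect_equal(sum(dec$label == "match"), 601L)       # 9400..10000
  expect_equal(sum(dec$label == "non_match"), 8800L)  # 0..8799
  expect_equal(sum(dec$label == "dubious"), 600L)     # 8800..9399
})

test_that("second round only relabels dubious pairs, never earlier decisions", {
  scores <- data.frame(id_a = as.character(1:5), id_b = as.character(1:5),
                       score = c(9500L, 9350L, 9100L, 8850L, 8000L),
                       stringsAsFactors = FALSE)
  r1 <- classify_all(scores, cutoff_config(max_rounds = 1))
  r2 <- classify_all(scores, cutoff_config(max_rounds = 2))
  # round-1 decisions preserved
  decided <- r1$label != "dubious"
  expect_equal(r2$label[decided], r1$label[decided])
  expect_equal(r2$label, c("match", "match", "dubious", "non_match",
                           "non_match"))
  expect_equal(r2$round, c(1L, 2L, 1L, 2L, 1L))
})

test_that("raising cutoffs is monotone in the match/non-match counts", {
  set.seed(42)
  scores <- data.frame(id_a = as.character(1:500), id_b = as.character(1:500),
                       score = sample(0:10000, 500), stringsAsFactors = FALSE)
  uppers <- c(9000L, 9400L, 9800L)
  n_match <- vapply(uppers, function(u) {
    sum(classify_all(scores, cutoff_config(upper = u, max_rounds = 1))$label
        == "match")
  }, integer(1))
  expect_true(all(diff(n_match) <= 0))
  lowers <- c(8000L, 8800L, 9200L)
  n_non <- vapply(lowers, function(l) {
    sum(classify_all(scores, cutoff_config(lower = l, max_rounds = 1))$label
        == "non_match")
  }, integer(1))
  expect_true(all(diff(n_non) >= 0))
})

test_that("greedy dedup keeps the best pair per record", {
  d <- data.frame(id_a = c("A1", "A1"), id_b = c("B1", "B2"),
                  score = c(9800L, 9500L), label = "match", round = 1L,
                  stringsAsFactors = FALSE)
  out <- best_match_dedup(d)
  expect_equal(nrow(out), 1L)
  expect_equal(out$id_b, "B1")

  tie <- data.frame(id_a = c("A1", "A1"), id_b = c("B2", "B1"),
                    score = 9600L, label = "match", round = 1L,
                    stringsAsFactors = FALSE)
  out2 <- best_match_dedup(tie)
  expect_equal(out2$id_b, "B1")  # lexicographic tie-break

  disjoint <- data.frame(id_a = c("A1", "A2"), id_b = c("B1", "B2"),
                         score = c(9500L, 9600L), label = "match",
                         round = 1L, stringsAsFactors = FALSE)
  expect_equal(nrow(best_match_dedup(disjoint)), 2L)
})
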