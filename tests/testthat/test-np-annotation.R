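test_that("the shipped worked-example fixture classifies to its labels", {
  fx <- load_table1_fixture()
  sp <- np_spans(fx$spans$start, fx$spans$end, fx$spans$head_lemma,
                 fx$spans$is_pronoun, fx$spans$is_null_subject,
                 fx$spans$anaphoric, fx$spans$generic, fx$spans$anomaly)
  a <- annotate_transcript(fx$transcript, sp)
  expect_identical(a$spans$category, fx$spans$expected_category)
})

test_that("classification cascade has the documented precedence", {
  tokens <- tokens_frame(c("kitapları", "evler"),
                         pos = "noun",
                         case = c("accusative", "none"),
                         plural = c(TRUE, TRUE))
  # anaphoric flag beats case marking beats plural beats generic
  s <- span1(0, 1, "kitap", anaphoric = TRUE, generic = TRUE)
  expect_identical(classify_np(s, tokens), "bare_anaphoric")
  s <- span1(0, 1, "kitap", generic = TRUE)
  expect_identical(classify_np(s, tokens), "bare_specific")
  s <- span1(1, 2, "ev", generic = TRUE)
  expect_identical(classify_np(s, tokens), "bare_indefinite")
  # pronoun beats determiner features
  tk2 <- tokens_frame("o", pos = "pronoun", determiner = "indefinite")
  s <- span1(0, 1, "o", is_pronoun = TRUE)
  expect_identical(classify_np(s, tk2), "lexical_pronoun")
  # total fallback
  tk3 <- tokens_frame("kız", pos = "noun")
  expect_identical(classify_np(span1(0, 1, "kız"), tk3), "bare_residual")
})

test_that("every valid feature combination yields a category", {
  dets <- c("none", "indefinite", "demonstrative")
  cases <- c("none", "accusative", "other")
  for (d in dets) for (cs in cases) for (pl in c(TRUE, FALSE))
    for (an in c(NA, TRUE, FALSE)) for (ge in c(NA, TRUE)) {
      tk <- tokens_frame("ev", pos = "noun", determiner = d, case = cs,
                         plural = pl)
      s <- span1(0, 1, "ev", anaphoric = an, generic = ge)
      expect_true(classify_np(s, tk) %in%
                    c("indefinite_dp", "definite_dp", "bare_anaphoric",
                      "bare_specific", "bare_indefinite", "bare_generic",
                      "bare_residual"))
    }
})

test_that("contradictory and invalid spans are rejected", {
  tk <- tokens_frame("bu", pos = "det", determiner = "demonstrative",
                     agreement_subject = TRUE)
  s <- span1(0, 0, "", is_null_subject = TRUE)
  expect_error(classify_np(s, tk), "contradictory")
  tk2 <- tokens_frame("ev", pos = "noun")
  expect_error(classify_np(span1(0, 0, "ev"), tk2), "start < end")
  expect_error(classify_np(span1(3, 4, "ev"), tk2), "outside")
})

test_that("registry drives anaphora and is narration-local", {
  t <- make_mini_transcript()
  a <- annotate_transcript(t, mini_spans())
  expect_identical(a$spans$category, c("indefinite_dp", "bare_anaphoric"))

  # an explicit FALSE manual flag overrides the lemma match
  sp <- mini_spans()
  sp$anaphoric[2] <- FALSE
  a2 <- annotate_transcript(t, sp)
  expect_identical(a2$spans$category[2], "bare_residual")

  # a second narration with the same spans starts from an empty registry:
  # its first bare "adam" span is introduced by the DP again, so results
  # are identical, not cumulative
  t2 <- make_mini_transcript("P1", "NC", 2L)
  b <- annotate_transcript(t2, mini_spans())
  expect_identical(b$spans$category, a$spans$category)

  # but a bare first mention with no DP introduction is residual
  sp_only_bare <- np_spans(4L, 5L, "adam")
  c1 <- annotate_transcript(t2, sp_only_bare)
  expect_identical(c1$spans$category, "bare_residual")
})

test_that("annotation rejects unsorted and overlapping lexical spans", {
  t <- make_mini_transcript()
  sp <- mini_spans()[2:1, ]
  expect_error(annotate_transcript(t, sp), "sorted")
  sp2 <- np_spans(start = c(0L, 1L), end = c(2L, 3L),
                  head_lemma = c("adam", "adam"))
  expect_error(annotate_transcript(t, sp2), "overlapping")
})

test_that("category counting is additive and empty-safe", {
  t <- make_mini_transcript()
  a <- annotate_transcript(t, mini_spans())
  cc <- count_categories(a)
  expect_identical(unname(cc[["indefinite_dp"]]), 1L)
  expect_identical(unname(cc[["bare_anaphoric"]]), 1L)
  expect_identical(unname(cc[["words"]]), 5L) # punctuation excluded

  empty <- annotate_transcript(t, NULL)
  cc0 <- count_categories(empty)
  expect_true(all(cc0[NP_CATEGORIES] == 0L))
  expect_identical(unname(cc0[["referential_anomalies"]]), 0L)

  # duplicating the narration doubles counts at the set level
  t2 <- make_mini_transcript("P1", "NC", 2L)
  a2 <- annotate_transcript(t2, mini_spans())
  expect_equal(count_categories(a)[NP_CATEGORIES] +
                 count_categories(a2)[NP_CATEGORIES],
               2L * count_categories(a)[NP_CATEGORIES])
})

test_that("macro-type mapping keeps the four testable classes", {
  expect_identical(macro_type("definite_dp"), "definite_dp")
  expect_identical(macro_type("bare_residual"), "bare_residual")
  expect_identical(macro_type(c("bare_anaphoric", "null_subject",
                                "lexical_pronoun", "bare_generic",
                                "bare_specific")),
                   rep("other", 5L))
})

test_that("definiteness aggregation follows the default composition", {
  zero <- setNames(rep(0L, length(NP_CATEGORIES)), NP_CATEGORIES)
  expect_equal(aggregate_definiteness(zero),
               c(all_definite = 0, all_indefinite = 0))

  fx <- load_table1_fixture()
  sp <- np_spans(fx$spans$start, fx$spans$end, fx$spans$head_lemma,
                 fx$spans$is_pronoun, fx$spans$is_null_subject,
                 fx$spans$anaphoric, fx$spans$generic, fx$spans$anomaly)
  cc <- count_categories(annotate_transcript(fx$transcript, sp))
  agg <- aggregate_definiteness(cc)
  expect_equal(agg, c(all_definite = 3, all_indefinite = 2))

  cc["definite_dp"] <- cc["definite_dp"] + 1L
  expect_equal(aggregate_definiteness(cc)[["all_definite"]], 4)

  # composition is configurable
  agg2 <- aggregate_definiteness(cc, indefinite = c("indefinite_dp",
                                                    "bare_indefinite",
                                                    "bare_generic"))
  expect_equal(agg2[["all_indefinite"]], 3)
})

test_that("Cohen's kappa matches its closed form", {
  expect_equal(cohens_kappa(letters[1:5], letters[1:5])$kappa, 1)

  fx <- make_kappa_fixture()
  k <- cohens_kappa(fx$a, fx$b)
  expect_equal(k$observed_agreement, 0.98)
  expect_equal(k$expected_agreement, 0.5)
  expect_equal(k$kappa, 0.96)

  # one rater constant, other balanced over two categories
  a <- rep("x", 100)
  b <- rep(c("x", "y"), 50)
  k2 <- cohens_kappa(a, b)
  expect_equal(k2$expected_agreement, 0.5)
  expect_equal(k2$kappa, (k2$observed_agreement - 0.5) / 0.5)

  expect_error(cohens_kappa(letters[1:3], letters[1:4]), "equal length")
  expect_error(cohens_kappa(character(0), character(0)), "non-empty")
})

test_that("kappa is bounded by 1 and attains it only at full agreement", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    a <- sample(c("p", "q", "r"), n, replace = TRUE)
    b <- sample(c("p", "q", "r"), n, replace = TRUE)
    k <- cohens_kappa(a, b)
    expect_lte(k$kappa, 1)
    if (k$expected_agreement < 1) {
      expect_identical(k$kappa == 1, k$observed_agreement == 1)
    }
  }
})
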