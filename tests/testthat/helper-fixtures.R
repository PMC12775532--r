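# Shared fixtures and independent oracles.

# Independent brute-force Benjamini-Hochberg step-up, straight from the
# definition: q_(i) = min_{j >= i} min(1, p_(j) * n / j).
bh_brute_force <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# A small hand-built narration: "bir adam ... adam tarlada" style sequence
# with one DP introduction followed by a bare re-mention.
make_mini_transcript <- function(participant = "P1", group = "NC",
                                 picture = 1L) {
  tk <- tokens_frame(
    surface = c("bir", "adam", "geldi", ".", "adam", "gitti"),
    is_punct = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    pos = c("det", "noun", "verb", "other", "noun", "verb"),
    determiner = c("none", "indefinite", "none", "none", "none", "none"),
    lemma = c("bir", "adam", "gel", ".", "adam", "git")
  )
  transcript(participant, group, picture, tk)
}

mini_spans <- function() {
  np_spans(start = c(0L, 4L), end = c(2L, 5L),
           head_lemma = c("adam", "adam"))
}

# Table 1 worked-example fixture shipped with the package.
load_table1_fixture <- function() {
  jsonl <- system.file("extdata", "table1_fixture.jsonl", package = "refcoh")
  spans <- system.file("extdata", "table1_fixture_spans.tsv",
                       package = "refcoh")
  tset <- read_transcripts(jsonl)
  tab <- read_annotations(spans)
  list(transcript = tset$transcripts[[1L]], spans = tab)
}

# Reliability fixture: two categories, balanced, 20 symmetric
# disagreements out of 1000.
make_kappa_fixture <- function() {
  a <- rep(c("lexical", "null"), each = 500)
  b <- a
  b[1:10] <- "null"      # 10 disagreements one way
  b[501:510] <- "lexical" # 10 the other way
  list(a = a, b = b)
}

# One-row span helper for classifier tests.
span1 <- function(...) np_spans(...)[1, ]
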