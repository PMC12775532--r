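#' refcoh: referential structure and semantic coherence metrics
#'
#' Quantifies discourse coherence in picture-elicited narrations along three
#' dimensions: the referential structure of noun phrases (NPs), the temporal
#' dynamics of their occurrence over narrative time, and embedding-derived
#' semantic similarity / predictability. A synthetic-corpus generator with
#' the same statistical structure makes every stage testable end to end.
#'
#' @section Main entry points:
#' * [read_transcripts()] / [write_transcripts()] — JSONL corpus I/O
#' * [annotate_transcript()], [classify_np()] — the NP taxonomy
#' * [exponentiality_test()] — Monte-Carlo KS test of memoryless arrivals
#' * [consecutive_cosine_similarity()], [pseudo_perplexity()] — semantics
#' * [poisson_glm_offset()], [gee_gaussian_exchangeable()] — inference
#' * [simulate_corpus()] — synthetic corpora
#' * [run_pipeline()], [report_run()] — end-to-end orchestration
#'
#' @keywords internal
"_PACKAGE"

# The four participant groups: neurotypical controls (reference), first
# episode of psychosis, ultra-high risk, family history of psychosis.
GROUP_LABELS <- c("NC", "FEP", "UHR", "FHP")

TOKEN_COLUMNS <- c("index", "surface", "is_punct", "is_stopword", "pos",
                   "determiner", "case", "plural", "lemma",
                   "agreement_subject")

#' Build a token table for one narration
#'
#' Tokens carry the morphosyntactic features the NP classifier consumes:
#' determiner type (`none`/`indefinite`/`demonstrative`), case marking
#' (`none`/`accusative`/`other`), plurality, lemma and whether the token is
#' a verb bearing subject-agreement morphology (used to anchor null
#' subjects in a pro-drop language).
#'
#' @param surface character vector of token surfaces (non-empty).
#' @param is_punct,is_stopword logical vectors (recycled).
#' @param pos coarse part-of-speech: `noun`, `pronoun`, `verb`, `det`, `other`.
#' @param determiner,case,plural,lemma,agreement_subject feature columns;
#'   `lemma` defaults to the lower-cased surface.
#' @return A `data.frame` with 0-based `index` and one row per token.
#' @export
tokens_frame <- function(surface,
                         is_punct = FALSE,
                         is_stopword = FALSE,
                         pos = "other",
                         determiner = "none",
                         case = "none",
                         plural = FALSE,
                         lemma = NULL,
                         agreement_subject = FALSE) {
  n <- length(surface)
  stopifnot(n == 0L || all(nzchar(surface)))
  if (is.null(lemma)) lemma <- tolower(surface)
  out <- data.frame(
    index = if (n) 0:(n - 1L) else integer(0),
    surface = as.character(surface),
    is_punct = rep_len(as.logical(is_punct), n),
    is_stopword = rep_len(as.logical(is_stopword), n),
    pos = rep_len(as.character(pos), n),
    determiner = rep_len(as.character(determiner), n),
    case = rep_len(as.character(case), n),
    plural = rep_len(as.logical(plural), n),
    lemma = rep_len(as.character(lemma), n),
    agreement_subject = rep_len(as.logical(agreement_subject), n),
    stringsAsFactors = FALSE
  )
  out
}

#' Construct a transcript (one narration)
#'
#' @param participant_id character scalar.
#' @param group one of `NC`, `FEP`, `UHR`, `FHP`.
#' @param picture_id integer picture identifier.
#' @param tokens a token table as built by [tokens_frame()].
#' @param word_count optional; recomputed as the number of non-punctuation
#'   tokens and checked against this value when supplied.
#' @return An object of class `transcript`.
#' @export
transcript <- function(participant_id, group, picture_id, tokens,
                       word_count = NULL) {
  wc <- sum(!tokens$is_punct)
  if (!is.null(word_count) && word_count != wc) {
    stop("stored word_count (", word_count,
         ") disagrees with token-derived count (", wc, ")")
  }
  t <- structure(
    list(participant_id = as.character(participant_id),
         group = as.character(group),
         picture_id = as.integer(picture_id),
         tokens = tokens,
         word_count = as.integer(wc)),
    class = "transcript"
  )
  v <- validate_transcript(t)
  if (length(v)) stop("invalid transcript: ", paste(v, collapse = "; "))
  t
}

#' Validate a transcript against the data-model invariants
#'
#' Violations are returned as data rather than raised, so that corpora can
#' be audited record by record.
#'
#' @param t a `transcript`.
#' @return Character vector of violations; empty when all invariants hold.
#' @export
validate_transcript <- function(t) {
  v <- character(0)
  tk <- t$tokens
  if (!all(TOKEN_COLUMNS %in% names(tk))) {
    return(paste("missing token columns:",
                 paste(setdiff(TOKEN_COLUMNS, names(tk)), collapse = ", ")))
  }
  if (nrow(tk) && !identical(as.integer(tk$index), 0:(nrow(tk) - 1L)))
    v <- c(v, "token indices not consecutive from 0")
  if (any(!nzchar(tk$surface)))
    v <- c(v, "empty token surface")
  if (!t$group %in% GROUP_LABELS)
    v <- c(v, paste0("unknown group label '", t$group, "'"))
  wc <- sum(!tk$is_punct)
  if (!identical(as.integer(t$word_count), as.integer(wc)))
    v <- c(v, sprintf("word_count %d does not match %d non-punctuation tokens",
                      t$word_count, wc))
  v
}

#' Construct a transcript set
#'
#' @param transcripts list of `transcript` objects.
#' @param provenance `"synthetic"` or `"external"`.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, provenance = "external") {
  stopifnot(provenance %in% c("synthetic", "external"))
  keys <- vapply(transcripts, function(t)
    paste(t$participant_id, t$picture_id, sep = "\r"), "")
  if (anyDuplicated(keys))
    stop("duplicate (participant_id, picture_id) pairs in transcript set")
  structure(list(transcripts = transcripts, provenance = provenance),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("<transcript_set> ", length(x$transcripts), " narrations (",
      x$provenance, ")\n", sep = "")
  invisible(x)
}

#' @export
length.transcript_set <- function(x) length(x$transcripts)

#' Read a JSONL corpus
#'
#' One JSON object per line, each a narration with `participant_id`,
#' `group`, `picture_id` and a `tokens` array whose entries carry `surface`,
#' `is_punct`, `pos` and a `features` object (`determiner`, `case`,
#' `plural`, `lemma`, `agreement_subject`). `word_count` is always
#' recomputed from the tokens; if present in the record it must agree.
#'
#' @param path path to a JSONL file.
#' @param provenance provenance tag for the resulting set.
#' @return A [transcript_set()].
#' @export
read_transcripts <- function(path, provenance = "external") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  ts <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e)
                      stop("line ", i, ": malformed JSON (", conditionMessage(e), ")"))
    ts[[i]] <- tryCatch(transcript_from_record(rec),
                        error = function(e)
                          stop("line ", i, ": ", conditionMessage(e)))
  }
  transcript_set(ts, provenance = provenance)
}

transcript_from_record <- function(rec) {
  for (f in c("participant_id", "group", "picture_id", "tokens")) {
    if (is.null(rec[[f]])) stop("record missing field '", f, "'")
  }
  tok <- rec$tokens
  if (is.data.frame(tok)) {
    feats <- tok$features
    if (is.null(feats)) feats <- data.frame(row.names = seq_len(nrow(tok)))
    get_feat <- function(name, default) {
      x <- feats[[name]]
      if (is.null(x)) rep(default, nrow(tok)) else ifelse(is.na(x), default, x)
    }
    get_col <- function(name, default) {
      x <- tok[[name]]
      if (is.null(x)) rep(default, nrow(tok)) else ifelse(is.na(x), default, x)
    }
    tk <- tokens_frame(
      surface = tok$surface,
      is_punct = get_col("is_punct", FALSE),
      is_stopword = get_col("is_stopword", FALSE),
      pos = get_col("pos", "other"),
      determiner = get_feat("determiner", "none"),
      case = get_feat("case", "none"),
      plural = get_feat("plural", FALSE),
      lemma = {
        lm <- feats[["lemma"]]
        if (is.null(lm)) tolower(tok$surface) else ifelse(is.na(lm) | !nzchar(lm),
                                                          tolower(tok$surface), lm)
      },
      agreement_subject = get_feat("agreement_subject", FALSE)
    )
  } else if (length(tok) == 0) {
    tk <- tokens_frame(character(0))
  } else {
    stop("'tokens' is not an array of token objects")
  }
  transcript(rec$participant_id, rec$group, rec$picture_id, tk,
             word_count = rec$word_count)
}

#' Write a transcript set as JSONL
#'
#' Inverse of [read_transcripts()]: `read_transcripts(write_transcripts(x))`
#' reproduces every field.
#'
#' @param x a `transcript_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(x, path) {
  stopifnot(inherits(x, "transcript_set"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (t in x$transcripts) {
    tk <- t$tokens
    rec <- list(
      participant_id = t$participant_id,
      group = t$group,
      picture_id = t$picture_id,
      word_count = t$word_count,
      tokens = data.frame(
        surface = tk$surface,
        is_punct = tk$is_punct,
        is_stopword = tk$is_stopword,
        pos = tk$pos,
        features = I(data.frame(
          determiner = tk$determiner, case = tk$case, plural = tk$plural,
          lemma = tk$lemma, agreement_subject = tk$agreement_subject,
          stringsAsFactors = FALSE)),
        stringsAsFactors = FALSE
      )
    )
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con,
               useBytes = TRUE)
  }
  invisible(path)
}

#' Write a results table as delimited text
#'
#' CSV by default, TSV when the path ends in `.tsv`. The companion
#' [read_table_file()] reads it back losslessly for the supported column
#' types (character, integer, double, logical).
#'
#' @param rows a data.frame sharing one header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(rows, path, sep = sep, row.names = FALSE,
                     quote = TRUE, qmethod = "double")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
}
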