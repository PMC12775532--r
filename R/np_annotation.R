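#' NP category and macro-type enumerations
#'
#' `NP_CATEGORIES` enumerates the nine mutually exclusive referential
#' classes assigned by [classify_np()]; `MACRO_TYPES` the four classes
#' frequent enough for arrival-dynamics testing.
#'
#' @format Character vectors.
#' @export
NP_CATEGORIES <- c("indefinite_dp", "definite_dp", "bare_anaphoric",
                   "bare_specific", "bare_indefinite", "bare_generic",
                   "bare_residual", "null_subject", "lexical_pronoun")

#' @rdname NP_CATEGORIES
#' @export
MACRO_TYPES <- c("definite_dp", "indefinite_dp", "bare_indefinite",
                 "bare_residual")

#' Build an NP span table
#'
#' A span is a half-open token range `[start, end)` within one narration.
#' Null subjects — grammatical subjects expressed only through verb
#' agreement morphology, as Turkish pro-drop allows — have an empty range
#' (`start == end`) anchored at the verb's token index. `anaphoric` and
#' `generic` are manual annotator judgements (`NA` = not judged); `anomaly`
#' flags a referential anomaly (a referent a listener could not track) and
#' is always annotator-supplied, never detected.
#'
#' @param start,end 0-based token range, end exclusive.
#' @param head_lemma lemma of the NP head (empty allowed for null subjects).
#' @param is_pronoun,is_null_subject logical.
#' @param anaphoric,generic optional logical manual flags (`NA` = unset).
#' @param anomaly logical referential-anomaly flag.
#' @return A `data.frame` with one row per span.
#' @export
np_spans <- function(start, end, head_lemma = "",
                     is_pronoun = FALSE, is_null_subject = FALSE,
                     anaphoric = NA, generic = NA, anomaly = FALSE) {
  n <- length(start)
  data.frame(
    start = as.integer(start),
    end = as.integer(end),
    head_lemma = rep_len(as.character(head_lemma), n),
    is_pronoun = rep_len(as.logical(is_pronoun), n),
    is_null_subject = rep_len(as.logical(is_null_subject), n),
    anaphoric = rep_len(as.logical(anaphoric), n),
    generic = rep_len(as.logical(generic), n),
    anomaly = rep_len(as.logical(anomaly), n),
    stringsAsFactors = FALSE
  )
}

span_head_index <- function(span) {
  if (isTRUE(span$is_null_subject)) span$start else span$end - 1L
}

#' Classify one NP span into the referential taxonomy
#'
#' The decision cascade mirrors the three annotation steps: (1) null
#' subjects and lexical pronouns are split off first; (2) lexical NPs with
#' a determiner become determiner phrases (DPs), subclassified (3) as
#' indefinite (indefiniteness markers such as "bir") or definite
#' (demonstratives such as "bu"). Bare NPs (no determiner) are then checked
#' in order: anaphoric (previously mentioned head lemma, or an explicit
#' manual judgement, which overrides the lemma match), specific
#' (accusative or other specificity-inducing case marker), indefinite
#' (plural morphology: quantification over a set), generic (manual flag),
#' and finally the total fallback `bare_residual`.
#'
#' @param span a one-row span (see [np_spans()]).
#' @param tokens the narration's token table.
#' @param registry character vector of head lemmas already mentioned in
#'   this narration, up to the span's start.
#' @return A category label, one of
#'   `indefinite_dp`, `definite_dp`, `bare_anaphoric`, `bare_specific`,
#'   `bare_indefinite`, `bare_generic`, `bare_residual`, `null_subject`,
#'   `lexical_pronoun`.
#' @export
classify_np <- function(span, tokens, registry = character(0)) {
  if (is.data.frame(span)) {
    stopifnot(nrow(span) == 1L)
    span <- as.list(span)
  }
  if (isTRUE(span$is_null_subject)) {
    if (span$start != span$end)
      stop("null-subject span must have an empty token range")
    hi <- span$start
    if (hi < 0L || hi >= nrow(tokens))
      stop("span head index ", hi, " outside narration (", nrow(tokens),
           " tokens)")
    if (!identical(tokens$determiner[hi + 1L], "none"))
      stop("contradictory features: null subject anchored at a token with a determiner")
    return("null_subject")
  }
  if (span$start >= span$end)
    stop("lexical NP span must have start < end")
  hi <- span$end - 1L
  if (hi < 0L || hi >= nrow(tokens))
    stop("span head index ", hi, " outside narration (", nrow(tokens),
         " tokens)")
  head_tok <- tokens[hi + 1L, ]
  if (isTRUE(span$is_pronoun)) return("lexical_pronoun")

  det <- head_tok$determiner
  if (identical(det, "indefinite")) return("indefinite_dp")
  if (identical(det, "demonstrative")) return("definite_dp")

  # bare NP cascade: anaphoric > case-marked > plural > generic > residual
  anaphoric <- if (!is.na(span$anaphoric)) isTRUE(span$anaphoric)
               else nzchar(span$head_lemma) && span$head_lemma %in% registry
  if (anaphoric) return("bare_anaphoric")
  if (!identical(head_tok$case, "none")) return("bare_specific")
  if (isTRUE(head_tok$plural)) return("bare_indefinite")
  if (isTRUE(span$generic)) return("bare_generic")
  "bare_residual"
}

#' Annotate a narration: classify all NP spans
#'
#' Classifies spans in textual order, building the discourse registry
#' incrementally: after a lexical NP (not a pronoun or null subject) is
#' classified, its head lemma becomes available for anaphora in later
#' spans. The registry is local to the narration — it never leaks across
#' pictures or participants.
#'
#' @param t a [transcript()].
#' @param spans a span table (see [np_spans()]), sorted by `start`.
#' @return An object of class `annotation_set` carrying the spans with
#'   their assigned `category`, the referential-anomaly count, and the
#'   narration's identifiers and word count.
#' @export
annotate_transcript <- function(t, spans) {
  stopifnot(inherits(t, "transcript"))
  if (is.null(spans) || nrow(spans) == 0L) {
    spans <- np_spans(integer(0), integer(0))
    spans$category <- character(0)
    return(new_annotation_set(t, spans))
  }
  if (is.unsorted(spans$start))
    stop("spans must be sorted by start index")
  lex <- !spans$is_null_subject
  if (any(lex)) {
    ls <- spans[lex, , drop = FALSE]
    if (nrow(ls) > 1L && any(ls$start[-1L] < ls$end[-nrow(ls)]))
      stop("overlapping lexical spans")
  }
  registry <- character(0)
  cats <- character(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    sp <- spans[i, ]
    cats[i] <- classify_np(sp, t$tokens, registry)
    if (!cats[i] %in% c("null_subject", "lexical_pronoun") &&
        nzchar(sp$head_lemma)) {
      registry <- c(registry, sp$head_lemma)
    }
  }
  spans$category <- cats
  new_annotation_set(t, spans)
}

new_annotation_set <- function(t, spans) {
  structure(
    list(participant_id = t$participant_id,
         group = t$group,
         picture_id = t$picture_id,
         word_count = t$word_count,
         n_tokens = nrow(t$tokens),
         spans = spans,
         anomaly_count = sum(spans$anomaly)),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("<annotation_set> ", x$participant_id, " picture ", x$picture_id,
      " (", x$group, "): ", nrow(x$spans), " NPs, ",
      x$anomaly_count, " anomalies\n", sep = "")
  invisible(x)
}

#' Per-category NP counts for one annotated narration
#'
#' @param a an `annotation_set`.
#' @return Named integer vector over the nine categories, plus
#'   `referential_anomalies` and `words` (the exposure for rate models).
#' @export
count_categories <- function(a) {
  stopifnot(inherits(a, "annotation_set"))
  counts <- table(factor(a$spans$category, levels = NP_CATEGORIES))
  out <- stats::setNames(as.integer(counts), NP_CATEGORIES)
  c(out, referential_anomalies = a$anomaly_count, words = a$word_count)
}

#' Map an NP category to its arrival-dynamics macro-type
#'
#' Only four NP classes have enough occurrences for their arrival process
#' over narrative time to be testable: definite DPs, indefinite DPs, bare
#' indefinite NPs and bare-residual NPs. These map to themselves; all other
#' categories map to `"other"`.
#'
#' @param category character vector of NP categories.
#' @return Character vector of macro labels.
#' @export
macro_type <- function(category) {
  ifelse(category %in% MACRO_TYPES, category, "other")
}

#' Aggregate counts into all-definite and all-indefinite totals
#'
#' Default composition: definite = definite DPs + bare anaphoric + bare
#' specific (all pick out an identifiable referent); indefinite =
#' indefinite DPs + bare indefinite. Null subjects and lexical pronouns are
#' modelled separately and excluded by default, as is the rare generic
#' class; both compositions are configurable.
#'
#' @param counts named vector as from [count_categories()].
#' @param definite,indefinite categories composing each total.
#' @return Named numeric vector `c(all_definite =, all_indefinite =)`.
#' @export
aggregate_definiteness <- function(counts,
    definite = c("definite_dp", "bare_anaphoric", "bare_specific"),
    indefinite = c("indefinite_dp", "bare_indefinite")) {
  stopifnot(all(c(definite, indefinite) %in% NP_CATEGORIES))
  c(all_definite = sum(counts[definite]),
    all_indefinite = sum(counts[indefinite]))
}

#' Cohen's kappa for two category sequences
#'
#' Chance-corrected inter-rater agreement: `kappa = (po - pe) / (1 - pe)`
#' with observed agreement `po` and chance agreement `pe` from the raters'
#' marginal category frequencies.
#'
#' @param a,b equal-length category vectors (one element per annotated NP).
#' @return An object of class `kappa_result` with `observed_agreement`,
#'   `expected_agreement` and `kappa`.
#' @export
cohens_kappa <- function(a, b) {
  if (length(a) != length(b)) stop("sequences must have equal length")
  if (length(a) == 0L) stop("sequences must be non-empty")
  n <- length(a)
  po <- mean(a == b)
  cats <- union(unique(a), unique(b))
  ma <- table(factor(a, levels = cats)) / n
  mb <- table(factor(b, levels = cats)) / n
  pe <- sum(as.numeric(ma) * as.numeric(mb))
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 1
  structure(list(observed_agreement = po, expected_agreement = pe,
                 kappa = kappa, n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.4f  (po = %.4f, pe = %.4f, n = %d)\n",
              x$kappa, x$observed_agreement, x$expected_agreement, x$n))
  invisible(x)
}

#' Read / write annotation span tables (TSV)
#'
#' Interchange format: `participant_id`, `picture_id`, `start`, `end`,
#' `category`, `anomaly` (0/1), plus the span feature columns needed to
#' re-run classification.
#'
#' @param annotations list of `annotation_set` objects.
#' @param path output path (`.tsv`).
#' @return `path` invisibly; `read_annotations()` returns the table.
#' @export
write_annotations <- function(annotations, path) {
  rows <- do.call(rbind, lapply(annotations, function(a) {
    if (nrow(a$spans) == 0L) return(NULL)
    cbind(data.frame(participant_id = a$participant_id,
                     group = a$group,
                     picture_id = a$picture_id,
                     stringsAsFactors = FALSE),
          a$spans)
  }))
  if (is.null(rows)) {
    rows <- cbind(data.frame(participant_id = character(0),
                             group = character(0),
                             picture_id = integer(0)),
                  np_spans(integer(0), integer(0)),
                  data.frame(category = character(0)))
  }
  rows$anomaly <- as.integer(rows$anomaly)
  write_table(rows, path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tab <- read_table_file(path)
  tab$anomaly <- as.logical(tab$anomaly)
  tab
}
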