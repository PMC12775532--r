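#' Preprocess a transcript for the similarity metric
#'
#' Removes punctuation tokens and stop words, preserving order. This
#' preprocessing applies only to the consecutive-cosine similarity path;
#' the referential (NP-based) and perplexity analyses always use the full
#' token stream. A small default Turkish stop-word list ships with the
#' package (`stopword_list()`); any list can be supplied.
#'
#' @param t a [transcript()].
#' @param stopwords character vector of stop words (matched on the
#'   lower-cased surface).
#' @return Character vector of surviving token surfaces, in order.
#' @export
preprocess_for_similarity <- function(t, stopwords = stopword_list()) {
  stopifnot(inherits(t, "transcript"))
  tk <- t$tokens
  keep <- !tk$is_punct & !(tolower(tk$surface) %in% tolower(stopwords))
  tk$surface[keep]
}

#' Default Turkish stop-word list
#'
#' A small function-word list shipped as a plain-text fixture; the metric
#' accepts any list, this is only a convenience default.
#'
#' @return Character vector of stop words.
#' @export
stopword_list <- function() {
  path <- system.file("extdata", "stopwords_tr.txt", package = "refcoh")
  if (!nzchar(path)) stop("stop-word fixture not found")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

row_norms <- function(m) sqrt(rowSums(m * m))

#' Consecutive-cosine semantic similarity
#'
#' The mean cosine similarity between every pair of consecutive token
#' embeddings: `(1/(n-1)) * sum_i cos(e_i, e_{i+1})`. This is the
#' word-to-word coherence metric: values near 1 indicate adjacent words
#' occupying a narrow ("shrunk") semantic neighbourhood.
#'
#' @param E numeric matrix, one embedding per row.
#' @return A number in `[-1, 1]`, or `NA_real_` when fewer than two
#'   embeddings are supplied (the quantity is undefined, not an error).
#' @export
consecutive_cosine_similarity <- function(E) {
  E <- as.matrix(E)
  n <- nrow(E)
  if (n < 2L) return(NA_real_)
  nrm <- row_norms(E)
  if (any(nrm == 0)) stop("zero-norm embedding vector")
  U <- E / nrm
  mean(rowSums(U[-n, , drop = FALSE] * U[-1L, , drop = FALSE]))
}

#' Pseudo-perplexity of a token-probability sequence
#'
#' `PPPL = exp((1/n) * sum_i -log P(w_i | context))` with natural
#' logarithms: the exponentiated mean token surprisal, equivalently the
#' inverse geometric mean of the token probabilities. Lower values mean
#' more predictable speech.
#'
#' @param p numeric vector of per-token probabilities in `(0, 1]`.
#' @return A number `>= 1`.
#' @export
pseudo_perplexity <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("probability sequence must be non-empty")
  if (any(p <= 0)) stop("probabilities must be positive")
  if (any(p > 1)) stop("probabilities must be at most 1")
  exp(mean(-log(p)))
}

#' Image-to-text (bimodal) similarity
#'
#' Mean cosine between one image embedding and the embeddings of the text
#' units describing it (sentences by default in the pipeline); the
#' per-participant aggregate of this quantity is the bimodal alignment
#' score.
#'
#' @param image_vec numeric image embedding.
#' @param text_vecs numeric matrix (rows = text units) or a list of
#'   vectors, same dimension as `image_vec`.
#' @return Mean cosine similarity.
#' @export
image_text_similarity <- function(image_vec, text_vecs) {
  if (is.list(text_vecs)) text_vecs <- do.call(rbind, text_vecs)
  text_vecs <- as.matrix(text_vecs)
  if (nrow(text_vecs) == 0L) stop("at least one text vector required")
  if (ncol(text_vecs) != length(image_vec))
    stop("dimension mismatch: image ", length(image_vec), ", text ",
         ncol(text_vecs))
  inorm <- sqrt(sum(image_vec^2))
  tnorm <- row_norms(text_vecs)
  if (inorm == 0 || any(tnorm == 0)) stop("zero-norm embedding vector")
  mean((text_vecs %*% image_vec) / (tnorm * inorm))
}

# Deterministic 32-bit polynomial hash of a string, mixed with a salt.
# Plain arithmetic mod 2^31 - 1 so the result is identical across
# platforms and R sessions.
string_hash <- function(s, salt = 0L) {
  m <- 2147483647
  h <- (salt %% m + 17) %% m
  for (code in utf8ToInt(enc2utf8(s))) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

#' Deterministic stub embedding/probability provider
#'
#' A test double for the pretrained models behind the provider contract
#' (a masked language model for token embeddings/probabilities, a bimodal
#' image-text model for image vectors). Embeddings are unit vectors derived
#' from a hash of the token surface and the seed, so the same input always
#' yields byte-identical output, across runs and platforms; different
#' seeds yield different geometry. It carries no linguistic knowledge and
#' is meant for pipeline exercise and unit tests only.
#'
#' @param seed integer; part of the provider's identity.
#' @param dim embedding dimension.
#' @return An object of class `embedding_provider` with functions
#'   `embed_tokens(surfaces)` (rows = unit-norm embeddings),
#'   `token_probabilities(surfaces)` (values in `(0, 1]`), and
#'   `embed_image(image_id)`.
#' @export
stub_provider <- function(seed = 1L, dim = 32L) {
  stopifnot(dim >= 2L)
  seed <- as.integer(seed)
  unit_vec <- function(h) {
    with_preserved_rng({
      set.seed(h)
      v <- stats::rnorm(dim)
      v / sqrt(sum(v^2))
    })
  }
  structure(list(
    model_id = sprintf("stub-%d-d%d", seed, dim),
    dim = as.integer(dim),
    embed_tokens = function(surfaces) {
      out <- vapply(as.character(surfaces),
                    function(s) unit_vec(string_hash(s, salt = seed)),
                    numeric(dim), USE.NAMES = FALSE)
      t(matrix(out, nrow = dim))
    },
    token_probabilities = function(surfaces) {
      vapply(as.character(surfaces), function(s) {
        h <- string_hash(s, salt = seed + 7919L)
        with_preserved_rng({
          set.seed(h)
          stats::runif(1, min = 0.01, max = 1)
        })
      }, numeric(1), USE.NAMES = FALSE)
    },
    embed_image = function(image_id) {
      unit_vec(string_hash(paste0("image:", image_id), salt = seed + 104729L))
    }
  ), class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> ", x$model_id, "\n", sep = "")
  invisible(x)
}

#' Transcript-level semantic metrics via a provider
#'
#' Convenience wrapper applying the full metric path to one narration:
#' similarity on the preprocessed token stream (punctuation and stop words
#' removed), pseudo-perplexity on the full stream, and image-to-text
#' similarity against the narration's picture embedding.
#'
#' @param t a [transcript()].
#' @param provider an `embedding_provider` (see [stub_provider()]).
#' @param stopwords stop-word list for the similarity path.
#' @param with_stopwords keep stop words and punctuation in the similarity
#'   path (the robustness variant).
#' @return Named list: `similarity`, `pppl`, `img2txt`, `n_tokens_used`.
#' @export
semantic_profile <- function(t, provider, stopwords = stopword_list(),
                             with_stopwords = FALSE) {
  stopifnot(inherits(t, "transcript"), inherits(provider, "embedding_provider"))
  surf_sim <- if (with_stopwords) t$tokens$surface[!t$tokens$is_punct]
              else preprocess_for_similarity(t, stopwords)
  sim <- if (length(surf_sim) >= 2L)
    consecutive_cosine_similarity(provider$embed_tokens(surf_sim))
  else NA_real_
  surf_all <- t$tokens$surface[!t$tokens$is_punct]
  pppl <- if (length(surf_all))
    pseudo_perplexity(provider$token_probabilities(surf_all))
  else NA_real_
  img <- if (length(surf_all)) {
    image_text_similarity(provider$embed_image(t$picture_id),
                          provider$embed_tokens(surf_all))
  } else NA_real_
  list(similarity = sim, pppl = pppl, img2txt = img,
       n_tokens_used = length(surf_sim))
}
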