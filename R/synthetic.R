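# Fast data.frame constructor for hot loops (skips data.frame()'s checks).
fast_df <- function(cols) {
  n <- length(cols[[1L]])
  structure(cols, class = "data.frame", row.names = c(NA_integer_, -n))
}

#' Configuration for the synthetic corpus generator
#'
#' Defaults encode the study conditions the analysis assumes: four groups
#' with the study's sizes (NC 34, FEP 53, UHR 64, FHP 39), four one-minute
#' narrations per participant, negative-binomial word counts (mean 250,
#' sd about 90), per-word NP base rates set to the exponentiated
#' neurotypical log-rate intercepts of the rate models, group rate
#' multipliers reproducing the reported contrasts (e.g. definite DPs in
#' FEP at ~0.7 of the control rate, raised referential-anomaly rates in
#' all clinical groups), and renewal families for the arrival processes:
#' gamma(shape 3) gaps for definite/indefinite DPs (narratives introduce
#' and then pick up referents, so these arrivals are more regular than
#' memoryless) except for FEP indefinite DPs, which revert to exponential
#' — the memoryless pattern the analysis is designed to detect.
#'
#' @param groups named integer vector of participants per group.
#' @param pictures narrations per participant.
#' @param words_mean,words_size,words_min negative-binomial word-count
#'   parameters (mean, dispersion size) and a floor.
#' @param base_rates named per-word occurrence rates per NP category
#'   (reference group).
#' @param rate_multipliers named list (by group) of named multipliers on
#'   `base_rates`.
#' @param renewal_shape named gamma shape per category (1 = exponential;
#'   categories not named default to 1). Shapes > 1 give regular
#'   (clustered-avoiding) arrivals, shapes < 1 bursty ones.
#' @param shape_overrides named list (by group) of named shape overrides.
#' @param anomaly_rate per-word referential-anomaly rate (reference group).
#' @param anomaly_multipliers named per-group multipliers.
#' @param age_mean,age_sd,edu_mean,edu_sd per-group covariate parameters.
#' @param embedding list: `dim` and named per-group consecutive-cosine
#'   mixing `rho`.
#' @param nll list: named per-group `mean` negative log-probability and
#'   common `sd` (drives pseudo-perplexity).
#' @param outcome list: clustered-outcome model (`beta`, `rho`, `sigma`).
#' @param seed default seed for [simulate_corpus()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    groups = c(NC = 34L, FEP = 53L, UHR = 64L, FHP = 39L),
    pictures = 4L,
    words_mean = 250, words_size = 9, words_min = 40L,
    base_rates = c(indefinite_dp = exp(-2.57),
                   definite_dp = exp(-3.02),
                   bare_anaphoric = exp(-3.55),
                   bare_specific = 0,
                   bare_indefinite = exp(-3.14),
                   bare_generic = exp(-6.24),
                   bare_residual = exp(-3.43),
                   null_subject = exp(-2.64),
                   lexical_pronoun = exp(-3.67)),
    rate_multipliers = list(
      FEP = c(definite_dp = exp(-0.37), bare_anaphoric = exp(-0.22),
              bare_residual = exp(0.30), null_subject = exp(-0.10)),
      UHR = c(indefinite_dp = exp(-0.10), lexical_pronoun = exp(-0.26)),
      FHP = c(definite_dp = exp(-0.10))),
    renewal_shape = c(indefinite_dp = 3, definite_dp = 3),
    shape_overrides = list(FEP = c(indefinite_dp = 1)),
    anomaly_rate = exp(-5.47),
    anomaly_multipliers = c(FEP = exp(1.26), UHR = exp(0.87),
                            FHP = exp(0.63)),
    age_mean = c(NC = 22.3, FEP = 20.9, UHR = 20.2, FHP = 22.4),
    age_sd = 4.2,
    edu_mean = c(NC = 14.4, FEP = 11.3, UHR = 11.6, FHP = 12.6),
    edu_sd = 2.5,
    embedding = list(dim = 32L,
                     rho = c(NC = 0.45, FEP = 0.55, UHR = 0.53, FHP = 0.47)),
    nll = list(mean = c(NC = 2.3, FEP = 2.3, UHR = 2.3, FHP = 2.3),
               sd = 0.8),
    outcome = list(beta = 0.09, rho = 0.4, sigma = 1),
    seed = 1L) {
  stopifnot(all(groups >= 1L), pictures >= 1L,
            all(base_rates >= 0), all(names(base_rates) %in% NP_CATEGORIES),
            all(renewal_shape >= 1 | renewal_shape > 0),
            anomaly_rate >= 0)
  cfg <- list(groups = groups, pictures = as.integer(pictures),
              words_mean = words_mean, words_size = words_size,
              words_min = as.integer(words_min),
              base_rates = base_rates,
              rate_multipliers = rate_multipliers,
              renewal_shape = renewal_shape,
              shape_overrides = shape_overrides,
              anomaly_rate = anomaly_rate,
              anomaly_multipliers = anomaly_multipliers,
              age_mean = age_mean, age_sd = age_sd,
              edu_mean = edu_mean, edu_sd = edu_sd,
              embedding = embedding, nll = nll, outcome = outcome,
              seed = as.integer(seed))
  structure(cfg, class = "generator_config")
}

group_rate <- function(cfg, group, category) {
  r <- cfg$base_rates[[category]]
  m <- cfg$rate_multipliers[[group]]
  if (!is.null(m) && category %in% names(m)) r <- r * m[[category]]
  r
}

group_shape <- function(cfg, group, category) {
  k <- if (category %in% names(cfg$renewal_shape))
    cfg$renewal_shape[[category]] else 1
  ov <- cfg$shape_overrides[[group]]
  if (!is.null(ov) && category %in% names(ov)) k <- ov[[category]]
  k
}

# Renewal-process arrival positions on 0..(n-1): gamma(shape k) gaps with
# mean 1/rate, cumulative sums floored to integer token indices. Collisions
# (two arrivals rounding to an occupied slot) are re-drawn by advancing to
# the next free slot, so counts are preserved up to truncation at n.
renewal_positions <- function(n, rate, shape, occupied) {
  if (rate <= 0) return(list(pos = integer(0), occupied = occupied))
  cum <- numeric(0)
  last <- 0
  while (last < n) {
    m <- max(8L, ceiling((n - last) * rate + 4 * sqrt(n * rate) + 4))
    g <- stats::rgamma(m, shape = shape, rate = shape * rate)
    cum <- c(cum, last + cumsum(g))
    last <- cum[length(cum)]
  }
  raw <- cum[cum < n]
  pos <- integer(0)
  for (x in floor(raw)) {
    while (x < n && occupied[x + 1L]) x <- x + 1L
    if (x < n) {
      occupied[x + 1L] <- TRUE
      pos <- c(pos, x)
    }
  }
  list(pos = as.integer(pos), occupied = occupied)
}

simulate_narration <- function(cfg, participant_id, group, picture_id) {
  n <- max(cfg$words_min,
           stats::rnbinom(1, size = cfg$words_size, mu = cfg$words_mean))

  cats <- names(cfg$base_rates)
  occupied <- logical(n)
  pos_by_cat <- vector("list", length(cats))
  names(pos_by_cat) <- cats
  for (cat in cats) {
    r <- group_rate(cfg, group, cat)
    res <- renewal_positions(n, r, group_shape(cfg, group, cat), occupied)
    occupied <- res$occupied
    pos_by_cat[[cat]] <- res$pos
  }

  surface <- paste0("w", seq_len(n))
  pos_tag <- rep("other", n)
  determiner <- rep("none", n)
  case <- rep("none", n)
  plural <- rep(FALSE, n)
  lemma <- surface
  agreement <- rep(FALSE, n)

  all_pos <- unlist(pos_by_cat, use.names = FALSE)
  all_cat <- rep(cats, lengths(pos_by_cat))
  o <- order(all_pos)
  all_pos <- all_pos[o]
  all_cat <- all_cat[o]
  n_spans <- length(all_pos)

  head_lemma <- character(n_spans)
  anaphoric <- rep(NA, n_spans)
  generic <- rep(NA, n_spans)
  is_pron <- rep(FALSE, n_spans)
  is_null <- rep(FALSE, n_spans)
  lex_seen <- 0L
  lex_lemmas <- character(n_spans)
  for (i in seq_len(n_spans)) {
    cat <- all_cat[i]
    j <- all_pos[i] + 1L
    fresh <- paste0("lm", participant_id, "p", picture_id, "i", i)
    if (cat == "null_subject") {
      is_null[i] <- TRUE
      pos_tag[j] <- "verb"
      agreement[j] <- TRUE
      head_lemma[i] <- ""
    } else if (cat == "lexical_pronoun") {
      is_pron[i] <- TRUE
      pos_tag[j] <- "pronoun"
      head_lemma[i] <- "pro"
    } else {
      pos_tag[j] <- "noun"
      lm <- fresh
      if (cat == "bare_anaphoric") {
        if (lex_seen > 0L) {
          lm <- lex_lemmas[sample.int(lex_seen, 1L)]
        } else {
          anaphoric[i] <- TRUE # first mention: manual annotator judgement
        }
      }
      if (cat == "indefinite_dp") determiner[j] <- "indefinite"
      if (cat == "definite_dp") determiner[j] <- "demonstrative"
      if (cat == "bare_specific") case[j] <- "accusative"
      if (cat == "bare_indefinite") plural[j] <- TRUE
      if (cat == "bare_generic") generic[i] <- TRUE
      head_lemma[i] <- lm
      lemma[j] <- lm
      lex_seen <- lex_seen + 1L
      lex_lemmas[lex_seen] <- lm
    }
  }

  anomaly <- rep(FALSE, n_spans)
  a_rate <- cfg$anomaly_rate
  if (group %in% names(cfg$anomaly_multipliers))
    a_rate <- a_rate * cfg$anomaly_multipliers[[group]]
  if (n_spans > 0L && a_rate > 0) {
    n_anom <- min(stats::rpois(1, a_rate * n), n_spans)
    if (n_anom > 0L) anomaly[sample.int(n_spans, n_anom)] <- TRUE
  }

  tokens <- fast_df(list(
    index = 0:(n - 1L), surface = surface,
    is_punct = rep(FALSE, n), is_stopword = rep(FALSE, n),
    pos = pos_tag, determiner = determiner, case = case, plural = plural,
    lemma = lemma, agreement_subject = agreement))
  names(tokens) <- TOKEN_COLUMNS

  spans <- fast_df(list(
    start = all_pos,
    end = all_pos + ifelse(is_null, 0L, 1L),
    head_lemma = head_lemma, is_pronoun = is_pron, is_null_subject = is_null,
    anaphoric = as.logical(anaphoric), generic = as.logical(generic),
    anomaly = anomaly, category = all_cat))
  names(spans) <- c("start", "end", "head_lemma", "is_pronoun",
                    "is_null_subject", "anaphoric", "generic", "anomaly",
                    "category")

  t <- structure(list(participant_id = participant_id, group = group,
                      picture_id = as.integer(picture_id), tokens = tokens,
                      word_count = n),
                 class = "transcript")
  list(transcript = t, annotation = new_annotation_set(t, spans))
}

#' Simulate a group-structured corpus of annotated narrations
#'
#' Generates, per narration: a negative-binomial word count; occurrence
#' positions for every NP category from its configured renewal process
#' truncated at narration length; token features consistent with each
#' category (so [classify_np()] recovers the generating label); anaphoric
#' spans re-using an earlier span's head lemma; and annotator-style
#' referential-anomaly flags at the group's rate. Per-participant age and
#' education covariates are drawn per group. Identical config and seed
#' give a byte-identical corpus.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed (defaults to `cfg$seed`).
#' @return Object of class `synthetic_corpus`: `transcripts` (a
#'   [transcript_set()]), `annotations` (list of `annotation_set`, same
#'   order), `participants` (data.frame with `participant_id`, `group`,
#'   `age`, `education`) and the `config`.
#' @export
simulate_corpus <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  groups <- rep(names(cfg$groups), cfg$groups)
  pid <- unlist(lapply(names(cfg$groups), function(g)
    sprintf("%s%03d", g, seq_len(cfg$groups[[g]]))))
  age <- stats::rnorm(length(pid), cfg$age_mean[groups], cfg$age_sd)
  edu <- stats::rnorm(length(pid), cfg$edu_mean[groups], cfg$edu_sd)
  participants <- data.frame(participant_id = pid, group = groups,
                             age = round(age, 1), education = round(edu, 1),
                             stringsAsFactors = FALSE)

  n_nar <- length(pid) * cfg$pictures
  transcripts <- vector("list", n_nar)
  annotations <- vector("list", n_nar)
  k <- 0L
  for (i in seq_along(pid)) {
    for (pic in seq_len(cfg$pictures)) {
      k <- k + 1L
      nar <- simulate_narration(cfg, pid[i], groups[i], pic)
      transcripts[[k]] <- nar$transcript
      annotations[[k]] <- nar$annotation
    }
  }
  structure(list(
    transcripts = structure(list(transcripts = transcripts,
                                 provenance = "synthetic"),
                            class = "transcript_set"),
    annotations = annotations,
    participants = participants,
    config = cfg,
    seed = as.integer(seed)
  ), class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat("<synthetic_corpus> ", nrow(x$participants), " participants x ",
      x$config$pictures, " narrations (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Per-narration count table for a corpus
#'
#' One row per narration: identifiers, covariates, word count, counts per
#' NP category and referential anomalies. This is the input shape of the
#' Poisson rate models.
#'
#' @param corpus a `synthetic_corpus`, or a list of `annotation_set`
#'   objects plus a `participants` data.frame.
#' @param annotations optional list of `annotation_set` overriding the
#'   corpus' stored ones (e.g. re-derived by [annotate_transcript()]).
#' @return data.frame of per-narration counts.
#' @export
corpus_counts <- function(corpus, annotations = NULL) {
  anns <- if (!is.null(annotations)) annotations
          else if (inherits(corpus, "synthetic_corpus")) corpus$annotations
          else corpus
  cm <- t(vapply(anns, count_categories,
                 numeric(length(NP_CATEGORIES) + 2L)))
  out <- data.frame(
    participant_id = vapply(anns, `[[`, "", "participant_id"),
    group = vapply(anns, `[[`, "", "group"),
    picture_id = vapply(anns, `[[`, 0L, "picture_id"),
    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(cm))
  if (inherits(corpus, "synthetic_corpus")) {
    m <- match(out$participant_id, corpus$participants$participant_id)
    out$age <- corpus$participants$age[m]
    out$education <- corpus$participants$education[m]
  }
  out
}

#' Simulate an embedding stream with controllable consecutive cosine
#'
#' First vector uniform on the unit sphere; each next vector is
#' `normalize(rho * e_i + sqrt(1 - rho^2) * eps)` with `eps` an isotropic
#' unit vector, so the expected consecutive cosine is `rho` and the
#' measured similarity is monotone in `rho`.
#'
#' @param n number of vectors (>= 2).
#' @param dim dimension (>= 2).
#' @param rho mixing coefficient in `[0, 1)`.
#' @param seed integer seed.
#' @return `n x dim` numeric matrix of unit vectors.
#' @export
simulate_embedding_stream <- function(n, dim, rho, seed = NULL) {
  stopifnot(n >= 2L, dim >= 2L, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  E <- matrix(0, n, dim)
  v <- stats::rnorm(dim)
  E[1L, ] <- v / sqrt(sum(v^2))
  w <- sqrt(1 - rho^2)
  for (i in 2:n) {
    eps <- stats::rnorm(dim)
    eps <- eps / sqrt(sum(eps^2))
    v <- rho * E[i - 1L, ] + w * eps
    E[i, ] <- v / sqrt(sum(v^2))
  }
  E
}

#' Simulate a token-probability stream
#'
#' Negative log-probabilities from a positive-truncated normal, so the
#' pseudo-perplexity concentrates near `exp(mean_nll)` at large `n` and
#' equals it exactly when `sd = 0`.
#'
#' @param n number of tokens.
#' @param mean_nll mean negative log probability (> 0).
#' @param sd standard deviation before truncation.
#' @param seed integer seed.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
simulate_probability_stream <- function(n, mean_nll, sd = 0.5, seed = NULL) {
  stopifnot(n >= 1L, mean_nll > 0, sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sd == 0) return(rep(exp(-mean_nll), n))
  nll <- stats::rnorm(n, mean_nll, sd)
  while (any(bad <- nll <= 0)) nll[bad] <- stats::rnorm(sum(bad), mean_nll, sd)
  exp(-nll)
}

#' Simulate a clustered continuous outcome for GEE recovery
#'
#' `y = intercept + beta * x + sigma * e` with exchangeable errors of
#' within-cluster correlation `rho`: `e = sqrt(rho) * b_cluster +
#' sqrt(1 - rho) * w`, `b` and `w` standard normal.
#'
#' @param n_clusters,cluster_size design shape.
#' @param beta true slope on the standard-normal predictor.
#' @param rho within-cluster correlation in `[0, 1)`.
#' @param sigma marginal error sd.
#' @param seed integer seed.
#' @param intercept true intercept.
#' @return List `y`, `X` (intercept + predictor `x`), `cluster`.
#' @export
simulate_clustered_outcome <- function(n_clusters, cluster_size, beta,
                                       rho, sigma = 1, seed = NULL,
                                       intercept = 0) {
  stopifnot(rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_clusters * cluster_size
  cluster <- rep(seq_len(n_clusters), each = cluster_size)
  x <- stats::rnorm(n)
  b <- stats::rnorm(n_clusters)[cluster]
  w <- stats::rnorm(n)
  y <- intercept + beta * x + sigma * (sqrt(rho) * b + sqrt(1 - rho) * w)
  X <- cbind("(Intercept)" = 1, x = x)
  list(y = y, X = X, cluster = cluster)
}
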