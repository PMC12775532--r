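#' Pipeline stage names, in dependency order
#' @format Character vector.
#' @export
PIPELINE_STAGES <- c("simulate", "annotate", "dynamics", "semantics",
                     "fit", "report")

#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: either a simulation config
#' or paths to an existing corpus, the stages to execute, and every seed
#' and test setting, so a run is fully reproducible from its config alone.
#'
#' @param simulation a [generator_config()], or `NULL` when reading an
#'   external corpus.
#' @param input list with `transcripts` (JSONL path) and optionally
#'   `annotations` (span TSV path); ignored when `simulation` is given.
#' @param stages stages to run, a subset of
#'   `simulate, annotate, dynamics, semantics, fit, report` (dependency
#'   order is enforced internally).
#' @param seed master seed; per-stage seeds are derived from it
#'   deterministically.
#' @param alpha significance level for the arrival tests.
#' @param n_sim Monte-Carlo replicates for the arrival tests (the
#'   full-scale analysis uses 100000; pipeline runs default to 2000).
#' @param min_gaps minimum gaps per arrival test.
#' @param provider `"stream"` (group-structured synthetic embedding and
#'   probability streams; only for synthetic corpora) or `"stub"`
#'   (deterministic hash provider on token surfaces).
#' @param dim embedding dimension for the semantics stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(simulation = generator_config(),
                       input = NULL,
                       stages = PIPELINE_STAGES,
                       seed = 1L, alpha = 0.05, n_sim = 2000L,
                       min_gaps = 8L,
                       provider = c("stream", "stub"),
                       dim = 32L) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  provider <- match.arg(provider)
  if (is.null(simulation) && is.null(input))
    stop("either a simulation config or input paths are required")
  structure(list(simulation = simulation, input = input,
                 stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages],
                 seed = as.integer(seed), alpha = alpha,
                 n_sim = as.integer(n_sim), min_gaps = as.integer(min_gaps),
                 provider = provider, dim = as.integer(dim)),
            class = "run_config")
}

config_hash <- function(cfg) {
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  tf <- tempfile()
  writeLines(js, tf, useBytes = TRUE)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 7919 + string_hash(label)) %% 2147483629)
}

annotations_from_table <- function(tset, tab) {
  keys <- paste(tab$participant_id, tab$picture_id, sep = "\r")
  lapply(tset$transcripts, function(t) {
    rows <- tab[keys == paste(t$participant_id, t$picture_id, sep = "\r"), ,
                drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    spans <- np_spans(rows$start, rows$end, rows$head_lemma,
                      rows$is_pronoun, rows$is_null_subject,
                      rows$anaphoric, rows$generic, rows$anomaly)
    annotate_transcript(t, spans)
  })
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order — simulate (or load),
#' annotate, dynamics, semantics, fit, report — writing each stage's
#' output as plain CSV/JSONL files under `out_dir` plus a JSON manifest
#' with the config hash, per-file checksums and record counts. Any stage
#' failure leaves the completed stages' outputs in place, records the
#' failed stage in the manifest, and then signals the error.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly, as an object of class `run_manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("refcoh")),
                   config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   created = format(Sys.time(), tz = "UTC"),
                   stages = list())
  state <- new.env(parent = emptyenv())

  record <- function(stage, files, n = NA_integer_) {
    paths <- file.path(out_dir, files)
    manifest$stages[[stage]] <<- list(
      status = "ok",
      checksums = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                          files)),
      n_records = n)
  }
  finish <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  for (stage in cfg$stages) {
    ok <- tryCatch({
      n <- switch(stage,
        simulate = stage_simulate(cfg, state, out_dir),
        annotate = stage_annotate(cfg, state, out_dir),
        dynamics = stage_dynamics(cfg, state, out_dir),
        semantics = stage_semantics(cfg, state, out_dir),
        fit = stage_fit(cfg, state, out_dir),
        report = { report_run(out_dir); NA_integer_ })
      record(stage, stage_files(stage), n)
      TRUE
    }, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      finish()
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  finish()
  invisible(structure(manifest, class = "run_manifest"))
}

stage_files <- function(stage) {
  switch(stage,
    simulate = c("corpus.jsonl", "annotations.tsv", "participants.csv"),
    annotate = "counts.csv",
    dynamics = "dynamics.csv",
    semantics = "semantics.csv",
    fit = c("fits_poisson.csv", "fits_gee.csv"),
    report = c("report_group_means.csv", "report_coefficients.csv",
               "report_arrivals.csv"))
}

stage_simulate <- function(cfg, state, out_dir) {
  if (is.null(cfg$simulation)) stop("no simulation config supplied")
  corpus <- simulate_corpus(cfg$simulation, seed = cfg$seed)
  state$corpus <- corpus
  state$annotations <- corpus$annotations
  write_transcripts(corpus$transcripts, file.path(out_dir, "corpus.jsonl"))
  write_annotations(corpus$annotations, file.path(out_dir, "annotations.tsv"))
  write_table(corpus$participants, file.path(out_dir, "participants.csv"))
  length(corpus$transcripts$transcripts)
}

load_inputs <- function(cfg, state) {
  if (is.null(state$tset)) {
    if (!is.null(state$corpus)) {
      state$tset <- state$corpus$transcripts
    } else {
      if (is.null(cfg$input$transcripts))
        stop("no corpus available: supply input$transcripts or run the simulate stage")
      state$tset <- read_transcripts(cfg$input$transcripts)
    }
  }
  state$tset
}

require_annotations <- function(cfg, state) {
  if (is.null(state$annotations)) {
    if (is.null(cfg$input$annotations))
      stop("no annotations available: supply input$annotations or run the simulate stage")
    tset <- load_inputs(cfg, state)
    tab <- read_annotations(cfg$input$annotations)
    state$annotations <- annotations_from_table(tset, tab)
  }
  state$annotations
}

stage_annotate <- function(cfg, state, out_dir) {
  tset <- load_inputs(cfg, state)
  anns <- require_annotations(cfg, state)
  # re-derive categories from the features via the classifier
  derived <- lapply(seq_along(anns), function(i) {
    a <- anns[[i]]
    sp <- a$spans
    sp$category <- NULL
    annotate_transcript(tset$transcripts[[i]], sp)
  })
  state$annotations <- derived
  counts <- corpus_counts(state$corpus %||% derived, annotations = derived)
  state$counts <- counts
  write_table(counts, file.path(out_dir, "counts.csv"))
  nrow(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_dynamics <- function(cfg, state, out_dir) {
  anns <- require_annotations(cfg, state)
  groups <- unique(vapply(anns, `[[`, "", "group"))
  rows <- list()
  for (g in groups) {
    in_g <- anns[vapply(anns, `[[`, "", "group") == g]
    for (m in MACRO_TYPES) {
      series <- lapply(in_g, occurrence_positions, macro = m)
      gaps <- inter_occurrence_gaps(series)
      tst <- exponentiality_test(gaps, n_sim = cfg$n_sim, alpha = cfg$alpha,
                                 seed = derive_seed(cfg$seed, paste(g, m)),
                                 min_gaps = cfg$min_gaps)
      rows[[paste(g, m)]] <- data.frame(
        group = g, macro_type = m, n_gaps = tst$n_gaps,
        mean_distance = mean_distance(gaps), lambda_hat = tst$lambda_hat,
        fraction_significant = tst$fraction_significant, mc_p = tst$mc_p,
        rejected = tst$rejected, status = tst$status,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write_table(out, file.path(out_dir, "dynamics.csv"))
  state$dynamics <- out
  nrow(out)
}

stage_semantics <- function(cfg, state, out_dir) {
  tset <- load_inputs(cfg, state)
  stub <- stub_provider(seed = cfg$seed, dim = cfg$dim)
  use_stream <- cfg$provider == "stream" && !is.null(state$corpus)
  sim_cfg <- if (use_stream) state$corpus$config else NULL
  rows <- lapply(tset$transcripts, function(t) {
    if (use_stream) {
      sd1 <- derive_seed(cfg$seed, paste0("emb:", t$participant_id, ":", t$picture_id))
      E <- simulate_embedding_stream(max(t$word_count, 2L), cfg$dim,
                                     sim_cfg$embedding$rho[[t$group]],
                                     seed = sd1)
      sim <- consecutive_cosine_similarity(E)
      sd2 <- derive_seed(cfg$seed, paste0("nll:", t$participant_id, ":", t$picture_id))
      p <- simulate_probability_stream(max(t$word_count, 1L),
                                       sim_cfg$nll$mean[[t$group]],
                                       sim_cfg$nll$sd, seed = sd2)
      pppl <- pseudo_perplexity(p)
      img <- image_text_similarity(stub$embed_image(t$picture_id),
                                   stub$embed_tokens(t$tokens$surface[!t$tokens$is_punct]))
      list(similarity = sim, pppl = pppl, img2txt = img)
    } else {
      semantic_profile(t, stub)
    }
  })
  out <- data.frame(
    participant_id = vapply(tset$transcripts, `[[`, "", "participant_id"),
    group = vapply(tset$transcripts, `[[`, "", "group"),
    picture_id = vapply(tset$transcripts, `[[`, 0L, "picture_id"),
    similarity = vapply(rows, `[[`, 0, "similarity"),
    pppl = vapply(rows, `[[`, 0, "pppl"),
    img2txt = vapply(rows, `[[`, 0, "img2txt"),
    stringsAsFactors = FALSE)
  write_table(out, file.path(out_dir, "semantics.csv"))
  state$semantics <- out
  nrow(out)
}

stage_fit <- function(cfg, state, out_dir) {
  if (is.null(state$counts)) {
    anns <- require_annotations(cfg, state)
    state$counts <- corpus_counts(state$corpus %||% anns, annotations = anns)
  }
  counts <- state$counts
  has_cov <- all(c("age", "education") %in% names(counts))
  covs <- if (has_cov) c("age", "education") else character(0)
  X <- design_matrix(counts, covariates = covs)

  outcomes <- c(NP_CATEGORIES, "referential_anomalies")
  prows <- list()
  for (oc in outcomes) {
    y <- counts[[oc]]
    if (sum(y) == 0) next
    fit <- suppressWarnings(
      poisson_glm_offset(y, log(counts$words), X))
    prows[[oc]] <- data.frame(
      outcome = oc, term = names(fit$coefficients),
      B = unname(fit$coefficients), Se = unname(fit$se), z = unname(fit$z),
      p = unname(fit$p), q = unname(fit$q),
      converged = fit$converged, separation = fit$separation,
      stringsAsFactors = FALSE)
  }
  pois <- do.call(rbind, prows)
  write_table(pois, file.path(out_dir, "fits_poisson.csv"))

  grows <- list()
  if (!is.null(state$semantics)) {
    sem <- state$semantics
    key <- paste(counts$participant_id, counts$picture_id)
    m <- match(paste(sem$participant_id, sem$picture_id), key)
    dat <- cbind(sem, counts[m, c(NP_CATEGORIES, "words"), drop = FALSE])
    dat$definite_rate <- with(dat, (definite_dp + bare_anaphoric +
                                      bare_specific) / words)
    dat$indefinite_rate <- with(dat, (indefinite_dp + bare_indefinite) / words)
    dat$age <- if (has_cov) counts$age[m] else NULL
    dat$education <- if (has_cov) counts$education[m] else NULL
    Xg <- design_matrix(dat, covariates = covs)
    for (oc in c("similarity", "pppl", "img2txt")) {
      ok <- is.finite(dat[[oc]])
      fit <- gee_gaussian_exchangeable(dat[[oc]][ok],
                                       Xg[ok, , drop = FALSE],
                                       dat$participant_id[ok])
      grows[[oc]] <- data.frame(
        outcome = oc, term = names(fit$coefficients),
        B = unname(fit$coefficients), Se = unname(fit$robust_se),
        z = unname(fit$z), p = unname(fit$p), q = unname(fit$q),
        rho = fit$rho, stringsAsFactors = FALSE)
    }
    Xr <- cbind(Xg, definite_rate = dat$definite_rate,
                indefinite_rate = dat$indefinite_rate)
    ok <- is.finite(dat$similarity)
    fit <- gee_gaussian_exchangeable(dat$similarity[ok], Xr[ok, , drop = FALSE],
                                     dat$participant_id[ok])
    grows[["similarity_vs_np_rates"]] <- data.frame(
      outcome = "similarity_vs_np_rates", term = names(fit$coefficients),
      B = unname(fit$coefficients), Se = unname(fit$robust_se),
      z = unname(fit$z), p = unname(fit$p), q = unname(fit$q),
      rho = fit$rho, stringsAsFactors = FALSE)
  }
  gee <- if (length(grows)) do.call(rbind, grows) else
    data.frame(outcome = character(0), term = character(0), B = numeric(0),
               Se = numeric(0), z = numeric(0), p = numeric(0),
               q = numeric(0), rho = numeric(0))
  write_table(gee, file.path(out_dir, "fits_gee.csv"))
  state$fits <- list(poisson = pois, gee = gee)
  nrow(pois) + nrow(gee)
}

#' Summarise a completed pipeline run
#'
#' Reads the stage outputs under `run_dir` and produces: per-group means
#' and standard deviations of the referential variables aggregated per
#' participant (word count, the nine NP categories, referential
#' anomalies); the coefficient tables of the fitted models (B, Se, z, p,
#' q); and the arrival-test table (group by macro-type). The three tables
#' are also written back as `report_*.csv`.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Object of class `run_report` with `group_means`,
#'   `coefficients`, `arrivals`.
#' @export
report_run <- function(run_dir) {
  need <- c("counts.csv")
  missing <- need[!file.exists(file.path(run_dir, need))]
  if (length(missing))
    stop("missing stage outputs: ", paste(missing, collapse = ", "))
  counts <- read_table_file(file.path(run_dir, "counts.csv"))

  vars <- c("words", NP_CATEGORIES, "referential_anomalies")
  per_part <- stats::aggregate(counts[vars],
                               by = list(participant_id = counts$participant_id,
                                         group = counts$group),
                               FUN = sum)
  groups <- unique(per_part$group)
  gm <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (g in groups) {
    sub <- per_part[per_part$group == g, vars, drop = FALSE]
    gm[[paste0(g, "_mean")]] <- round(vapply(sub, mean, 0), 3)
    gm[[paste0(g, "_sd")]] <- round(vapply(sub, stats::sd, 0), 3)
  }

  coefs <- NULL
  for (f in c("fits_poisson.csv", "fits_gee.csv")) {
    p <- file.path(run_dir, f)
    if (file.exists(p)) {
      tab <- read_table_file(p)
      tab <- tab[, intersect(c("outcome", "term", "B", "Se", "z", "p", "q"),
                             names(tab)), drop = FALSE]
      coefs <- rbind(coefs, tab)
    }
  }
  arrivals <- if (file.exists(file.path(run_dir, "dynamics.csv")))
    read_table_file(file.path(run_dir, "dynamics.csv")) else NULL

  write_table(gm, file.path(run_dir, "report_group_means.csv"))
  write_table(coefs %||% data.frame(), file.path(run_dir, "report_coefficients.csv"))
  write_table(arrivals %||% data.frame(),
              file.path(run_dir, "report_arrivals.csv"))
  structure(list(group_means = gm, coefficients = coefs,
                 arrivals = arrivals),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\nGroup means (per participant):\n")
  print(x$group_means)
  if (!is.null(x$arrivals)) {
    cat("\nArrival tests:\n")
    print(x$arrivals)
  }
  invisible(x)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> refcoh ", x$package_version, ", seed ", x$seed,
      ", config ", substr(x$config_hash, 1, 8), "\n", sep = "")
  for (s in names(x$stages))
    cat("  ", s, ": ", x$stages[[s]]$status, "\n", sep = "")
  invisible(x)
}
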