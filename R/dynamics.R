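#' Occurrence positions of a macro-type within one narration
#'
#' Head-token indices (0-based) of the spans whose category maps to the
#' requested macro-type, in narrative order.
#'
#' @param a an `annotation_set`.
#' @param macro one of `definite_dp`, `indefinite_dp`, `bare_indefinite`,
#'   `bare_residual`.
#' @return An object of class `occurrence_series` with sorted `positions`.
#' @export
occurrence_positions <- function(a, macro) {
  stopifnot(inherits(a, "annotation_set"), macro %in% MACRO_TYPES)
  sp <- a$spans
  sel <- macro_type(sp$category) == macro
  pos <- sort(as.integer(ifelse(sp$is_null_subject[sel], sp$start[sel],
                                sp$end[sel] - 1L)))
  structure(list(macro_type = macro,
                 participant_id = a$participant_id,
                 group = a$group,
                 picture_id = a$picture_id,
                 n_tokens = a$n_tokens,
                 positions = pos),
            class = "occurrence_series")
}

#' Inter-occurrence gaps
#'
#' Token-index differences between successive occurrences of the same
#' macro-type within one narration. Gaps never span narration boundaries;
#' a narration with fewer than two occurrences contributes no gaps. Given a
#' list of series (e.g. all narrations of a group) the gaps are pooled.
#'
#' @param s an `occurrence_series` or a list of them.
#' @return An object of class `gap_sample` with the numeric `gaps` and a
#'   `source` data frame tracking each gap's narration.
#' @export
inter_occurrence_gaps <- function(s) {
  if (inherits(s, "occurrence_series")) s <- list(s)
  gaps <- lapply(s, function(x) diff(x$positions))
  src <- do.call(rbind, lapply(seq_along(s), function(i) {
    k <- length(gaps[[i]])
    if (!k) return(NULL)
    data.frame(participant_id = rep(s[[i]]$participant_id, k),
               group = rep(s[[i]]$group, k),
               picture_id = rep(s[[i]]$picture_id, k),
               macro_type = rep(s[[i]]$macro_type, k),
               stringsAsFactors = FALSE)
  }))
  structure(list(gaps = as.numeric(unlist(gaps)), source = src),
            class = "gap_sample")
}

#' Mean inter-occurrence distance
#'
#' The average number of tokens between successive occurrences; larger
#' values indicate sparser recurrence of the macro-type. `NA` when there
#' are no gaps.
#'
#' @param g a `gap_sample` or numeric vector of gaps.
#' @return A number, or `NA_real_` when empty.
#' @export
mean_distance <- function(g) {
  gaps <- if (inherits(g, "gap_sample")) g$gaps else as.numeric(g)
  if (length(gaps) == 0L) NA_real_ else mean(gaps)
}

#' Incidence rate per word
#'
#' @param count non-negative occurrence count.
#' @param words positive word-count exposure.
#' @return `count / words`.
#' @export
incidence_rate <- function(count, words) {
  stopifnot(all(count >= 0))
  if (any(words <= 0)) stop("words must be positive")
  count / words
}

# ---- Kolmogorov-Smirnov internals -----------------------------------------
# Hand-vectorised because the Monte-Carlo loops evaluate the statistic
# ~10^6 times; cross-checked against stats::ks.test in the unit tests.

# Asymptotic Kolmogorov distribution: P(sqrt(n) D > q).
ks_pvalue_asymptotic <- function(q) {
  if (q < 0.05) return(1)
  k <- 1:101
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * q^2))
  min(1, max(0, p))
}

# Two-sample KS statistic with the standard handling of ties (mirrors the
# stats::ks.test construction).
ks2_statistic <- function(x_sorted, y) {
  n_x <- length(x_sorted)
  n_y <- length(y)
  w <- c(x_sorted, y)
  o <- order(w)
  z <- cumsum(ifelse(o <= n_x, 1 / n_x, -1 / n_y))
  ws <- w[o]
  ties <- ws[-1] == ws[-length(ws)]
  if (any(ties)) z <- z[c(!ties, TRUE)]
  max(abs(z))
}

# One-sample KS statistic of sorted data against the Exp(rate) cdf.
ks1_exp_statistic <- function(x_sorted, rate) {
  n <- length(x_sorted)
  f <- 1 - exp(-rate * x_sorted)
  i <- seq_len(n)
  max(i / n - f, f - (i - 1) / n)
}

#' Monte-Carlo test of exponential (memoryless) inter-occurrence gaps
#'
#' Tests whether a macro-type's inter-occurrence gaps are compatible with a
#' Poisson arrival process, i.e. exponential inter-arrival times with rate
#' `lambda_hat = 1 / mean(gaps)`. Two Monte-Carlo procedures are computed:
#'
#' * `two_sample_fraction` — each of `n_sim` simulated samples of the same
#'   size from `Exp(lambda_hat)` is compared to the empirical gaps with a
#'   two-sample KS test; the fraction of comparisons significant at `alpha`
#'   is reported. Under exponential data this fraction stays near `alpha`;
#'   a clearly non-exponential sample pushes it towards 1, so the decision
#'   rule rejects when the fraction exceeds `fraction_threshold`.
#' * `lilliefors_mc` — the one-sample KS statistic `D` of the gaps against
#'   `Exp(lambda_hat)` is referred to its simulated null distribution,
#'   re-estimating the rate within each replicate (the Lilliefors
#'   construction, which accounts for the estimated parameter);
#'   `mc_p` is the fraction of simulated statistics at least as large as
#'   the observed one.
#'
#' Integer token-index gaps introduce ties; the standard tied statistic is
#' used, which is slightly conservative. A seeded uniform jitter on
#' `(-0.5, 0.5)` can be enabled to break ties; it is off by default.
#'
#' @param g a `gap_sample` or numeric vector of gaps (all >= 1).
#' @param n_sim number of simulated null samples (>= 100).
#' @param alpha significance level for the per-comparison tests and the
#'   primary decision.
#' @param seed integer seed; the test is bit-reproducible given the seed.
#' @param method primary method deciding `rejected`.
#' @param methods which procedures to compute (both by default).
#' @param min_gaps minimum usable gap count; below it an explicit
#'   "insufficient occurrences" result is returned and no test is run.
#' @param fraction_threshold rejection threshold for the two-sample
#'   fraction rule.
#' @param jitter add seeded continuity jitter to the integer gaps.
#' @return An object of class `arrival_test` with `lambda_hat`, `n_gaps`,
#'   `fraction_significant`, `mc_p`, `rejected`, `status`, and the settings
#'   used.
#' @export
exponentiality_test <- function(g, n_sim = 100000L, alpha = 0.05,
                                seed = NULL,
                                method = c("lilliefors_mc",
                                           "two_sample_fraction"),
                                methods = c("lilliefors_mc",
                                            "two_sample_fraction"),
                                min_gaps = 8L,
                                fraction_threshold = 0.5,
                                jitter = FALSE) {
  method <- match.arg(method)
  methods <- match.arg(methods, several.ok = TRUE)
  if (!method %in% methods) methods <- unique(c(method, methods))
  gaps <- if (inherits(g, "gap_sample")) g$gaps else as.numeric(g)
  stopifnot(n_sim >= 100L)

  res <- structure(
    list(lambda_hat = NA_real_, n_gaps = length(gaps), n_sim = as.integer(n_sim),
         method = method, fraction_significant = NA_real_, mc_p = NA_real_,
         alpha = alpha, seed = seed, rejected = NA, status = "ok"),
    class = "arrival_test")

  if (length(gaps) < min_gaps) {
    res$status <- "insufficient occurrences"
    return(res)
  }
  if (any(gaps <= 0)) stop("gaps must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (jitter) gaps <- gaps + stats::runif(length(gaps), -0.5, 0.5)

  n <- length(gaps)
  lambda_hat <- 1 / mean(gaps)
  res$lambda_hat <- lambda_hat
  gs <- sort(gaps)

  if ("lilliefors_mc" %in% methods) {
    d_obs <- ks1_exp_statistic(gs, lambda_hat)
    sims <- matrix(stats::rexp(n_sim * n, rate = lambda_hat), nrow = n_sim)
    # row-wise sort, then per-replicate re-estimated rate
    sims <- matrix(sims[order(row(sims), sims)], nrow = n_sim, byrow = TRUE)
    lam_star <- 1 / rowMeans(sims)
    f <- 1 - exp(-sims * lam_star)
    hi <- matrix(rep(seq_len(n) / n, each = n_sim), nrow = n_sim)
    d_star <- do.call(pmax, as.data.frame(pmax(hi - f, f - (hi - 1 / n))))
    res$mc_p <- mean(d_star >= d_obs)
  }

  if ("two_sample_fraction" %in% methods) {
    sig <- logical(n_sim)
    scale_fac <- sqrt(n * n / (n + n))
    for (j in seq_len(n_sim)) {
      y <- stats::rexp(n, rate = lambda_hat)
      d <- ks2_statistic(gs, y)
      sig[j] <- ks_pvalue_asymptotic(scale_fac * d) < alpha
    }
    res$fraction_significant <- mean(sig)
  }

  res$rejected <- switch(method,
    lilliefors_mc = res$mc_p < alpha,
    two_sample_fraction = res$fraction_significant > fraction_threshold)
  res
}

#' @export
print.arrival_test <- function(x, ...) {
  cat("<arrival_test> ", x$method, ", n_gaps = ", x$n_gaps, sep = "")
  if (x$status != "ok") {
    cat(" — ", x$status, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(", lambda_hat = %.4f\n", x$lambda_hat))
  if (!is.na(x$mc_p))
    cat(sprintf("  lilliefors_mc:       mc_p = %.4f\n", x$mc_p))
  if (!is.na(x$fraction_significant))
    cat(sprintf("  two_sample_fraction: %.3f significant at alpha = %g\n",
                x$fraction_significant, x$alpha))
  cat("  rejected:", x$rejected, "\n")
  invisible(x)
}
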