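#' Build a design matrix with group contrasts and centered covariates
#'
#' Intercept, indicator columns for each non-reference group (reference
#' NC), and covariates centered on the analysis-sample mean. Gender-style
#' factors should be passed pre-coded as indicators.
#'
#' @param data data.frame holding the predictor columns.
#' @param group name of the group column (levels from the data; reference
#'   first).
#' @param covariates character vector of numeric covariate columns to
#'   center and include.
#' @param reference reference group level.
#' @param extra character vector of numeric columns included as-is
#'   (e.g. picture indicators already coded).
#' @return Numeric matrix with named columns, full column rank enforced by
#'   the fitters.
#' @export
design_matrix <- function(data, group = "group", covariates = character(0),
                          reference = "NC", extra = character(0)) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  X <- matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(group) && group %in% names(data)) {
    g0 <- data[[group]]
    g <- as.character(g0)
    others <- if (is.factor(g0)) setdiff(levels(g0), reference)
              else if (all(unique(g) %in% GROUP_LABELS))
                intersect(GROUP_LABELS, setdiff(unique(g), reference))
              else sort(setdiff(unique(g), reference))
    levels <- c(reference, others)
    for (lev in levels[-1L]) {
      X <- cbind(X, as.numeric(g == lev))
      colnames(X)[ncol(X)] <- paste0(group, lev)
    }
  }
  for (cv in covariates) {
    x <- as.numeric(data[[cv]])
    X <- cbind(X, x - mean(x))
    colnames(X)[ncol(X)] <- paste0(cv, "_c")
  }
  for (cv in extra) {
    X <- cbind(X, as.numeric(data[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  X
}

check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(qx)
}

#' Poisson rate regression with a log-exposure offset
#'
#' Fits `counts ~ Poisson(exp(X beta + log_exposure))` by iteratively
#' reweighted least squares, so coefficients are log rate differences per
#' word relative to the reference group. Convergence when the largest
#' coefficient update falls below `tol` (default 1e-10) or after
#' `max_iter` iterations. Quasi-separation (a group with all-zero counts
#' drives its coefficient towards -Inf) is flagged, not penalised: the fit
#' is reported with a warning, `separation = TRUE` and `converged = FALSE`
#' if the iteration limit was hit.
#'
#' @param counts non-negative integer outcome vector.
#' @param log_exposure log word-count offset, same length.
#' @param X design matrix (see [design_matrix()]); full column rank.
#' @param tol,max_iter IRLS convergence controls.
#' @param fdr apply Benjamini-Hochberg across the non-intercept p-values
#'   (one family per fitted outcome); intercept `q` is `NA`.
#' @return Object of class `poisson_fit`: `coefficients`, `se`, `z`, `p`,
#'   `q`, `loglik`, `aic`, `converged`, `separation`, `fitted`, plus the
#'   inputs.
#' @export
poisson_glm_offset <- function(counts, log_exposure, X, tol = 1e-10,
                               max_iter = 100L, fdr = TRUE) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(counts) != nrow(X) || length(log_exposure) != nrow(X))
    stop("counts, log_exposure and X must have matching lengths")
  check_full_rank(X)
  p <- ncol(X)

  mu <- counts + 0.5
  eta <- log(mu)
  beta <- rep(0, p)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- pmax(mu, 1e-10) # guards the weighted system under separation
    z <- eta - log_exposure + (counts - mu) / pmax(mu, 1e-10)
    xtw <- t(X * w)
    beta_new <- solve(xtw %*% X, xtw %*% z)[, 1L]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    eta <- drop(X %*% beta) + log_exposure
    mu <- exp(eta)
    if (delta < tol) { converged <- TRUE; break }
    if (any(abs(beta) > 30)) break # diverging: quasi-separation
  }

  info <- t(X * pmax(mu, 1e-10)) %*% X
  se <- sqrt(diag(solve(info)))
  z_stat <- beta / se
  pval <- 2 * stats::pnorm(-abs(z_stat))
  qval <- rep(NA_real_, p)
  if (fdr && p > 1L) {
    idx <- which(colnames(X) != "(Intercept)")
    qval[idx] <- stats::p.adjust(pval[idx], method = "BH")
  }
  separation <- any(abs(beta) > 10)
  if (separation)
    warning("possible quasi-separation: |coefficient| > 10 (",
            paste(colnames(X)[abs(beta) > 10], collapse = ", "), ")")
  ll <- sum(stats::dpois(counts, mu, log = TRUE))

  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z_stat, colnames(X)),
    p = stats::setNames(pval, colnames(X)),
    q = stats::setNames(qval, colnames(X)),
    loglik = ll,
    aic = -2 * ll + 2 * p,
    offset = log_exposure,
    fitted = mu,
    counts = counts,
    X = X,
    converged = converged,
    separation = separation,
    iterations = iter
  ), class = "poisson_fit")
}

#' @export
coef.poisson_fit <- function(object, ...) object$coefficients

#' @export
logLik.poisson_fit <- function(object, ...) {
  structure(object$loglik, df = ncol(object$X), class = "logLik")
}

#' @export
vcov.poisson_fit <- function(object, ...) {
  solve(t(object$X * object$fitted) %*% object$X)
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("<poisson_fit> log-rate model with offset, ",
      length(x$coefficients), " coefficients, ", length(x$counts),
      " observations\n", sep = "")
  print(round(coef_table(x), 4))
  if (!x$converged) cat("  (not converged after", x$iterations, "iterations)\n")
  if (x$separation) cat("  (quasi-separation flagged)\n")
  invisible(x)
}

#' @export
summary.poisson_fit <- function(object, ...) {
  out <- coef_table(object)
  attr(out, "loglik") <- object$loglik
  attr(out, "aic") <- object$aic
  out
}

coef_table <- function(fit) {
  data.frame(B = fit$coefficients, Se = fit$se, z = fit$z, p = fit$p,
             q = fit$q, row.names = names(fit$coefficients))
}

#' Likelihood-ratio and AIC comparison of nested Poisson fits
#'
#' @param fit_full,fit_reduced fits of the same data; the reduced design's
#'   columns must be a subset of the full design's.
#' @return List with `lrt_stat`, `df`, `p`, `delta_aic`
#'   (`AIC(reduced) - AIC(full)`; positive favours the full model).
#' @export
compare_models <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "poisson_fit"),
            inherits(fit_reduced, "poisson_fit"))
  if (length(fit_full$counts) != length(fit_reduced$counts))
    stop("fits are not on the same data")
  if (!all(colnames(fit_reduced$X) %in% colnames(fit_full$X)))
    stop("models are not nested: reduced design has columns absent from the full design")
  df <- ncol(fit_full$X) - ncol(fit_reduced$X)
  if (df < 0) stop("models are not nested: reduced design is larger")
  lrt <- 2 * (fit_full$loglik - fit_reduced$loglik)
  list(lrt_stat = lrt, df = df,
       p = if (df > 0) stats::pchisq(lrt, df, lower.tail = FALSE) else NA_real_,
       delta_aic = fit_reduced$aic - fit_full$aic)
}
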