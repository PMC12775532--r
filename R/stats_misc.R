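#' Spearman partial correlation
#'
#' Rank-transforms `x`, `y` and the controlling covariates, residualises
#' the ranked `x` and `y` on the ranked covariates (with intercept), and
#' correlates the residuals. The p-value uses the t approximation with
#' `n - 2 - ncol(Z)` degrees of freedom. With no covariates this reduces
#' to the ordinary Spearman correlation.
#'
#' @param x,y numeric vectors.
#' @param Z optional numeric matrix / data.frame of covariates to control
#'   for (factors must be pre-coded as indicators).
#' @return Object of class `partial_cor`: `rho`, `p`, `n`, `df`,
#'   `controlled`.
#' @export
spearman_partial <- function(x, y, Z = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  k <- 0L
  controlled <- character(0)
  rx <- rank(x); ry <- rank(y)
  if (!is.null(Z)) {
    Z <- as.matrix(as.data.frame(Z))
    if (nrow(Z) != n) stop("Z must have the same number of rows as x")
    k <- ncol(Z)
    controlled <- colnames(Z)
    if (is.null(controlled)) controlled <- paste0("z", seq_len(k))
    if (n <= k + 2L) stop("need n > ncol(Z) + 2")
    rz <- apply(Z, 2L, rank)
    q <- qr(cbind(1, rz))
    sx <- stats::sd(rx); sy <- stats::sd(ry)
    rx <- qr.resid(q, rx)
    ry <- qr.resid(q, ry)
    if (stats::sd(rx) <= 1e-10 * sx || stats::sd(ry) <= 1e-10 * sy)
      stop("input is rank-collinear with covariates: partial correlation undefined")
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(list(rho = rho, p = pval, n = n, df = df,
                 controlled = controlled),
            class = "partial_cor")
}

#' @export
print.partial_cor <- function(x, ...) {
  cat(sprintf("Spearman partial rho = %.4f (p = %.4g, n = %d", x$rho, x$p, x$n))
  if (length(x$controlled))
    cat(", controlling ", paste(x$controlled, collapse = ", "), sep = "")
  cat(")\n")
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with enforced monotonicity, as implemented by
#' `stats::p.adjust(method = "BH")`, wrapped with input validation and a
#' family label so that correction families stay explicit in reported
#' tables.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param family label naming the correction family.
#' @return Object of class `fdr_result` with `p`, `q` and `family`.
#' @export
bh_fdr <- function(p, family = "") {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  structure(list(p = p, q = stats::p.adjust(p, method = "BH"),
                 family = family),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> family '", x$family, "', ", length(x$p), " p-values, ",
      sum(x$q < 0.05), " with q < 0.05\n", sep = "")
  invisible(x)
}
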