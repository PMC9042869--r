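# Confound screening and partial correlation.
#
# A candidate confound (age, gender, ...) is correlated with the target
# scores -- Pearson for continuous variables, point-biserial (Pearson on
# the 0/1 coding) for binary ones -- and with every edge. The flagging rule
# follows effect size as well as significance: |r| >= 0.15 with the score,
# or p < alpha with the score, or any BH-significant edge association,
# marks the variable as a confound to be partialled out of edge selection.

# Pearson r with two-sided p from the t-distribution on df degrees of
# freedom; a (residually) constant input carries no association (r = 0)
.cor_test <- function(x, y, df = length(x) - 2L) {
  if (stats::sd(x) < .Machine$double.eps^0.5 ||
      stats::sd(y) < .Machine$double.eps^0.5) {
    return(list(r = 0, p = 1))
  }
  r <- stats::cor(x, y)
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df))
}

#' Screen a candidate confounding variable
#'
#' @param values Numeric vector of the candidate variable (binary variables
#'   coded 0/1).
#' @param z_scores Standardized target scores.
#' @param z_edges Optional subjects x edges matrix of standardized edge
#'   weights; when given, per-edge associations are screened too.
#' @param kind `"continuous"` (Pearson) or `"binary"` (point-biserial).
#' @param alpha Significance level (default 0.05).
#' @param r_threshold Effect-size threshold on the score association that
#'   flags the variable regardless of significance (default 0.15).
#' @return List of class `confound_report`: `variable` (from the argument),
#'   `r_with_score`, `p_with_score`, `n_edges_associated` (BH-significant
#'   at `alpha`), `treated_as_confound`.
#' @export
screen_confound <- function(values, z_scores, z_edges = NULL,
                            kind = c("continuous", "binary"),
                            alpha = 0.05, r_threshold = 0.15) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(z_scores))
  if (stats::sd(values) <= 0) stop("candidate variable is constant")
  if (kind == "binary" && !all(values %in% c(0, 1))) {
    stop("binary variables must be coded 0/1")
  }
  ct <- .cor_test(values, z_scores)
  n_assoc <- 0L
  if (!is.null(z_edges)) {
    stopifnot(is.matrix(z_edges), nrow(z_edges) == length(values))
    sds <- matrixStats::colSds(z_edges)
    valid <- sds > .Machine$double.eps^0.5
    r_e <- drop(stats::cor(z_edges[, valid, drop = FALSE], values))
    df <- length(values) - 2L
    t_e <- r_e * sqrt(df / pmax(1 - r_e^2, .Machine$double.eps))
    p_e <- stats::p.adjust(2 * stats::pt(-abs(t_e), df), method = "BH")
    n_assoc <- sum(p_e < alpha)
  }
  structure(list(
    variable = deparse(substitute(values)),
    kind = kind,
    r_with_score = ct$r,
    p_with_score = ct$p,
    n_edges_associated = n_assoc,
    treated_as_confound = abs(ct$r) >= r_threshold || ct$p < alpha ||
      n_assoc > 0L
  ), class = "confound_report")
}

#' @export
print.confound_report <- function(x, ...) {
  cat(sprintf(paste0("<confound_report> %s (%s): r = %.3f (p = %.3g) with ",
                     "score, %d associated edge(s) -> %sconfound\n"),
              x$variable, x$kind, x$r_with_score, x$p_with_score,
              x$n_edges_associated,
              if (x$treated_as_confound) "" else "not a "))
  invisible(x)
}

#' Partial Pearson correlation
#'
#' Correlation between the residuals of `x` and `y` after linear regression
#' on the covariates (with intercept); the p-value comes from the
#' t-distribution with n - k - 2 degrees of freedom. With no covariates
#' this is the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional matrix/vector of k covariates.
#' @return List `r`, `p`, `df`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    k <- ncol(covariates)
    if (n <= k + 2L) stop("need n > k + 2 observations")
    res <- .residualize(cbind(x, y), covariates)
    x <- res[, 1L]
    y <- res[, 2L]
  }
  ct <- .cor_test(x, y, df = n - k - 2L)
  list(r = ct$r, p = ct$p, df = n - k - 2L)
}
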