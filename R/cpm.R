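# CPM core: edge standardization, FDR edge selection into positive and
# negative tails, network-strength features, and the trained model object.

#' Fit per-edge standardization parameters on a training set
#'
#' Computes each edge's mean and (n-1) standard deviation across training
#' subjects. Degenerate edges (zero variance) are flagged; they are excluded
#' from selection and map to z = 0 when the standardization is applied.
#'
#' @param train_edges Training matrix, subjects x edges (raw weights).
#' @return Object of class `edge_standardization` with `means`, `sds`, and
#'   logical `degenerate`.
#' @export
fit_edge_standardization <- function(train_edges) {
  stopifnot(is.matrix(train_edges))
  if (nrow(train_edges) < 2L) stop("need at least 2 training subjects")
  means <- colMeans(train_edges)
  sds <- matrixStats::colSds(train_edges)
  degenerate <- sds < .Machine$double.eps^0.5
  structure(list(means = means, sds = sds, degenerate = degenerate),
            class = "edge_standardization")
}

#' Apply frozen edge standardization
#'
#' Z-transforms each edge with the training-set mean and SD (never the test
#' set's own moments). Degenerate edges map to 0.
#'
#' @param edges Matrix (subjects x edges) or single edge vector.
#' @param std An [fit_edge_standardization()] object.
#' @return Z-scored matrix of the same shape (vectors come back as 1-row
#'   matrices' vector).
#' @export
apply_edge_standardization <- function(edges, std) {
  stopifnot(inherits(std, "edge_standardization"))
  vec <- !is.matrix(edges)
  if (vec) edges <- matrix(edges, nrow = 1L)
  if (ncol(edges) != length(std$means)) {
    stop("edge count mismatch: ", ncol(edges), " vs ", length(std$means))
  }
  sds <- ifelse(std$degenerate, 1, std$sds)
  z <- sweep(sweep(edges, 2L, std$means, `-`), 2L, sds, `/`)
  if (any(std$degenerate)) z[, std$degenerate] <- 0
  if (vec) drop(z) else z
}

#' Positive/negative-tail edge network
#'
#' @param pos_edges,neg_edges Disjoint integer edge indices.
#' @param n_edges Optional total edge count for validation.
#' @return Object of class `predictive_network`.
#' @export
predictive_network <- function(pos_edges = integer(), neg_edges = integer(),
                               n_edges = NULL) {
  pos_edges <- sort(unique(as.integer(pos_edges)))
  neg_edges <- sort(unique(as.integer(neg_edges)))
  if (length(intersect(pos_edges, neg_edges))) {
    stop("positive and negative tails must be disjoint")
  }
  if (!is.null(n_edges) && length(c(pos_edges, neg_edges)) &&
      max(c(pos_edges, neg_edges)) > n_edges) {
    stop("edge index exceeds n_edges")
  }
  structure(list(pos_edges = pos_edges, neg_edges = neg_edges),
            class = "predictive_network")
}

#' @export
print.predictive_network <- function(x, ...) {
  cat(sprintf("<predictive_network> %d positive, %d negative edges\n",
              length(x$pos_edges), length(x$neg_edges)))
  invisible(x)
}

# residualize columns of m on covariates (with intercept)
.residualize <- function(m, covariates) {
  X <- cbind(1, as.matrix(covariates))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("rank-deficient covariate matrix")
  m - X %*% qr.coef(qrX, m)
}

#' Select score-correlated edges under FDR control
#'
#' Correlates every edge with the standardized scores (Pearson), adjusts the
#' two-sided p-values by Benjamini-Hochberg across all non-degenerate edges,
#' retains edges with adjusted p below `q`, and splits them by correlation
#' sign into the positive tail (weights rise with depression severity) and
#' the negative tail. When covariates are supplied the *edges* are first
#' residualized on them (semi-partial correlation; the t-test then uses
#' n - 2 - k degrees of freedom).
#'
#' @param z_edges Subjects x edges matrix of standardized edge weights.
#' @param z_scores Standardized scores (non-constant).
#' @param q FDR level (default 0.01).
#' @param covariates Optional subjects x k matrix/vector of confounds to
#'   partial out of the edges.
#' @return `predictive_network` with attributes `r` (per-edge correlations)
#'   and `p_fdr` (adjusted p-values; NA for degenerate edges).
#' @export
select_edges <- function(z_edges, z_scores, q = 0.01, covariates = NULL) {
  stopifnot(is.matrix(z_edges))
  n <- nrow(z_edges)
  if (n < 4L) stop("need at least 4 subjects for edge selection")
  if (length(z_scores) != n) stop("score length mismatch")
  if (stats::sd(z_scores) <= 0) stop("scores are constant")
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n)
    k <- ncol(covariates)
    z_edges <- .residualize(z_edges, covariates)
  }
  sds <- matrixStats::colSds(z_edges)
  valid <- sds > .Machine$double.eps^0.5
  r <- rep(NA_real_, ncol(z_edges))
  r[valid] <- drop(stats::cor(z_edges[, valid, drop = FALSE], z_scores))
  df <- n - 2L - k
  if (df < 1L) stop("too few subjects for ", k, " covariate(s)")
  tval <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df)
  p_fdr <- rep(NA_real_, length(p))
  p_fdr[valid] <- stats::p.adjust(p[valid], method = "BH")
  sel <- which(valid & p_fdr < q)
  net <- predictive_network(pos_edges = sel[r[sel] > 0],
                            neg_edges = sel[r[sel] < 0],
                            n_edges = ncol(z_edges))
  attr(net, "r") <- r
  attr(net, "p_fdr") <- p_fdr
  net
}

#' Network strength features of one subject
#'
#' @param z_edge_vector Standardized edge vector of one subject.
#' @param network A [predictive_network()].
#' @return List of class `strength_features`: `pos_strength` (sum of z over
#'   the positive tail), `neg_strength` (sum over the negative tail), and
#'   `summed_index = pos_strength - neg_strength`. Empty tails give 0.
#' @export
network_strength <- function(z_edge_vector, network) {
  stopifnot(inherits(network, "predictive_network"))
  pos <- if (length(network$pos_edges))
    sum(z_edge_vector[network$pos_edges]) else 0
  neg <- if (length(network$neg_edges))
    sum(z_edge_vector[network$neg_edges]) else 0
  structure(list(pos_strength = pos, neg_strength = neg,
                 summed_index = pos - neg),
            class = "strength_features")
}

# subjects x {pos, neg, summed} strength matrix
.strength_matrix <- function(z_edges, network) {
  pos <- if (length(network$pos_edges))
    rowSums(z_edges[, network$pos_edges, drop = FALSE]) else numeric(nrow(z_edges))
  neg <- if (length(network$neg_edges))
    rowSums(z_edges[, network$neg_edges, drop = FALSE]) else numeric(nrow(z_edges))
  cbind(pos = pos, neg = neg, summed = pos - neg)
}

.feature_modes <- c("pos", "neg", "combined", "both")

# feature matrix for a mode: pos / neg / combined (summed index) / both
.features_for_mode <- function(strengths, feature_mode) {
  switch(feature_mode,
         pos = strengths[, "pos", drop = FALSE],
         neg = strengths[, "neg", drop = FALSE],
         combined = strengths[, "summed", drop = FALSE],
         both = strengths[, c("pos", "neg"), drop = FALSE],
         stop("unknown feature_mode '", feature_mode, "'"))
}

#' Train a CPM model
#'
#' Fits the full training path on one cohort: per-edge standardization,
#' FDR edge selection (unless a `network` is supplied, e.g. a consensus
#' network), network-strength features, and a linear epsilon-SVR from the
#' features to the standardized scores. When the selected network is empty
#' (no informative edges) the model degrades to a dummy mean predictor.
#'
#' @param edges Subjects x edges matrix of raw edge weights.
#' @param z_scores Standardized scores.
#' @param q FDR level for selection (default 0.01).
#' @param feature_mode `"pos"`, `"neg"`, `"combined"` (summed index,
#'   default) or `"both"` (pos and neg as two features).
#' @param covariates Optional confound matrix passed to [select_edges()].
#' @param network Optional fixed [predictive_network()]; skips selection.
#' @param C,epsilon SVR hyperparameters (defaults 1 and 0.1).
#' @param scale_params Optional [scale_params()] recorded for score
#'   harmonization at prediction/external-validation time.
#' @return Object of class `cpm_model`.
#' @export
cpm_train <- function(edges, z_scores, q = 0.01,
                      feature_mode = c("combined", "pos", "neg", "both"),
                      covariates = NULL, network = NULL,
                      C = 1, epsilon = 0.1, scale_params = NULL) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.matrix(edges), nrow(edges) == length(z_scores))
  std <- fit_edge_standardization(edges)
  z_edges <- apply_edge_standardization(edges, std)
  if (is.null(network)) {
    network <- select_edges(z_edges, z_scores, q = q, covariates = covariates)
  }
  feats <- .features_for_mode(.strength_matrix(z_edges, network), feature_mode)
  degenerate <- all(matrixStats::colSds(feats) < .Machine$double.eps^0.5)
  regressor <- if (degenerate) {
    structure(list(mean = mean(z_scores)), class = "dummy_model")
  } else {
    fit_svr(feats, z_scores, C = C, epsilon = epsilon)
  }
  structure(list(edge_std = std, network = network,
                 feature_mode = feature_mode, regressor = regressor,
                 q = q, C = C, epsilon = epsilon,
                 train_mean = mean(z_scores),
                 scale_params = scale_params),
            class = "cpm_model")
}

#' @export
predict.dummy_model <- function(object, newdata, ...) {
  rep(object$mean, if (is.matrix(newdata)) nrow(newdata) else 1L)
}

#' Predict standardized scores for new connectomes
#'
#' Applies the frozen training pipeline: vectorize (if a matrix connectome),
#' frozen edge standardization, strength features over the model's network,
#' regressor output.
#'
#' @param object A [cpm_train()] model.
#' @param newdata Subjects x edges matrix, a single edge vector, or a
#'   square `cpm_connectome` matrix.
#' @param ... Unused.
#' @return Predicted standardized score(s).
#' @export
predict.cpm_model <- function(object, newdata, ...) {
  if (is.matrix(newdata) && nrow(newdata) == ncol(newdata) &&
      nrow(newdata) > 1L && isTRUE(all.equal(unname(unclass(newdata)),
                                             unname(t(unclass(newdata)))))) {
    newdata <- matrix(vectorize_connectome(unclass(newdata)), nrow = 1L)
  } else if (!is.matrix(newdata)) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  if (ncol(newdata) != length(object$edge_std$means)) {
    stop("edge count mismatch: ", ncol(newdata), " vs ",
         length(object$edge_std$means))
  }
  z <- apply_edge_standardization(newdata, object$edge_std)
  if (!is.matrix(z)) z <- matrix(z, nrow = 1L)
  feats <- .features_for_mode(.strength_matrix(z, object$network),
                              object$feature_mode)
  stats::predict(object$regressor, feats)
}

#' @export
print.cpm_model <- function(x, ...) {
  cat(sprintf("<cpm_model> feature_mode=%s, %d pos / %d neg edges, %s\n",
              x$feature_mode, length(x$network$pos_edges),
              length(x$network$neg_edges),
              if (inherits(x$regressor, "dummy_model")) "dummy (mean) regressor"
              else sprintf("linear SVR (C=%g, eps=%g)", x$C, x$epsilon)))
  invisible(x)
}
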