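# Internal k-fold x iteration cross-validation with permutation null,
# consensus networks, external validation with frozen parameters, and
# baselines. All training-side estimation (edge standardization, selection,
# SVR) sees training folds only; test subjects pass through frozen
# parameters.

#' Prediction performance metrics
#'
#' Pearson correlation, mean absolute error, and coefficient of
#' determination R^2 = 1 - SS_res / SS_tot (computed against the observed
#' mean; can be negative on held-out data). A constant prediction vector
#' carries no linear association and is recorded as r = 0.
#'
#' @param pred,obs Numeric vectors of equal length >= 3; `obs` must be
#'   non-constant.
#' @return Named list `r`, `mae`, `r_squared`.
#' @export
#' @examples
#' metrics(c(1, 2, 3), c(1, 2, 4))
metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(obs) < 3L) stop("need at least 3 observations")
  if (stats::sd(obs) <= 0) stop("observed values are constant")
  r <- if (stats::sd(pred) > 0) stats::cor(pred, obs) else 0
  list(r = r,
       mae = mean(abs(pred - obs)),
       r_squared = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2))
}

#' Balanced k-fold assignment
#'
#' Random partition of `n` subjects into `k` folds whose sizes differ by at
#' most one.
#'
#' @param n Number of subjects.
#' @param k Number of folds (2 <= k <= n).
#' @return Integer vector of fold labels in `1..k`.
#' @export
fold_plan <- function(n, k) {
  stopifnot(k >= 2L, n >= k)
  sample(rep_len(seq_len(k), n))
}

# split a master seed into a reproducible stream of sub-seeds (< 2^31)
.seed_stream <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max, n))
}

# fit on train rows, predict test rows; returns predictions + network + aux
.cpm_fold <- function(edges, z_scores, train, test, q, feature_mode,
                      covariates, C, epsilon) {
  model <- cpm_train(edges[train, , drop = FALSE], z_scores[train], q = q,
                     feature_mode = feature_mode,
                     covariates = if (is.null(covariates)) NULL
                                  else covariates[train, , drop = FALSE],
                     C = C, epsilon = epsilon)
  list(pred = stats::predict(model, edges[test, , drop = FALSE]),
       network = model$network,
       train_mean = model$train_mean)
}

#' Internal validation: repeated k-fold cross-validation
#'
#' Runs `n_iterations` independent, reshuffled k-fold cross-validations.
#' Within each fold, edge standardization, FDR edge selection, and the SVR
#' are fit on the training folds only; the held-out fold is predicted
#' through the frozen parameters. Performance is reported as mean +/- SD
#' over all folds x iterations, alongside the dummy (training-mean)
#' baseline MAE and the per-fold selected networks.
#'
#' @param edges Subjects x edges matrix of raw edge weights.
#' @param z_scores Standardized scores.
#' @param k Folds (default 5; 10 is the usual alternative).
#' @param n_iterations Repetitions with reshuffled folds (default 100).
#' @param q FDR level (default 0.01).
#' @param feature_mode See [cpm_train()] (default `"combined"`).
#' @param covariates Optional confound matrix (subjects x k).
#' @param groups Optional group labels for group-wise evaluation of the
#'   pooled per-iteration predictions.
#' @param C,epsilon SVR hyperparameters.
#' @param seed Optional master seed (fold plans are drawn from it).
#' @param keep_networks Keep per-fold networks for consensus extraction
#'   (default TRUE).
#' @return Object of class `cpm_cv`: per-metric mean/SD (`r`, `mae`,
#'   `r_squared`, each `c(mean, sd)`), `dummy_mae`, `networks` (list of
#'   `predictive_network`, one per fold x iteration), `edge_counts`,
#'   `per_group`, and the run configuration.
#' @export
cross_validate <- function(edges, z_scores, k = 5, n_iterations = 100,
                           q = 0.01, feature_mode = "combined",
                           covariates = NULL, groups = NULL,
                           C = 1, epsilon = 0.1, seed = NULL,
                           keep_networks = TRUE) {
  stopifnot(is.matrix(edges), nrow(edges) == length(z_scores))
  n <- nrow(edges)
  if (!k %in% 2:n || n < 2 * k) stop("too few subjects for ", k, " folds")
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  run <- function() {
    r_all <- mae_all <- r2_all <- dummy_all <- numeric(0)
    networks <- list()
    edge_counts <- integer(0)
    per_group_acc <- list()
    for (it in seq_len(n_iterations)) {
      folds <- fold_plan(n, k)
      pred_pool <- numeric(n)
      for (f in seq_len(k)) {
        test <- which(folds == f)
        train <- which(folds != f)
        fit <- .cpm_fold(edges, z_scores, train, test, q, feature_mode,
                         covariates, C, epsilon)
        pred_pool[test] <- fit$pred
        m <- metrics(fit$pred, z_scores[test])
        r_all <- c(r_all, m$r)
        mae_all <- c(mae_all, m$mae)
        r2_all <- c(r2_all, m$r_squared)
        dummy_all <- c(dummy_all,
                       dummy_baseline(z_scores[train], z_scores[test]))
        if (keep_networks) networks[[length(networks) + 1L]] <- fit$network
        edge_counts <- c(edge_counts, length(fit$network$pos_edges) +
                           length(fit$network$neg_edges))
      }
      if (!is.null(groups)) {
        per_group_acc[[it]] <- groupwise_eval(pred_pool, z_scores, groups)
      }
    }
    per_group <- NULL
    if (length(per_group_acc)) {
      gnames <- names(per_group_acc[[1L]])
      per_group <- lapply(stats::setNames(gnames, gnames), function(g) {
        rs <- vapply(per_group_acc, function(x) x[[g]]$r, numeric(1))
        maes <- vapply(per_group_acc, function(x) x[[g]]$mae, numeric(1))
        list(r = mean(rs), mae = mean(maes))
      })
    }
    list(r = c(mean = mean(r_all), sd = stats::sd(r_all)),
         mae = c(mean = mean(mae_all), sd = stats::sd(mae_all)),
         r_squared = c(mean = mean(r2_all), sd = stats::sd(r2_all)),
         dummy_mae = c(mean = mean(dummy_all), sd = stats::sd(dummy_all)),
         networks = networks, edge_counts = edge_counts,
         per_group = per_group)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(c(res, list(k = k, n_iterations = n_iterations, q = q,
                        feature_mode = feature_mode, n = n, seed = seed)),
            class = "cpm_cv")
}

#' @export
print.cpm_cv <- function(x, ...) {
  cat(sprintf(paste0("<cpm_cv> %d-fold x %d iterations (n=%d, %s)\n",
                     "  r   = %.3f +/- %.3f\n  MAE = %.3f +/- %.3f ",
                     "(dummy %.3f)\n  R^2 = %.3f +/- %.3f\n"),
              x$k, x$n_iterations, x$n, x$feature_mode,
              x$r[["mean"]], x$r[["sd"]], x$mae[["mean"]], x$mae[["sd"]],
              x$dummy_mae[["mean"]], x$r_squared[["mean"]],
              x$r_squared[["sd"]]))
  invisible(x)
}

#' Permutation test on the cross-validated MAE
#'
#' Shuffles the scores `n_perm` times; each permutation reruns the full
#' leakage-free cross-validation (reshuffled folds) and contributes one
#' mean MAE to the null distribution. The p-value uses the add-one
#' convention p = (1 + #\{null MAE <= observed MAE\}) / (1 + n_perm), so a
#' model no better than chance cannot reach p = 0.
#'
#' @param edges,z_scores,k,q,feature_mode,covariates,C,epsilon As in
#'   [cross_validate()].
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param n_iterations CV iterations for the observed run and each
#'   permutation (default 1; the observed MAE averages over folds either
#'   way).
#' @param seed Optional master seed, split across the observed run and the
#'   permutations.
#' @return List of class `cpm_perm`: `p`, `observed_mae`, `null_mae`
#'   (length `n_perm`), `n_perm`.
#' @export
permutation_test <- function(edges, z_scores, k = 5, q = 0.01,
                             feature_mode = "combined", covariates = NULL,
                             n_perm = 1000, n_iterations = 1,
                             C = 1, epsilon = 0.1, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  seeds <- .seed_stream(seed, 2L * n_perm + 1L)
  obs <- cross_validate(edges, z_scores, k = k, n_iterations = n_iterations,
                        q = q, feature_mode = feature_mode,
                        covariates = covariates, C = C, epsilon = epsilon,
                        seed = seeds[1L], keep_networks = FALSE)
  observed_mae <- obs$mae[["mean"]]
  null_mae <- vapply(seq_len(n_perm), function(b) {
    perm <- withr::with_seed(seeds[2L * b], sample(z_scores))
    cv <- cross_validate(edges, perm, k = k, n_iterations = n_iterations,
                         q = q, feature_mode = feature_mode,
                         covariates = covariates, C = C, epsilon = epsilon,
                         seed = seeds[2L * b + 1L],
                         keep_networks = FALSE)
    cv$mae[["mean"]]
  }, numeric(1))
  p <- (1 + sum(null_mae <= observed_mae)) / (1 + n_perm)
  structure(list(p = p, observed_mae = observed_mae, null_mae = null_mae,
                 n_perm = n_perm, observed = obs),
            class = "cpm_perm")
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat(sprintf("<cpm_perm> observed MAE %.3f, %d permutations, p = %.4g\n",
              x$observed_mae, x$n_perm, x$p))
  invisible(x)
}

#' Consensus predictive network across iterations
#'
#' Edges that persist in every per-fold/per-iteration network: the positive
#' tail is the intersection of all positive tails, likewise the negative.
#'
#' @param networks Non-empty list of [predictive_network()] objects, e.g.
#'   `cross_validate(...)$networks`.
#' @return A `predictive_network`.
#' @export
consensus_network <- function(networks) {
  if (!is.list(networks) || length(networks) == 0L) {
    stop("networks must be a non-empty list")
  }
  stopifnot(all(vapply(networks, inherits, logical(1), "predictive_network")))
  pos <- Reduce(intersect, lapply(networks, `[[`, "pos_edges"))
  neg <- Reduce(intersect, lapply(networks, `[[`, "neg_edges"))
  predictive_network(pos_edges = pos, neg_edges = neg)
}

#' Dummy (training-mean) baseline MAE
#'
#' @param train_targets,test_targets Non-empty numeric vectors.
#' @return MAE of predicting `mean(train_targets)` for every test subject.
#' @export
dummy_baseline <- function(train_targets, test_targets) {
  if (!length(train_targets) || !length(test_targets)) {
    stop("empty target vector")
  }
  mean(abs(test_targets - mean(train_targets)))
}

#' Group-wise evaluation
#'
#' Computes r and MAE separately within each group label; groups with fewer
#' than `min_n` subjects (or constant observed scores) are omitted with a
#' message.
#'
#' @param pred,obs Predictions and observations.
#' @param groups Group labels (same length).
#' @param min_n Minimum group size to report (default 3).
#' @return Named list: group -> list(r, mae, n).
#' @export
groupwise_eval <- function(pred, obs, groups, min_n = 3) {
  stopifnot(length(pred) == length(obs), length(groups) == length(obs))
  out <- list()
  for (g in unique(as.character(groups))) {
    sel <- which(groups == g)
    if (length(sel) < min_n || stats::sd(obs[sel]) <= 0) {
      message("group '", g, "' omitted (n=", length(sel), " or constant)")
      next
    }
    m <- metrics(pred[sel], obs[sel])
    out[[g]] <- list(r = m$r, mae = m$mae, n = length(sel))
  }
  out
}

#' External validation with frozen model and consensus network
#'
#' Scores an independent cohort through a frozen training pipeline: target
#' scores are standardized with the training scale parameters (rescaled by
#' the rule of three when the cohort is on a different scale), edges pass
#' through the frozen training standardization, strengths are computed over
#' the model's (typically consensus) network, and the trained regressor
#' predicts. A bootstrap p-value for r > 0 is computed by resampling
#' subject pairs.
#'
#' @param model A [cpm_train()] model carrying `scale_params`; typically
#'   retrained on the full training cohort with `network = consensus`.
#' @param edges External cohort subjects x edges matrix.
#' @param raw_scores External raw scores in their native scale units.
#' @param scale Scale of `raw_scores` (`"BDI"` or `"HDRS"`).
#' @param groups Optional group labels for group-wise evaluation.
#' @param n_boot Bootstrap resamples for the p-value (default 1000).
#' @param seed Optional seed for the bootstrap.
#' @return List of class `cpm_external`: `r`, `mae`, `r_squared`,
#'   `boot_p`, `dummy_mae`, `pred`, `obs_z`, `per_group`.
#' @export
external_validate <- function(model, edges, raw_scores, scale,
                              groups = NULL, n_boot = 1000, seed = NULL) {
  stopifnot(inherits(model, "cpm_model"))
  if (is.null(model$scale_params)) {
    stop("model carries no scale_params; train with scale_params set")
  }
  rng <- scale_ranges()
  if (!scale %in% names(rng)) stop("unknown scale '", scale, "'")
  params <- if (identical(scale, model$scale_params$scale)) model$scale_params
            else equivalent_scale_params(model$scale_params, rng[[scale]],
                                         scale = scale)
  obs_z <- standardize_scores(raw_scores, params)
  pred <- stats::predict(model, edges)
  m <- metrics(pred, obs_z)
  boot <- function() {
    n <- length(pred)
    vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(pred[i]) > 0 && stats::sd(obs_z[i]) > 0)
        stats::cor(pred[i], obs_z[i]) else 0
    }, numeric(1))
  }
  r_boot <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  boot_p <- (1 + sum(r_boot <= 0)) / (1 + n_boot)
  per_group <- if (is.null(groups)) NULL else groupwise_eval(pred, obs_z, groups)
  structure(list(r = m$r, mae = m$mae, r_squared = m$r_squared,
                 boot_p = boot_p,
                 dummy_mae = mean(abs(obs_z - model$train_mean)),
                 pred = pred, obs_z = obs_z, per_group = per_group,
                 scale = scale, n = length(pred)),
            class = "cpm_external")
}

#' @export
print.cpm_external <- function(x, ...) {
  cat(sprintf(paste0("<cpm_external> n=%d (%s): r = %.3f (bootstrap p = ",
                     "%.4g), MAE = %.3f (dummy %.3f), R^2 = %.3f\n"),
              x$n, x$scale, x$r, x$boot_p, x$mae, x$dummy_mae, x$r_squared))
  invisible(x)
}
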