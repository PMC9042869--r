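# Shared fixtures: small synthetic worlds built in code at test time.
# Module tests use a 16-region world (120 edges) for speed; acceptance
# tests use the full 68-region / 2278-edge geometry.

tiny_model <- function(n_regions = 16, n_pos = 4, n_neg = 2,
                       effect_size = 0.1, noise_sd = 0.05, seed = 101) {
  planted_model(n_regions = n_regions, n_pos = n_pos, n_neg = n_neg,
                effect_size = effect_size, noise_sd = noise_sd, seed = seed)
}

tiny_world <- function(n_hc = 40, n_mdd = 25, model = tiny_model(),
                       seed = 202) {
  cohort <- gen_cohort(n_hc, n_mdd, seed = seed)
  edges <- stack_connectomes(gen_connectomes(cohort, model, seed = seed + 1L))
  params <- fit_scale_params(cohort$score)
  list(cohort = cohort, model = model, edges = edges, params = params,
       z = standardize_scores(cohort$score, params))
}

# primal epsilon-SVR oracle: direct minimisation of
# 0.5*|w|^2 + C * sum(max(0, |y - Xw - b| - eps)), independent of the QP path
svr_primal_oracle <- function(x, y, C = 1, epsilon = 0.1) {
  obj <- function(p) {
    w <- p[-length(p)]
    b <- p[length(p)]
    0.5 * sum(w^2) + C * sum(pmax(abs(y - drop(x %*% w) - b) - epsilon, 0))
  }
  p0 <- c(stats::coef(stats::lm(y ~ x))[-1L], mean(y))
  fit <- stats::optim(p0, obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 5000))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 20000))
  list(w = fit$par[-length(fit$par)], b = fit$par[length(fit$par)],
       value = fit$value, objective = obj)
}
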