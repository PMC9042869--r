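test_that("metrics match hand arithmetic and conventions", {
  obs <- c(1, 2, 4)
  m <- metrics(c(1, 2, 3), obs)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$r, cov(c(1, 2, 3), obs) / (sd(c(1, 2, 3)) * sd(obs)))
  expect_equal(m$r_squared, 1 - 1 / sum((obs - mean(obs))^2))
  perfect <- metrics(obs, obs)
  expect_equal(unlist(perfect), c(r = 1, mae = 0, r_squared = 1))
  shifted <- metrics(obs + 0.5, obs)
  expect_equal(shifted$mae, 0.5)
  expect_equal(shifted$r, 1)
  constant <- metrics(rep(2, 3), obs)       # constant prediction -> r = 0
  expect_equal(constant$r, 0)
  expect_error(metrics(1:3, 1:4), "mismatch")
  expect_error(metrics(1:3, rep(1, 3)), "constant")
})

test_that("fold plans partition subjects into near-equal folds", {
  withr::with_seed(1, {
    for (n in c(121, 50)) {
      f <- fold_plan(n, 5)
      sizes <- tabulate(f, 5)
      expect_equal(sum(sizes), n)
      expect_lte(diff(range(sizes)), 1L)
      expect_true(all(sizes %in% c(24, 25)) || n != 121)
    }
  })
  expect_error(fold_plan(4, 5), "n >= k")
})

test_that("cross_validate aggregates exactly the leakage-free manual path", {
  w <- tiny_world()
  seed <- 33
  cv <- cross_validate(w$edges, w$z, k = 5, n_iterations = 1, seed = seed)
  # reproduce the fold plan from the same seeded stream, then walk each
  # fold with training-only fitting; any leakage in cross_validate would
  # break the equality
  folds <- withr::with_seed(seed, fold_plan(nrow(w$edges), 5))
  r_manual <- mae_manual <- dummy_manual <- numeric(5)
  for (f in 1:5) {
    tr <- which(folds != f)
    te <- which(folds == f)
    model <- cpm_train(w$edges[tr, , drop = FALSE], w$z[tr])
    mm <- metrics(predict(model, w$edges[te, , drop = FALSE]), w$z[te])
    r_manual[f] <- mm$r
    mae_manual[f] <- mm$mae
    dummy_manual[f] <- dummy_baseline(w$z[tr], w$z[te])
  }
  expect_equal(cv$r[["mean"]], mean(r_manual))
  expect_equal(cv$mae[["mean"]], mean(mae_manual))
  expect_equal(cv$dummy_mae[["mean"]], mean(dummy_manual))
  expect_length(cv$networks, 5L)
  expect_equal(cv$edge_counts,
               vapply(cv$networks, function(n)
                 length(n$pos_edges) + length(n$neg_edges), integer(1)))
})

test_that("cross_validate recovers planted signal and beats the dummy", {
  w <- tiny_world()
  cv <- cross_validate(w$edges, w$z, k = 5, n_iterations = 3, seed = 2,
                       groups = w$cohort$group)
  expect_gt(cv$r[["mean"]], 0.8)
  expect_lt(cv$mae[["mean"]], cv$dummy_mae[["mean"]])
  expect_named(cv$per_group, c("HC", "MDD"), ignore.order = TRUE)
  # pooled r exceeds the range-restricted within-group r
  expect_lt(cv$per_group$HC$r, cv$r[["mean"]])
  expect_error(cross_validate(w$edges[1:8, ], w$z[1:8], k = 5), "too few")
})

test_that("consensus network is the intersection across iterations", {
  n1 <- predictive_network(pos_edges = c(1, 2, 3), neg_edges = c(9, 10))
  n2 <- predictive_network(pos_edges = c(2, 3, 4), neg_edges = c(10, 11))
  n3 <- predictive_network(pos_edges = c(2, 3), neg_edges = 12)
  cons <- consensus_network(list(n1, n2, n3))
  expect_equal(cons$pos_edges, c(2L, 3L))
  expect_length(cons$neg_edges, 0L)
  expect_equal(consensus_network(list(n1)), n1)
  # idempotence on identical networks
  expect_equal(consensus_network(list(n2, n2, n2)), n2)
  # consensus is contained in every input network
  cv_nets <- list(n1, n2, n3)
  for (nn in cv_nets) expect_true(all(cons$pos_edges %in% nn$pos_edges))
  expect_error(consensus_network(list()), "non-empty")
})

test_that("dummy baseline arithmetic", {
  expect_equal(dummy_baseline(rep(3, 5), rep(3, 4)), 0)
  expect_equal(dummy_baseline(c(-1, 1), c(-1, 1)), 1)
  expect_error(dummy_baseline(numeric(0), 1), "empty")
})

test_that("permutation test flags planted signal and respects conventions", {
  w <- tiny_world()
  pt <- permutation_test(w$edges, w$z, k = 5, n_perm = 100, seed = 4)
  expect_lte(pt$p, 0.05)
  expect_gt(pt$p, 0)
  expect_length(pt$null_mae, 100L)
  expect_equal(pt$p, (1 + sum(pt$null_mae <= pt$observed_mae)) / 101)
  expect_error(permutation_test(w$edges, w$z, n_perm = 50), ">= 100")
})

test_that("group-wise evaluation splits and guards small groups", {
  obs <- c(1, 2, 3, 10, 11, 12)
  groups <- rep(c("HC", "MDD"), each = 3)
  ge <- groupwise_eval(obs, obs, groups)
  expect_equal(ge$HC$r, 1)
  expect_equal(ge$MDD$mae, 0)
  # single group equals global metrics
  ge1 <- groupwise_eval(obs + 0.5, obs, rep("all", 6))
  expect_equal(ge1$all$mae, metrics(obs + 0.5, obs)$mae)
  expect_message(ge2 <- groupwise_eval(obs, obs, c(rep("a", 5), "b")),
                 "omitted")
  expect_named(ge2, "a")
})

test_that("external validation transfers across scales with frozen params", {
  pm <- tiny_model()
  train <- gen_cohort(60, 40, seed = 51)
  train_edges <- stack_connectomes(gen_connectomes(train, pm, seed = 52))
  params <- fit_scale_params(train$score)
  z <- standardize_scores(train$score, params)
  cv <- cross_validate(train_edges, z, k = 5, n_iterations = 3, seed = 53)
  cons <- consensus_network(cv$networks)
  model <- cpm_train(train_edges, z, network = cons, scale_params = params)

  # external cohort on HDRS, same generator world
  ext <- gen_cohort(30, 20, scale = "HDRS", seed = 54)
  ext_edges <- stack_connectomes(gen_connectomes(ext, pm, seed = 55))
  ev <- external_validate(model, ext_edges, ext$score, "HDRS",
                          groups = ext$group, n_boot = 500, seed = 56)
  expect_lt(abs(ev$r - cv$r[["mean"]]), 0.15)
  expect_lt(ev$boot_p, 0.05)
  expect_lt(ev$mae, ev$dummy_mae)
  # the targets were standardized against rule-of-three equivalent params
  eq <- equivalent_scale_params(params, 52, scale = "HDRS")
  expect_equal(ev$obs_z, standardize_scores(ext$score, eq))

  # scrambled scores carry no signal
  scr <- withr::with_seed(57, sample(ext$score))
  ev0 <- external_validate(model, ext_edges, scr, "HDRS", n_boot = 200,
                           seed = 58)
  expect_lt(abs(ev0$r), 0.35)
  expect_error(external_validate(model, ext_edges, ext$score, "FOO"),
               "unknown scale")
})
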