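test_that("edge standardization: two-point case and self-application", {
  m <- rbind(c(0.2, 0.5), c(0.4, 0.5))
  std <- fit_edge_standardization(m)
  expect_equal(std$means, c(0.3, 0.5))
  expect_equal(std$sds[1], sd(c(0.2, 0.4)))
  expect_true(std$degenerate[2])       # constant edge flagged

  w <- tiny_world(n_hc = 10, n_mdd = 6)
  std2 <- fit_edge_standardization(w$edges)
  z <- apply_edge_standardization(w$edges, std2)
  expect_equal(colMeans(z), rep(0, ncol(z)), tolerance = 1e-12)
  expect_equal(matrixStats::colSds(z), rep(1, ncol(z)), tolerance = 1e-12)
  expect_error(fit_edge_standardization(m[1, , drop = FALSE]), "2 training")
})

test_that("frozen standardization on new subjects matches hand arithmetic", {
  train <- rbind(c(0.1, 0.6), c(0.3, 0.2), c(0.5, 0.4))
  std <- fit_edge_standardization(train)
  newv <- c(0.4, 0.3)
  expect_equal(apply_edge_standardization(newv, std),
               (newv - colMeans(train)) / apply(train, 2, sd))
  # the training mean vector maps to all zeros
  expect_equal(apply_edge_standardization(colMeans(train), std), c(0, 0))
  expect_error(apply_edge_standardization(c(1, 2, 3), std), "mismatch")
})

test_that("select_edges finds a strong planted edge and controls the rest", {
  n <- 100
  withr::with_seed(5, {
    z <- rnorm(n)
    edges <- matrix(rnorm(n * 120), n, 120)
    edges[, 7] <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
    edges[, 8] <- -0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  })
  net <- select_edges(edges, z, q = 0.01)
  expect_true(7 %in% net$pos_edges)
  expect_true(8 %in% net$neg_edges)
  # negating the scores swaps the tails exactly
  net2 <- select_edges(edges, -z, q = 0.01)
  expect_identical(net2$pos_edges, net$neg_edges)
  expect_identical(net2$neg_edges, net$pos_edges)
  # Pearson invariance: affine rescaling of one edge changes nothing
  edges2 <- edges
  edges2[, 7] <- 100 * edges2[, 7] - 3
  net3 <- select_edges(edges2, z, q = 0.01)
  expect_identical(net3$pos_edges, net$pos_edges)
  expect_identical(net3$neg_edges, net$neg_edges)
})

test_that("select_edges validates input and handles constant edges", {
  withr::with_seed(6, {
    edges <- matrix(rnorm(40 * 10), 40, 10)
    z <- rnorm(40)
  })
  expect_error(select_edges(edges, rep(1, 40)), "constant")
  expect_error(select_edges(edges[1:3, ], z[1:3]), "at least 4")
  edges[, 4] <- 2   # degenerate edge: excluded, NA p
  net <- select_edges(edges, z)
  expect_true(is.na(attr(net, "p_fdr")[4]))
  expect_false(4 %in% c(net$pos_edges, net$neg_edges))
})

test_that("covariate residualization changes selection as intended", {
  n <- 120
  withr::with_seed(7, {
    conf <- rnorm(n)
    z <- rnorm(n)
    edges <- matrix(rnorm(n * 50), n, 50)
    edges[, 3] <- conf            # edge driven purely by the confound
  })
  # make scores correlated with the confound so edge 3 looks predictive
  z2 <- 0.8 * conf + 0.6 * z
  raw_net <- select_edges(edges, z2, q = 0.05)
  adj_net <- select_edges(edges, z2, q = 0.05, covariates = conf)
  expect_true(3 %in% c(raw_net$pos_edges, raw_net$neg_edges))
  expect_false(3 %in% c(adj_net$pos_edges, adj_net$neg_edges))
})

test_that("network strength features and the summed-index identity", {
  net <- predictive_network(pos_edges = c(1, 3), neg_edges = 5)
  z <- c(1.5, 0, 0.5, 0, 1.0)
  s <- network_strength(z, net)
  expect_equal(s$pos_strength, 2.0)
  expect_equal(s$neg_strength, 1.0)
  expect_equal(s$summed_index, 1.0)
  s1 <- network_strength(c(2, 0), predictive_network(pos_edges = 1))
  expect_equal(unlist(s1), c(pos_strength = 2, neg_strength = 0,
                             summed_index = 2))
  empty <- network_strength(z, predictive_network())
  expect_equal(unlist(empty), c(pos_strength = 0, neg_strength = 0,
                                summed_index = 0))
  expect_error(predictive_network(pos_edges = 1:3, neg_edges = 3), "disjoint")
})

test_that("trained model predicts consistently and round-trips a subject", {
  w <- tiny_world()
  model <- cpm_train(w$edges, w$z, scale_params = w$params)
  # a training subject through its own model equals the in-sample prediction
  p_all <- predict(model, w$edges)
  expect_equal(predict(model, w$edges[4, ]), unname(p_all[4]))
  # identical connectomes give identical predictions
  expect_identical(predict(model, w$edges[4, ]), predict(model, w$edges[4, ]))
  # square symmetric matrix input is vectorized automatically
  mat <- connectome_from_edges(w$edges[4, ], 16)
  expect_equal(predict(model, mat), unname(p_all[4]))
  # planted signal is recovered end to end
  expect_gt(cor(p_all, w$z), 0.9)
  expect_error(predict(model, w$edges[, 1:10]), "mismatch")
})

test_that("feature modes select the matching feature dimension", {
  w <- tiny_world()
  for (fm in c("pos", "neg", "combined")) {
    m <- cpm_train(w$edges, w$z, feature_mode = fm)
    expect_equal(m$regressor$d, 1L)
  }
  m2 <- cpm_train(w$edges, w$z, feature_mode = "both")
  expect_equal(m2$regressor$d, 2L)
})

test_that("an empty network degrades to the dummy mean predictor", {
  withr::with_seed(8, {
    edges <- matrix(rnorm(40 * 30), 40, 30)
    z <- rnorm(40)
  })
  model <- cpm_train(edges, z, network = predictive_network())
  expect_s3_class(model$regressor, "dummy_model")
  expect_equal(predict(model, edges), rep(mean(z), 40))
})
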