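test_that("degree centrality sums absolute off-diagonal weights", {
  A <- matrix(0.5, 3, 3); diag(A) <- 1
  g <- a2gcn:::new_brain_graph(A)
  expect_equal(centrality_features(g, "DC"), rep(1, 3))
  # on a complete equal-weight graph no node lies on another's geodesic
  expect_equal(centrality_features(g, "BC"), rep(0, 3))
})

test_that("betweenness and closeness match a brute-force shortest-path oracle", {
  set.seed(61)
  for (i in 1:5) {
    g <- random_graph(7)
    feats <- centrality_features(g, c("DC", "BC", "CC"))
    A <- abs(g$adjacency); diag(A) <- 0
    len <- 1 - A
    len[len < 1e-6] <- 1e-6
    len[len > 1] <- 1
    expect_equal(feats[1:7], unname(rowSums(A)), tolerance = 1e-12)
    expect_equal(feats[8:14], unname(oracle_betweenness(len)), tolerance = 1e-9)
    expect_equal(feats[15:21], unname(oracle_closeness(len)), tolerance = 1e-9)
  }
})

test_that("feature lengths follow the DC/BD/BDC and upper-triangle conventions", {
  g <- random_graph(116, seed = 62)
  expect_length(centrality_features(g, "DC"), 116L)
  expect_length(centrality_features(g, c("DC", "BC")), 232L)
  expect_length(centrality_features(g, c("DC", "BC", "CC")), 348L)
  expect_length(vectorize_graph(g), 6670L)   # 116 * 115 / 2
  expect_length(vectorize_graph(random_graph(3)), 3L)
})

test_that("svm baseline separates easy features and is chance on permuted labels", {
  set.seed(63)
  n <- 30
  y <- rep(c(0L, 1L), each = n)
  X <- matrix(rnorm(2 * n * 4), 2 * n, 4) + outer(y, c(6, -6, 4, 0))
  Xt <- matrix(rnorm(2 * n * 4), 2 * n, 4) + outer(y, c(6, -6, 4, 0))
  res <- svm_baseline(X, y, Xt)
  expect_equal(mean(res$pred == y), 1.0)
  expect_identical(res$score, svm_baseline(X, y, Xt)$score)
  expect_gt(auc_score(res$score, y), 0.99)

  # chance-level check on structureless features: with no class signal,
  # permuted labels give target accuracy near 0.5
  accs <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Xn <- matrix(rnorm(2 * n * 4), 2 * n, 4)
    Xnt <- matrix(rnorm(2 * n * 4), 2 * n, 4)
    mean(svm_baseline(Xn, sample(y), Xnt)$pred == y)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.12)
  expect_error(svm_baseline(X, rep(1L, 2 * n), Xt), "single class")
})

test_that("dnn pipeline reduces dimension with PCA and learns", {
  sim <- tiny_cohort(n_rois = 12, m_per_class = 10, delta = 0.8,
                     shift = 0, seed = 64)
  # a long enough schedule for the small network to fit the easy signal
  cfg <- a2gcn_config(batch_size = 8L, epochs_pretrain = 0L,
                      epochs_joint = 600L)
  expect_warning(
    bl <- fit_baseline("dnn", sim, config = cfg, seed = 1),
    "reducing PCA")   # 40 subjects < 64 components
  expect_length(bl$pred, 20L)
  truth <- sim$target_labels_heldout
  expect_gt(mean(bl$pred == truth), 0.8)
  bl2 <- suppressWarnings(fit_baseline("dnn", sim, config = cfg, seed = 1))
  expect_identical(bl2$score, bl$score)
})

test_that("dnnc's CORAL term vanishes on identical domains", {
  set.seed(65)
  y <- rep(c(0L, 1L), each = 10)
  X <- matrix(rnorm(20 * 6), 20, 6) + outer(y, rep(0.5, 6))
  # coinciding domains: the CORAL term is 0 every step, so full-batch
  # training (order-invariant, dropout off) matches coral-free training
  set.seed(2)
  with_coral <- a2gcn:::mlp_train(X, y, Xt = X, hidden = 8L,
                                  coral_weight = 0.5, epochs = 10L,
                                  batch_size = 100L, dropout = 0)
  set.seed(2)
  without <- a2gcn:::mlp_train(X, y, hidden = 8L, coral_weight = 0,
                               epochs = 10L, batch_size = 100L,
                               dropout = 0)
  expect_equal(with_coral$history, without$history, tolerance = 1e-6)
  expect_equal(with_coral$params, without$params, tolerance = 1e-6)
})

test_that("dnnc fits on a cohort and emits predictions", {
  sim <- tiny_cohort(seed = 65)
  cfg <- fast_config()
  bl <- suppressWarnings(fit_baseline("dnnc", sim, config = cfg, seed = 2))
  expect_length(bl$pred, length(sim$graphs_target))
  expect_true(all(bl$score >= 0 & bl$score <= 1))
})

test_that("mmd and dann variants train, predict and reduce to shared schema", {
  sim <- tiny_cohort(seed = 66)
  cfg <- fast_config()
  for (m in c("mmd", "dann")) {
    bl <- fit_baseline(m, sim, config = cfg, seed = 3)
    expect_s3_class(bl$fit, "a2gcn")
    expect_length(bl$pred, length(sim$graphs_target))
    expect_true(all(bl$score >= 0 & bl$score <= 1))
    bl2 <- fit_baseline(m, sim, config = cfg, seed = 3)
    expect_identical(bl$score, bl2$score)
  }
})

test_that("all baselines emit the shared prediction schema", {
  sim <- tiny_cohort(seed = 67)
  cfg <- fast_config()
  for (m in c("dc", "bd", "gcn")) {
    bl <- fit_baseline(m, sim, config = cfg, seed = 1)
    expect_named(bl[c("method", "pred", "score")],
                 c("method", "pred", "score"))
    expect_length(bl$pred, length(sim$graphs_target))
    expect_true(all(bl$pred %in% c(0L, 1L)))
    met <- metrics_from_predictions(bl$pred, bl$score,
                                    sim$target_labels_heldout)
    expect_length(met, 7L)
  }
})
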