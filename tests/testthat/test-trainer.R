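test_that("seeded refits are bit-identical", {
  sim <- tiny_cohort(seed = 51)
  cfg <- fast_config()
  f1 <- a2gcn(sim, config = cfg, seed = 5)
  f2 <- a2gcn(sim, config = cfg, seed = 5)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$target$prob, f2$target$prob)
  f3 <- a2gcn(sim, config = cfg, seed = 6)
  expect_false(identical(f1$params$W0, f3$params$W0))
})

test_that("identical source and target cohorts give zero alignment losses", {
  sim <- tiny_cohort(seed = 52)
  # copy the source graphs into the target slot: domains coincide
  twin <- sim
  twin$graphs_target <- sim$graphs_source
  twin$target_labels_heldout <- sim$labels_source
  cfg <- fast_config(batch_size = 100L)  # one full-cohort step per epoch
  fit <- a2gcn(twin, config = cfg, seed = 3)
  h <- fit$history
  pre <- h[h$stage == "pretrain", ]
  # with a single full batch the position-wise pairing is a permutation of
  # identical graphs only at matching positions; LA compares identical
  # covariance sets, so it is exactly 0 throughout pretraining
  expect_true(all(pre$la < 1e-24))
  expect_equal(fit$cf_post, 0, tolerance = 1e-10)
})

test_that("zero alignment weights reproduce the GCN baseline exactly", {
  sim <- tiny_cohort(seed = 53)
  cfg <- fast_config(gamma1 = 0, gamma2 = 0,
                     gamma1_pretrain = 0, gamma2_pretrain = 0,
                     use_attention = FALSE)
  fit0 <- a2gcn(sim, config = cfg, seed = 9)
  base <- fit_baseline("gcn", sim, config = fast_config(), seed = 9)
  expect_identical(fit0$params, base$fit$params)
  expect_identical(fit0$history, base$fit$history)
  expect_identical(fit0$target$prob, base$fit$target$prob)
})

test_that("pretraining minimizes only the alignment objective", {
  sim <- tiny_cohort(seed = 54, shift = 0.6)
  cfg <- a2gcn_config(epochs_pretrain = 40L, epochs_joint = 1L,
                      batch_size = 8L)
  fit <- a2gcn(sim, config = cfg, seed = 2)
  pre <- fit$history[fit$history$stage == "pretrain", ]
  expect_true(all(pre$lc == 0))
  align <- pre$lm + pre$la
  # optimization progress: the alignment objective decreases
  expect_lt(mean(tail(align, 5)), mean(head(align, 5)))
})

test_that("training separates an easy source cohort", {
  sim <- tiny_cohort(n_rois = 12, m_per_class = 10, delta = 0.8,
                     shift = 0, seed = 55)
  cfg <- a2gcn_config(batch_size = 8L)
  fit <- a2gcn(sim, config = cfg, seed = 1)
  src_acc <- mean((fit$source$prob[, 2] > 0.5) ==
                    (fit$labels_source == 1))
  expect_gte(src_acc, 0.95)
})

test_that("target labels never influence training", {
  sim <- tiny_cohort(seed = 56)
  cfg <- fast_config()
  fit1 <- a2gcn(sim, config = cfg, seed = 4)
  # scramble the held-out labels: the fit must not change at all
  scram <- sim
  scram$target_labels_heldout <- rev(sim$target_labels_heldout)
  scram$manifest$label[!scram$manifest$is_source] <-
    rev(scram$manifest$label[!scram$manifest$is_source])
  fit2 <- a2gcn(scram, config = cfg, seed = 4)
  expect_identical(fit1$params, fit2$params)
  expect_identical(fit1$target$prob, fit2$target$prob)
})

test_that("interrupted training resumes bit-identically", {
  sim <- tiny_cohort(seed = 57)
  cfg <- fast_config(dropout = 0)
  prep_s <- a2gcn:::engine_prepare(sim$graphs_source, "absolute")
  prep_t <- a2gcn:::engine_prepare(sim$graphs_target, "absolute")
  stage_w <- list(ce = 1, mae = 0.5, coral = 0.5, mmd = 0, dann = 0)
  mk_stage <- function(n) list(list(name = "joint", w = stage_w, epochs = n))
  set.seed(8)
  params <- init_a2gcn_params(10, cfg)
  full <- a2gcn:::engine_train(prep_s, sim$labels_source, prep_t,
                               params, cfg, mk_stage(6L))
  set.seed(8)
  params <- init_a2gcn_params(10, cfg)
  part1 <- a2gcn:::engine_train(prep_s, sim$labels_source, prep_t,
                                params, cfg, mk_stage(3L))
  part2 <- a2gcn:::engine_train(prep_s, sim$labels_source, prep_t,
                                part1$params, cfg, mk_stage(3L),
                                adam = part1$adam, epoch_offset = 3L)
  expect_identical(full$params, part2$params)
  expect_equal(full$history$loss, c(part1$history$loss,
                                    part2$history$loss))
})

test_that("run_experiment aggregates metrics across derived seeds", {
  sim <- tiny_cohort(seed = 58)
  cfg <- fast_config()
  ex1 <- run_experiment(sim, "gcn", config = cfg, repeats = 1, seed = 3)
  expect_true(all(ex1$sd == 0 | is.na(ex1$sd)))
  ex <- run_experiment(sim, "gcn", config = cfg, repeats = 3, seed = 3)
  expect_equal(dim(ex$per_repeat), c(3L, 7L))
  expect_true(all(ex$per_repeat >= 0 & ex$per_repeat <= 1, na.rm = TRUE))
  # repeat 1 of the batch equals a standalone run at the same seed
  expect_equal(unname(ex$per_repeat[1, ]), unname(ex1$per_repeat[1, ]))
  ex2 <- run_experiment(sim, "gcn", config = cfg, repeats = 3, seed = 3)
  expect_identical(ex$per_repeat, ex2$per_repeat)
})
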