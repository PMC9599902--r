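# Finite-difference verification of the analytic gradients used by the
# trainer.  Small dimensions keep the FD loops cheap; tolerances are
# relative (1e-4) as appropriate for central differences.

rel_err <- function(a, b) {
  d <- max(abs(a - b))
  d / max(1e-8, max(abs(a)), max(abs(b)))
}

test_that("loss input-gradients match finite differences", {
  set.seed(41)
  # cross entropy wrt logits through softmax
  y <- c(0L, 1L, 1L, 0L)
  logits <- matrix(rnorm(8), 4, 2)
  f_ce <- function(v) {
    p <- a2gcn:::softmax_rows(matrix(v, 4, 2))
    cross_entropy_loss(p, y)
  }
  g_an <- a2gcn:::ce_grad(a2gcn:::softmax_rows(logits), y)
  expect_lt(rel_err(as.numeric(g_an), fd_grad(f_ce, as.numeric(logits))),
            1e-5)

  # CORAL wrt both inputs
  Gs <- matrix(rnorm(18), 6, 3); Gt <- matrix(rnorm(15), 5, 3)
  g <- a2gcn:::coral_grad_pair(Gs, Gt, 3)
  f_s <- function(v) coral_loss(matrix(v, 6, 3), Gt, denom_dim = 3)
  f_t <- function(v) coral_loss(Gs, matrix(v, 5, 3), denom_dim = 3)
  expect_lt(rel_err(as.numeric(g$s), fd_grad(f_s, as.numeric(Gs))), 1e-4)
  expect_lt(rel_err(as.numeric(g$t), fd_grad(f_t, as.numeric(Gt))), 1e-4)

  # MMD wrt both inputs at fixed bandwidths
  A <- matrix(rnorm(12), 4, 3); B <- matrix(rnorm(12), 4, 3)
  bw <- c(0.8, 2)
  gm <- a2gcn:::mmd_value_grad(A, B, bw)
  f_a <- function(v) a2gcn:::mmd_value_grad(matrix(v, 4, 3), B, bw)$value
  f_b <- function(v) a2gcn:::mmd_value_grad(A, matrix(v, 4, 3), bw)$value
  expect_lt(rel_err(as.numeric(gm$s), fd_grad(f_a, as.numeric(A))), 1e-4)
  expect_lt(rel_err(as.numeric(gm$t), fd_grad(f_b, as.numeric(B))), 1e-4)
})

test_that("backpropagated parameter gradients match finite differences", {
  set.seed(42)
  N <- 5L
  graphs_s <- lapply(1:3, function(i) random_graph(N))
  graphs_t <- lapply(1:3, function(i) random_graph(N))
  labels <- c(0L, 1L, 1L)
  cfg <- a2gcn_config(gcn_dims = c(3L, 3L), fc_hidden = 4L, dropout = 0)
  params <- init_a2gcn_params(N, cfg)
  prep_s <- a2gcn:::engine_prepare(graphs_s, "absolute")
  prep_t <- a2gcn:::engine_prepare(graphs_t, "absolute")
  gamma1 <- 0.7; gamma2 <- 0.9
  denom <- 2L * 3L

  loss_at <- function(p) {
    fs <- a2gcn:::engine_forward(prep_s, 1:3, p, use_attention = TRUE,
                                 training = FALSE, with_classifier = TRUE)
    ft <- a2gcn:::engine_forward(prep_t, 1:3, p, use_attention = TRUE,
                                 training = FALSE, with_classifier = FALSE)
    cross_entropy_loss(fs$prob, labels) +
      gamma1 * mean(abs(fs$Z - ft$Z)) +
      gamma2 * coral_loss(fs$G, ft$G, denom_dim = denom)
  }

  fs <- a2gcn:::engine_forward(prep_s, 1:3, params, use_attention = TRUE,
                               training = FALSE, with_classifier = TRUE)
  ft <- a2gcn:::engine_forward(prep_t, 1:3, params, use_attention = TRUE,
                               training = FALSE, with_classifier = FALSE)
  gm <- a2gcn:::mae_grad_pair(fs$Z, ft$Z)
  gc <- a2gcn:::coral_grad_pair(fs$G, ft$G, denom)
  grads <- a2gcn:::engine_backward(
    fs, prep_s, params,
    list(dlogits = a2gcn:::ce_grad(fs$prob, labels),
         dG = gamma2 * gc$s, dZ = gamma1 * gm$s))
  gt <- a2gcn:::engine_backward(
    ft, prep_t, params,
    list(dlogits = NULL, dG = gamma2 * gc$t, dZ = gamma1 * gm$t))
  for (nm in names(gt)) grads[[nm]] <- grads[[nm]] + gt[[nm]]

  for (nm in c("W0", "W1", "Wa1", "ba1", "Wa2", "ba2",
               "Wc1", "bc1", "Wc2", "bc2")) {
    f_nm <- function(v) {
      p <- params
      p[[nm]] <- if (is.matrix(p[[nm]]))
        matrix(v, nrow(p[[nm]]), ncol(p[[nm]])) else v
      loss_at(p)
    }
    fd <- fd_grad(f_nm, as.numeric(params[[nm]]))
    expect_lt(rel_err(as.numeric(grads[[nm]]), fd), 1e-4)
  }
})

test_that("domain-head gradients and reversal scaling match finite differences", {
  set.seed(43)
  cfg <- a2gcn_config(gcn_dims = c(3L, 3L), fc_hidden = 4L, dropout = 0)
  params <- init_a2gcn_params(5, cfg, dann = TRUE)
  G <- matrix(rnorm(36), 6, 6)   # 6 subjects x 2*d2 features
  dom <- c(0L, 0L, 0L, 1L, 1L, 1L)
  hd <- a2gcn:::domain_head_forward(G, params)
  hb <- a2gcn:::domain_head_backward(hd, G, params,
                                     a2gcn:::ce_grad(hd$prob, dom))
  f_G <- function(v) {
    h <- a2gcn:::domain_head_forward(matrix(v, 6, 6), params)
    cross_entropy_loss(h$prob, dom)
  }
  fd <- fd_grad(f_G, as.numeric(G))
  expect_lt(rel_err(as.numeric(hb$dG), fd), 1e-4)
  # through the reversal layer the extractor sees -lambda times that
  lam <- 0.37
  expect_equal(grl_backward(hb$dG, lam), -lam * hb$dG)
  for (nm in c("Wd1", "bd1", "Wd2", "bd2")) {
    f_nm <- function(v) {
      p <- params
      p[[nm]] <- if (is.matrix(p[[nm]]))
        matrix(v, nrow(p[[nm]]), ncol(p[[nm]])) else v
      h <- a2gcn:::domain_head_forward(G, p)
      cross_entropy_loss(h$prob, dom)
    }
    fd <- fd_grad(f_nm, as.numeric(params[[nm]]))
    expect_lt(rel_err(as.numeric(hb$grads[[nm]]), fd), 1e-4)
  }
})
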