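test_that("normalize_adjacency matches the explicit dense oracle", {
  expect_equal(normalize_adjacency(diag(3)), diag(3))
  expect_equal(normalize_adjacency(matrix(1, 2, 2)),
               matrix(0.5, 2, 2))
  set.seed(21)
  for (i in 1:20) {
    A <- random_graph(8)$adjacency
    got <- normalize_adjacency(A)
    expect_equal(unname(got), unname(oracle_normalize(A)),
                 tolerance = 1e-12)
    expect_equal(got, t(got), tolerance = 1e-12)
  }
})

test_that("raw-degree normalization errors on non-positive row sums", {
  A <- matrix(c(1, -0.9, -0.9, -0.9, 1, 0.5, -0.9, 0.5, 1), 3, 3)
  expect_error(normalize_adjacency(A, mode = "raw"), "non-positive")
  B <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  expect_equal(normalize_adjacency(B, mode = "raw"),
               normalize_adjacency(B, mode = "absolute"))
})

test_that("gcn_forward equals the unrolled dense oracle", {
  set.seed(22)
  params <- list(W0 = matrix(0, 4, 3), W1 = matrix(0, 3, 3))
  X <- random_graph(4)$adjacency
  Ahat <- normalize_adjacency(X)
  expect_true(all(gcn_forward(X, Ahat, params) == 0))

  # identity propagation: Ahat = I and identity weights reduce to ReLU(X)
  pid <- list(W0 = diag(4), W1 = diag(4))
  expect_equal(gcn_forward(X, diag(4), pid), pmax(X, 0),
               ignore_attr = TRUE)

  for (i in 1:30) {
    X <- random_graph(4)$adjacency
    Ahat <- normalize_adjacency(X)
    W0 <- matrix(rnorm(12), 4, 3); W1 <- matrix(rnorm(9), 3, 3)
    expect_equal(gcn_forward(X, Ahat, list(W0 = W0, W1 = W1)),
                 oracle_gcn(X, Ahat, W0, W1), tolerance = 1e-12)
  }
  expect_error(gcn_forward(X, Ahat, list(W0 = matrix(0, 7, 3))), "match")
})

test_that("node_attention matches the unrolled oracle and stays in [0,1]", {
  zero <- list(Wa1 = matrix(0, 5, 5), ba1 = numeric(5),
               Wa2 = matrix(0, 5, 5), ba2 = numeric(5))
  H <- matrix(rnorm(15), 5, 3)
  expect_equal(node_attention(H, zero), rep(0.5, 5))

  set.seed(23)
  for (i in 1:30) {
    H <- matrix(rnorm(15), 5, 3)
    p <- list(Wa1 = matrix(rnorm(25), 5, 5), ba1 = rnorm(5),
              Wa2 = matrix(rnorm(25), 5, 5), ba2 = rnorm(5))
    a <- node_attention(H, p)
    expect_true(all(a >= 0 & a <= 1))
    expect_equal(a, oracle_attention(H, p$Wa1, p$ba1, p$Wa2, p$ba2),
                 tolerance = 1e-12)
  }
})

test_that("reweight is the residual scaling Z = (1 + a) * H", {
  set.seed(24)
  H <- matrix(rnorm(24), 6, 4)
  expect_equal(reweight(H, rep(0, 6)), H)
  expect_equal(reweight(H, rep(1, 6)), 2 * H)
  a <- runif(6)
  Z <- reweight(H, a)
  expect_equal(Z - H, H * a)
  # row norms scale by exactly (1 + a_i)
  expect_equal(sqrt(rowSums(Z^2)), (1 + a) * sqrt(rowSums(H^2)),
               tolerance = 1e-12)
  expect_error(reweight(H, rep(0, 5)), "length")
})

test_that("readout concatenates column means and maxima", {
  z1 <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(readout(z1), c(1, 2, 3, 1, 2, 3))
  zc <- matrix(2, 4, 3)
  expect_equal(readout(zc), rep(2, 6))
  set.seed(25)
  for (i in 1:20) {
    Z <- matrix(rnorm(40), 8, 5)
    G <- readout(Z)
    expect_length(G, 10)
    expect_true(all(G[6:10] >= G[1:5]))  # max >= mean per feature
    expect_equal(G[1:5], colMeans(Z))
    expect_equal(G[6:10], apply(Z, 2, max))
  }
})

test_that("classifier head: zero weights, eval determinism, seeded dropout", {
  p <- list(Wc1 = matrix(0, 6, 4), bc1 = numeric(4),
            Wc2 = matrix(0, 4, 2), bc2 = numeric(2))
  out <- classify(rnorm(6), p)
  expect_equal(unname(out$logits[1, ]), c(0, 0))
  expect_equal(unname(out$prob[1, ]), c(0.5, 0.5))

  set.seed(26)
  p2 <- list(Wc1 = matrix(rnorm(24), 6, 4), bc1 = rnorm(4),
             Wc2 = matrix(rnorm(8), 4, 2), bc2 = rnorm(2))
  g <- rnorm(6)
  expect_identical(classify(g, p2), classify(g, p2))  # eval mode
  set.seed(99); tr1 <- classify(g, p2, training = TRUE)
  set.seed(99); tr2 <- classify(g, p2, training = TRUE)
  expect_identical(tr1, tr2)
  expect_error(classify(rnorm(5), p2), "match")
})

test_that("batched engine forward agrees with the single-subject operations", {
  set.seed(27)
  graphs <- lapply(1:3, function(i) random_graph(6))
  cfg <- a2gcn_config(gcn_dims = c(4L, 4L), fc_hidden = 5L)
  params <- init_a2gcn_params(6, cfg)
  prep <- a2gcn:::engine_prepare(graphs, "absolute")
  f <- a2gcn:::engine_forward(prep, 1:3, params, use_attention = TRUE,
                              training = FALSE, with_classifier = TRUE)
  for (s in 1:3) {
    A <- graphs[[s]]$adjacency
    Ahat <- normalize_adjacency(A)
    H <- gcn_forward(A, Ahat, params)
    att <- node_attention(H, params)
    Z <- reweight(H, att)
    G <- readout(Z)
    rows <- ((s - 1) * 6 + 1):(s * 6)
    expect_equal(unname(f$H2[rows, ]), unname(H), tolerance = 1e-12)
    expect_equal(unname(f$Att[s, ]), unname(att), tolerance = 1e-12)
    expect_equal(unname(f$G[s, ]), unname(G), tolerance = 1e-12)
    cls <- classify(G, params)
    expect_equal(unname(f$prob[s, ]), unname(cls$prob[1, ]),
                 tolerance = 1e-12)
  }
})

test_that("zero attention output reduces the forward pass to plain GCN", {
  set.seed(28)
  g <- random_graph(5)
  cfg <- a2gcn_config(gcn_dims = c(3L, 3L), fc_hidden = 4L)
  params <- init_a2gcn_params(5, cfg)
  # force the attention head to output exactly zero scores
  params$Wa1[] <- 0; params$ba1[] <- 0
  params$Wa2[] <- 0; params$ba2[] <- -1e9
  Ahat <- normalize_adjacency(g$adjacency)
  H <- gcn_forward(g$adjacency, Ahat, params)
  att <- node_attention(H, params)
  expect_equal(att, rep(0, 5), tolerance = 1e-12)
  expect_equal(reweight(H, att), H, tolerance = 1e-12)
  prep <- a2gcn:::engine_prepare(list(g), "absolute")
  f_att <- a2gcn:::engine_forward(prep, 1L, params, use_attention = TRUE)
  f_plain <- a2gcn:::engine_forward(prep, 1L, params, use_attention = FALSE)
  expect_equal(f_att$G, f_plain$G, tolerance = 1e-12)
})
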