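# Independent brute-force oracles used to verify the package's
# implementations.  These deliberately use the most literal textbook
# formulation of each quantity and share no code with R/.

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

oracle_normalize <- function(A) {
  D <- diag(1 / sqrt(rowSums(abs(A))))
  D %*% A %*% D
}

oracle_relu <- function(x) pmax(x, 0)

oracle_gcn <- function(X, Ahat, W0, W1) {
  H1 <- oracle_relu(Ahat %*% X %*% W0)
  oracle_relu(Ahat %*% H1 %*% W1)
}

oracle_attention <- function(H, Wa1, ba1, Wa2, ba2) {
  m <- apply(H, 1, max)
  a1 <- oracle_relu(as.numeric(Wa1 %*% m) + ba1)
  1 / (1 + exp(-(as.numeric(Wa2 %*% a1) + ba2)))
}

# two-pass covariance: explicit mean centering
oracle_covariance <- function(G) {
  M <- nrow(G)
  mu <- colMeans(G)
  C <- matrix(0, ncol(G), ncol(G))
  for (i in seq_len(M)) {
    d <- G[i, ] - mu
    C <- C + outer(d, d)
  }
  C / (M - 1)
}

oracle_coral <- function(Gs, Gt, d) {
  delta <- oracle_covariance(Gs) - oracle_covariance(Gt)
  sum(delta^2) / (4 * d^2)
}

oracle_mae <- function(Zs, Zt) {
  s <- 0
  for (i in seq_along(Zs)) s <- s + abs(Zs[i] - Zt[i])
  s / length(Zs)
}

oracle_cross_entropy <- function(p1, y) {
  s <- 0
  for (i in seq_along(y))
    s <- s + if (y[i] == 1) -log(p1[i]) else -log(1 - p1[i])
  s / length(y)
}

# AUC by exhaustive concordant-pair enumeration (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

oracle_metrics <- function(TP, TN, FP, FN) {
  div <- function(a, b) if (b > 0) a / b else NA_real_
  rec <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  pre <- div(TP, TP + FP)
  c(ACC = div(TP + TN, TP + TN + FP + FN),
    Pre = pre, Rec = rec,
    F1 = if (is.na(pre) || is.na(rec) || pre + rec == 0) NA_real_
         else 2 * pre * rec / (pre + rec),
    BAC = if (is.na(rec) || is.na(spec)) NA_real_ else (rec + spec) / 2,
    NPV = div(TN, TN + FN))
}

# multi-kernel MMD^2 by explicit double loops at fixed bandwidths
oracle_mmd <- function(Gs, Gt, bandwidths) {
  k <- function(x, y) sum(sapply(bandwidths,
                                 function(b) exp(-sum((x - y)^2) / b)))
  ms <- nrow(Gs); mt <- nrow(Gt)
  kss <- 0; ktt <- 0; kst <- 0
  for (i in seq_len(ms)) for (j in seq_len(ms))
    kss <- kss + k(Gs[i, ], Gs[j, ])
  for (i in seq_len(mt)) for (j in seq_len(mt))
    ktt <- ktt + k(Gt[i, ], Gt[j, ])
  for (i in seq_len(ms)) for (j in seq_len(mt))
    kst <- kst + k(Gs[i, ], Gt[j, ])
  kss / ms^2 + ktt / mt^2 - 2 * kst / (ms * mt)
}

# all-pairs shortest-path distances by Floyd-Warshall on an edge-length
# matrix (0 = no self loop, Inf = no edge)
oracle_fw <- function(len) {
  n <- nrow(len)
  d <- len
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# betweenness assuming unique shortest paths (continuous random weights):
# node v lies on the s-t geodesic iff d(s,v) + d(v,t) == d(s,t)
oracle_betweenness <- function(len, tol = 1e-9) {
  d <- oracle_fw(len)
  n <- nrow(len)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (abs(d[s, v] + d[v, t] - d[s, t]) < tol) bc[v] <- bc[v] + 1
    }
  }
  bc
}

oracle_closeness <- function(len) {
  d <- oracle_fw(len)
  1 / rowSums(d)
}

# exact hypergeometric upper tail P(X >= x) by summing the pmf
oracle_hyper_tail <- function(x, n_inf, n_tot, n_drawn) {
  kk <- x:min(n_inf, n_drawn)
  sum(choose(n_inf, kk) * choose(n_tot - n_inf, n_drawn - kk)) /
    choose(n_tot, n_drawn)
}

# numeric gradient by central finite differences
fd_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

random_graph <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ts <- matrix(rnorm(4 * n * n), 4 * n, n)
  build_graph(ts)
}

tiny_cohort <- function(n_rois = 10, n_time = 40, m_per_class = 4,
                        delta = 0.5, shift = 0.3, seed = 7, ...) {
  simulate_cohort(n_rois = n_rois, n_time = n_time,
                  m_per_class = m_per_class, k_informative = 3,
                  delta = delta, shift = shift, seed = seed, ...)
}

fast_config <- function(...) {
  defaults <- list(epochs_pretrain = 3L, epochs_joint = 5L,
                   batch_size = 8L)
  do.call(a2gcn_config, utils::modifyList(defaults, list(...)))
}

upper_vals <- function(g) g$adjacency[upper.tri(g$adjacency)]
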