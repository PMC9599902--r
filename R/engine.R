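# Batched training engine: manual forward/backward passes over stacked
# per-subject graphs with shared parameters, and an Adam optimizer.  All
# gradients are exact analytic derivatives of the losses in losses.R; the
# test suite checks them against finite differences.

engine_prepare <- function(graphs, norm_mode = "absolute") {
  stopifnot(length(graphs) >= 1L)
  N <- graphs[[1L]]$n_rois
  Ahat <- lapply(graphs, function(g) {
    if (g$n_rois != N) stop("graphs have differing ROI counts")
    normalize_adjacency(g$adjacency, norm_mode)
  })
  # layer-1 message passing (Ahat %*% X) is constant: precompute per subject
  P0 <- lapply(seq_along(graphs),
               function(i) Ahat[[i]] %*% graphs[[i]]$features)
  list(N = N, M = length(graphs), Ahat = Ahat, P0 = P0,
       subject_ids = vapply(graphs, function(g) g$subject_id, character(1L)))
}

# Forward pass for a batch of subjects.  Rows of the stacked matrices are
# subject-major: subject s occupies rows (s-1)*N + 1:N.
engine_forward <- function(prep, idx, params, use_attention = TRUE,
                           training = FALSE, dropout = 0,
                           with_classifier = TRUE) {
  b <- length(idx); N <- prep$N
  P0b <- do.call(rbind, prep$P0[idx])
  U1 <- P0b %*% params$W0
  H1 <- relu(U1)
  V1 <- H1 %*% params$W1
  U2 <- matrix(0, b * N, ncol(V1))
  for (s in seq_len(b)) {
    r <- ((s - 1L) * N + 1L):(s * N)
    U2[r, ] <- prep$Ahat[[idx[s]]] %*% V1[r, , drop = FALSE]
  }
  H2 <- relu(U2)
  d2 <- ncol(H2)

  if (use_attention) {
    jmax <- max.col(H2, ties.method = "first")
    mvec <- H2[cbind(seq_len(b * N), jmax)]
    Mmat <- matrix(mvec, b, N, byrow = TRUE)
    A1pre <- Mmat %*% t(params$Wa1) +
      matrix(params$ba1, b, N, byrow = TRUE)
    A1 <- relu(A1pre)
    A2pre <- A1 %*% t(params$Wa2) +
      matrix(params$ba2, b, N, byrow = TRUE)
    Att <- stats::plogis(A2pre)
    attvec <- as.vector(t(Att))
    Z <- H2 * (1 + attvec)
  } else {
    jmax <- NULL; Mmat <- NULL; A1pre <- NULL; A1 <- NULL
    Att <- NULL; attvec <- NULL
    Z <- H2
  }

  group <- rep(seq_len(b), each = N)
  Gmean <- rowsum(Z, group) / N
  Gmax <- Z[(0:(b - 1L)) * N + 1L, , drop = FALSE]
  imax <- matrix(1L, b, d2)
  if (N > 1L) for (i in 2:N) {
    cand <- Z[(0:(b - 1L)) * N + i, , drop = FALSE]
    upd <- cand > Gmax
    Gmax[upd] <- cand[upd]
    imax[upd] <- i
  }
  G <- cbind(Gmean, Gmax)

  out <- list(b = b, N = N, d2 = d2, idx = idx,
              P0b = P0b, U1 = U1, H1 = H1, U2 = U2, H2 = H2,
              jmax = jmax, Mmat = Mmat, A1pre = A1pre, A1 = A1,
              Att = Att, attvec = attvec, Z = Z,
              group = group, imax = imax, G = G,
              use_attention = use_attention)
  if (with_classifier) {
    F1pre <- sweep(G %*% params$Wc1, 2L, params$bc1, "+")
    F1 <- relu(F1pre)
    if (training && dropout > 0) {
      mask <- matrix((stats::runif(length(F1)) >= dropout) / (1 - dropout),
                     nrow(F1), ncol(F1))
    } else mask <- NULL
    F1d <- if (is.null(mask)) F1 else F1 * mask
    logits <- sweep(F1d %*% params$Wc2, 2L, params$bc2, "+")
    out$F1pre <- F1pre; out$F1d <- F1d; out$mask <- mask
    out$logits <- logits
    out$prob <- softmax_rows(logits)
  }
  out
}

# Backward pass.  `d` carries the upstream gradients: `dlogits` (b x 2 or
# NULL), `dG` (b x 2*d2 or NULL), `dZ` (bN x d2 or NULL).  Returns a named
# list of parameter gradients (subset of the parameter names).
engine_backward <- function(cache, prep, params, d) {
  b <- cache$b; N <- cache$N; d2 <- cache$d2
  grads <- list()
  dG <- if (is.null(d$dG)) matrix(0, b, 2L * d2) else d$dG

  if (!is.null(d$dlogits)) {
    dlogits <- d$dlogits
    grads$Wc2 <- crossprod(cache$F1d, dlogits)
    grads$bc2 <- colSums(dlogits)
    dF1d <- dlogits %*% t(params$Wc2)
    dF1 <- if (is.null(cache$mask)) dF1d else dF1d * cache$mask
    dF1pre <- dF1 * (cache$F1pre > 0)
    grads$Wc1 <- crossprod(cache$G, dF1pre)
    grads$bc1 <- colSums(dF1pre)
    dG <- dG + dF1pre %*% t(params$Wc1)
  }

  dGmean <- dG[, seq_len(d2), drop = FALSE]
  dGmax <- dG[, d2 + seq_len(d2), drop = FALSE]
  dZ <- dGmean[cache$group, , drop = FALSE] / N
  for (j in seq_len(d2)) {
    rws <- (0:(b - 1L)) * N + cache$imax[, j]
    dZ[cbind(rws, j)] <- dZ[cbind(rws, j)] + dGmax[, j]
  }
  if (!is.null(d$dZ)) dZ <- dZ + d$dZ

  if (cache$use_attention) {
    dH2 <- dZ * (1 + cache$attvec)
    dAtt <- matrix(rowSums(dZ * cache$H2), b, N, byrow = TRUE)
    dA2pre <- dAtt * cache$Att * (1 - cache$Att)
    grads$Wa2 <- crossprod(dA2pre, cache$A1)
    grads$ba2 <- colSums(dA2pre)
    dA1 <- dA2pre %*% params$Wa2
    dA1pre <- dA1 * (cache$A1pre > 0)
    grads$Wa1 <- crossprod(dA1pre, cache$Mmat)
    grads$ba1 <- colSums(dA1pre)
    dMmat <- dA1pre %*% params$Wa1
    dH2m <- matrix(0, b * N, d2)
    dH2m[cbind(seq_len(b * N), cache$jmax)] <- as.vector(t(dMmat))
    dH2 <- dH2 + dH2m
  } else {
    dH2 <- dZ
  }

  dU2 <- dH2 * (cache$U2 > 0)
  dV1 <- matrix(0, b * N, d2)
  for (s in seq_len(b)) {
    r <- ((s - 1L) * N + 1L):(s * N)
    # Ahat is symmetric, so t(Ahat) %*% x == Ahat %*% x
    dV1[r, ] <- prep$Ahat[[cache$idx[s]]] %*% dU2[r, , drop = FALSE]
  }
  grads$W1 <- crossprod(cache$H1, dV1)
  dH1 <- dV1 %*% t(params$W1)
  dU1 <- dH1 * (cache$U1 > 0)
  grads$W0 <- crossprod(cache$P0b, dU1)
  grads
}

# --- analytic loss gradients -------------------------------------------

ce_grad <- function(prob, labels) {
  onehot <- cbind(labels == 0L, labels == 1L) * 1
  (prob - onehot) / length(labels)
}

mae_grad_pair <- function(Zs, Zt) {
  g <- sign(Zs - Zt) / length(Zs)
  list(s = g, t = -g)
}

coral_grad_pair <- function(Gs, Gt, denom_dim) {
  delta <- feature_covariance(Gs) - feature_covariance(Gt)
  cs <- scale(Gs, center = TRUE, scale = FALSE)
  ct <- scale(Gt, center = TRUE, scale = FALSE)
  list(s = cs %*% delta / ((nrow(Gs) - 1) * denom_dim^2),
       t = -ct %*% delta / ((nrow(Gt) - 1) * denom_dim^2))
}

mmd_bandwidths_of <- function(Gs, Gt, n_kernels = 5L, mul = 2) {
  d2 <- pairwise_sqdist(rbind(Gs, Gt))
  med <- stats::median(d2[upper.tri(d2)])
  if (!is.finite(med) || med <= 0) med <- 1
  med * mul^(seq_len(n_kernels) - 1L - (n_kernels - 1L) / 2)
}

# value and gradient of the biased multi-kernel MMD^2 at fixed bandwidths
mmd_value_grad <- function(Gs, Gt, bandwidths) {
  ms <- nrow(Gs); mt <- nrow(Gt)
  X <- rbind(Gs, Gt)
  d2 <- pairwise_sqdist(X)
  m <- ms + mt
  is <- seq_len(ms); it <- ms + seq_len(mt)
  K <- matrix(0, m, m); Kw <- matrix(0, m, m)
  for (b in bandwidths) {
    Kb <- exp(-d2 / b)
    K <- K + Kb
    Kw <- Kw + Kb / b
  }
  val <- mean(K[is, is]) + mean(K[it, it]) - 2 * mean(K[is, it, drop = FALSE])
  C <- matrix(0, m, m)
  C[is, is] <- 1 / ms^2
  C[it, it] <- 1 / mt^2
  C[is, it] <- -1 / (ms * mt)
  C[it, is] <- -1 / (ms * mt)
  W <- C * Kw   # symmetric
  # dval/dx_i = sum_j 2*W_ij * (-2)(x_i - x_j) = -4 (rowSums(W) x_i - W X)
  gX <- -4 * (rowSums(W) * X - W %*% X)
  list(value = val, s = gX[is, , drop = FALSE], t = gX[it, , drop = FALSE])
}

# --- Adam ---------------------------------------------------------------

adam_init <- function() list(m = list(), v = list(), t = list())

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
      state$t[[nm]] <- 0L
    }
    state$t[[nm]] <- state$t[[nm]] + 1L
    t <- state$t[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- epoch batching ------------------------------------------------------

# Split 1..n into chunks of `size`; a trailing chunk of 1 is merged into
# the previous one so per-chunk covariances stay defined.
chunk_positions <- function(n, size) {
  ch <- split(seq_len(n), ceiling(seq_len(n) / size))
  k <- length(ch)
  if (k > 1L && length(ch[[k]]) < 2L) {
    ch[[k - 1L]] <- c(ch[[k - 1L]], ch[[k]])
    ch[[k]] <- NULL
  }
  unname(ch)
}

# Per-epoch subject orders for the two domains: each is permuted, and the
# smaller domain is resampled with replacement up to the larger size, so
# position-wise pairing is a fresh random pairing every epoch.
epoch_orders <- function(Ms, Mt) {
  n <- max(Ms, Mt)
  os <- if (Ms == n) sample.int(Ms) else sample.int(Ms, n, replace = TRUE)
  ot <- if (Mt == n) sample.int(Mt) else sample.int(Mt, n, replace = TRUE)
  list(s = os, t = ot, n = n)
}

# --- training loop -------------------------------------------------------

# Stage weights: list(ce, mae, coral, mmd, dann).
engine_train <- function(prep_s, labels_s, prep_t, params, config,
                         stages, adam = adam_init(), epoch_offset = 0L,
                         total_steps_all = NULL) {
  history <- list()
  d2 <- config$gcn_dims[2L]
  denom <- if (config$coral_denom == "feature_dim") 2L * d2 else d2
  use_target <- !is.null(prep_t)
  global_step <- 0L
  if (is.null(total_steps_all)) {
    n_per_epoch <- if (use_target) max(prep_s$M, prep_t$M) else prep_s$M
    total_epochs <- sum(vapply(stages, `[[`, integer(1L), "epochs"))
    total_steps_all <- max(1L, total_epochs *
                             length(chunk_positions(n_per_epoch,
                                                    config$batch_size)))
  }

  for (stage in stages) {
    w <- stage$w
    for (ep in seq_len(stage$epochs)) {
      acc <- c(lc = 0, lm = 0, la = 0, lmmd = 0, ld = 0, loss = 0)
      if (use_target) {
        ords <- epoch_orders(prep_s$M, prep_t$M)
        chunks <- chunk_positions(ords$n, config$batch_size)
      } else {
        ords <- list(s = sample.int(prep_s$M))
        chunks <- chunk_positions(prep_s$M, config$batch_size)
      }
      for (pos in chunks) {
        global_step <- global_step + 1L
        idx_s <- ords$s[pos]
        bs <- length(idx_s)
        with_cls <- w$ce > 0 || w$dann > 0
        fs <- engine_forward(prep_s, idx_s, params,
                             use_attention = config$use_attention,
                             training = TRUE, dropout = config$dropout,
                             with_classifier = with_cls)
        ft <- NULL
        if (use_target) {
          idx_t <- ords$t[pos]
          ft <- engine_forward(prep_t, idx_t, params,
                               use_attention = config$use_attention,
                               training = TRUE, dropout = config$dropout,
                               with_classifier = FALSE)
        }

        dlogits_s <- NULL
        dZ_s <- NULL; dZ_t <- NULL
        dG_s <- NULL; dG_t <- NULL
        lc <- 0; lm <- 0; la <- 0; lmmd <- 0; ld <- 0

        if (w$ce > 0) {
          yb <- labels_s[idx_s]
          lc <- cross_entropy_loss(fs$prob, yb)
          dlogits_s <- w$ce * ce_grad(fs$prob, yb)
        }
        if (use_target && w$mae > 0) {
          lm <- mean(abs(fs$Z - ft$Z))
          g <- mae_grad_pair(fs$Z, ft$Z)
          dZ_s <- w$mae * g$s
          dZ_t <- w$mae * g$t
        }
        if (use_target && w$coral > 0) {
          la <- coral_loss(fs$G, ft$G, denom_dim = denom)
          g <- coral_grad_pair(fs$G, ft$G, denom)
          dG_s <- w$coral * g$s
          dG_t <- w$coral * g$t
        }
        if (use_target && w$mmd > 0) {
          bw <- mmd_bandwidths_of(fs$G, ft$G, config$mmd_bandwidths)
          g <- mmd_value_grad(fs$G, ft$G, bw)
          lmmd <- g$value
          dG_s <- add_or(dG_s, w$mmd * g$s)
          dG_t <- add_or(dG_t, w$mmd * g$t)
        }

        head_grads <- NULL
        if (use_target && w$dann > 0) {
          p <- (global_step - 1L) / total_steps_all
          lam <- dann_lambda(min(1, p))
          Gall <- rbind(fs$G, ft$G)
          dom <- c(rep(0L, bs), rep(1L, nrow(ft$G)))
          hd <- domain_head_forward(Gall, params, training = TRUE,
                                    dropout = config$dropout)
          ld <- cross_entropy_loss(hd$prob, dom)
          dl <- w$dann * ce_grad(hd$prob, dom)
          hb <- domain_head_backward(hd, Gall, params, dl)
          head_grads <- hb$grads
          # gradient reversal into the feature extractor
          dG_dom <- grl_backward(hb$dG, lam)
          dG_s <- add_or(dG_s, dG_dom[seq_len(bs), , drop = FALSE])
          dG_t <- add_or(dG_t, dG_dom[bs + seq_len(nrow(ft$G)), ,
                                      drop = FALSE])
        }

        grads <- engine_backward(fs, prep_s, params,
                                 list(dlogits = dlogits_s, dG = dG_s,
                                      dZ = dZ_s))
        if (use_target && (!is.null(dG_t) || !is.null(dZ_t))) {
          gt <- engine_backward(ft, prep_t, params,
                                list(dlogits = NULL, dG = dG_t, dZ = dZ_t))
          for (nm in names(gt))
            grads[[nm]] <- if (is.null(grads[[nm]])) gt[[nm]]
                           else grads[[nm]] + gt[[nm]]
        }
        if (!is.null(head_grads)) grads <- c(grads, head_grads)

        upd <- adam_update(params, grads, adam, config$lr)
        params <- upd$params
        adam <- upd$state

        tot <- w$ce * lc + w$mae * lm + w$coral * la + w$mmd * lmmd +
          w$dann * ld
        acc <- acc + c(lc, lm, la, lmmd, ld, tot)
      }
      nsteps <- length(chunks)
      history[[length(history) + 1L]] <-
        data.frame(epoch = epoch_offset + length(history) + 0L + 1L,
                   stage = stage$name,
                   lc = acc[["lc"]] / nsteps, lm = acc[["lm"]] / nsteps,
                   la = acc[["la"]] / nsteps, lmmd = acc[["lmmd"]] / nsteps,
                   ld = acc[["ld"]] / nsteps, loss = acc[["loss"]] / nsteps)
    }
  }
  list(params = params, adam = adam,
       history = do.call(rbind, history))
}

add_or <- function(a, b) if (is.null(a)) b else a + b

domain_head_forward <- function(G, params, training = FALSE, dropout = 0) {
  F1pre <- sweep(G %*% params$Wd1, 2L, params$bd1, "+")
  F1 <- relu(F1pre)
  mask <- NULL
  if (training && dropout > 0) {
    mask <- matrix((stats::runif(length(F1)) >= dropout) / (1 - dropout),
                   nrow(F1), ncol(F1))
    F1 <- F1 * mask
  }
  logits <- sweep(F1 %*% params$Wd2, 2L, params$bd2, "+")
  list(F1pre = F1pre, F1d = F1, mask = mask, logits = logits,
       prob = softmax_rows(logits))
}

domain_head_backward <- function(cache, G, params, dlogits) {
  grads <- list(Wd2 = crossprod(cache$F1d, dlogits),
                bd2 = colSums(dlogits))
  dF1d <- dlogits %*% t(params$Wd2)
  dF1 <- if (is.null(cache$mask)) dF1d else dF1d * cache$mask
  dF1pre <- dF1 * (cache$F1pre > 0)
  grads$Wd1 <- crossprod(G, dF1pre)
  grads$bd1 <- colSums(dF1pre)
  list(grads = grads, dG = dF1pre %*% t(params$Wd1))
}

# Eval-mode forward over all subjects of a prepared set.
engine_predict <- function(prep, params, config) {
  f <- engine_forward(prep, seq_len(prep$M), params,
                      use_attention = config$use_attention,
                      training = FALSE, dropout = 0,
                      with_classifier = TRUE)
  att <- if (config$use_attention) f$Att else NULL
  list(prob = f$prob, logits = f$logits, G = f$G, Z = f$Z, H = f$H2,
       attention = att)
}
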