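#' Node centrality features of a connectivity graph
#'
#' Classical hand-crafted features: weighted degree (DC), betweenness (BC)
#' and closeness (CC) centrality of every node, concatenated in the order
#' DC, BC, CC.  Centralities are computed on the absolute edge weights;
#' betweenness and closeness need edge lengths, for which each edge gets
#' length \eqn{1 - |w|} clipped to \eqn{[10^{-6}, 1]} (strong connections =
#' short paths).  Degree excludes the unit self-loop.
#'
#' @param graph a `brain_graph`.
#' @param kinds subset of `c("DC", "BC", "CC")`.
#' @return numeric vector of length `N * length(kinds)`.
#' @export
centrality_features <- function(graph, kinds = c("DC", "BC", "CC")) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  A <- abs(graph$adjacency)
  diag(A) <- 0
  out <- numeric(0)
  if ("DC" %in% kinds) out <- c(out, rowSums(A))
  if (any(c("BC", "CC") %in% kinds)) {
    len <- 1 - A
    len[len < 1e-6] <- 1e-6
    len[len > 1] <- 1
    diag(len) <- 0
    g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    if ("BC" %in% kinds)
      out <- c(out, igraph::betweenness(g, weights = igraph::E(g)$weight,
                                        directed = FALSE))
    if ("CC" %in% kinds)
      out <- c(out, igraph::closeness(g, weights = igraph::E(g)$weight,
                                      normalized = FALSE))
  }
  unname(out)
}

#' Linear SVM trained on source features, applied to target features
#'
#' @param features_s,features_t M x d feature matrices.
#' @param labels_s 0/1 source labels (both classes required).
#' @param cost SVM regularization constant.
#' @return list with `pred` (0/1 target predictions), `score` (decision
#'   values oriented so that larger means class 1) and the fitted `svm`.
#' @export
svm_baseline <- function(features_s, labels_s, features_t, cost = 1) {
  labels_s <- as.integer(labels_s)
  if (length(unique(labels_s)) < 2L)
    stop("source labels contain a single class")
  fit <- e1071::svm(x = as.matrix(features_s),
                    y = factor(labels_s, levels = c(0L, 1L)),
                    kernel = "linear", cost = cost, scale = FALSE)
  pr <- stats::predict(fit, as.matrix(features_t), decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient the decision value toward class "1"
  first <- strsplit(colnames(dv)[1L], "/")[[1L]][1L]
  score <- if (identical(first, "1")) dv[, 1L] else -dv[, 1L]
  list(pred = as.integer(as.character(pr)), score = as.numeric(score),
       svm = fit)
}

#' Strict upper-triangle vectorization of a connectivity graph
#'
#' The constant unit diagonal is uninformative and excluded; for N ROIs
#' the vector has length N(N-1)/2.
#'
#' @param graph a `brain_graph` (or plain square matrix).
#' @return numeric vector.
#' @export
vectorize_graph <- function(graph) {
  upper_tri_vec(graph)
}

graphs_to_pca_features <- function(graphs_s, graphs_t, n_components = 64L) {
  Fs <- t(vapply(graphs_s, upper_tri_vec,
                 numeric(n_upper(graphs_s[[1L]]$n_rois))))
  Ft <- t(vapply(graphs_t, upper_tri_vec,
                 numeric(n_upper(graphs_t[[1L]]$n_rois))))
  X <- rbind(Fs, Ft)
  k <- min(n_components, ncol(X), nrow(X) - 1L)
  if (k < n_components)
    warning(sprintf("reducing PCA components from %d to %d (few subjects)",
                    n_components, k))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  list(s = pc$x[seq_len(nrow(Fs)), , drop = FALSE],
       t = pc$x[nrow(Fs) + seq_len(nrow(Ft)), , drop = FALSE],
       pca = pc)
}

# Minimal MLP (input -> hidden -> 2) trained with Adam on source cross
# entropy, optionally with a CORAL penalty between the source and target
# hidden activations (the DNNC construction).  Manual backprop; seeded.
mlp_train <- function(Xs, ys, Xt = NULL, hidden = 16L, coral_weight = 0,
                      epochs = 150L, lr = 1e-4, batch_size = 16L,
                      dropout = 0.4) {
  d <- ncol(Xs)
  params <- list(W1 = glorot_uniform(d, hidden), b1 = numeric(hidden),
                 W2 = glorot_uniform(hidden, 2L), b2 = numeric(2L))
  adam <- adam_init()
  use_t <- !is.null(Xt) && coral_weight > 0
  fwd <- function(X, training) {
    F1pre <- sweep(X %*% params$W1, 2L, params$b1, "+")
    F1 <- relu(F1pre)
    mask <- NULL
    if (training && dropout > 0) {
      mask <- matrix((stats::runif(length(F1)) >= dropout) / (1 - dropout),
                     nrow(F1), ncol(F1))
    }
    F1d <- if (is.null(mask)) F1 else F1 * mask
    logits <- sweep(F1d %*% params$W2, 2L, params$b2, "+")
    list(F1pre = F1pre, F1 = F1, F1d = F1d, mask = mask,
         logits = logits, prob = softmax_rows(logits))
  }
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    if (use_t) {
      ords <- epoch_orders(nrow(Xs), nrow(Xt))
      chunks <- chunk_positions(ords$n, batch_size)
    } else {
      ords <- list(s = sample.int(nrow(Xs)))
      chunks <- chunk_positions(nrow(Xs), batch_size)
    }
    tot <- 0
    for (pos in chunks) {
      is <- ords$s[pos]
      Xb <- Xs[is, , drop = FALSE]; yb <- ys[is]
      fs <- fwd(Xb, training = TRUE)
      lc <- cross_entropy_loss(fs$prob, yb)
      dlogits <- ce_grad(fs$prob, yb)
      grads <- list(W2 = crossprod(fs$F1d, dlogits),
                    b2 = colSums(dlogits))
      dF1d <- dlogits %*% t(params$W2)
      dF1 <- if (is.null(fs$mask)) dF1d else dF1d * fs$mask
      la <- 0
      if (use_t) {
        it <- ords$t[pos]
        Xtb <- Xt[it, , drop = FALSE]
        ft <- fwd(Xtb, training = TRUE)
        la <- coral_loss(fs$F1, ft$F1, denom_dim = hidden)
        g <- coral_grad_pair(fs$F1, ft$F1, hidden)
        dF1 <- dF1 + coral_weight * g$s
        dF1pre_t <- (coral_weight * g$t) * (ft$F1pre > 0)
        grads$W1 <- crossprod(Xtb, dF1pre_t)
        grads$b1 <- colSums(dF1pre_t)
      }
      dF1pre <- dF1 * (fs$F1pre > 0)
      grads$W1 <- add_or(grads$W1, 0) + crossprod(Xb, dF1pre)
      grads$b1 <- add_or(grads$b1, 0) + colSums(dF1pre)
      upd <- adam_update(params, grads, adam, lr)
      params <- upd$params; adam <- upd$state
      tot <- tot + lc + coral_weight * la
    }
    history[ep] <- tot / length(chunks)
  }
  predict_fun <- function(X) {
    f <- fwd(X, training = FALSE)
    f$prob
  }
  list(params = params, history = history, predict_prob = predict_fun)
}

#' Fit one of the competing baseline methods
#'
#' Eight baselines behind one interface, all consuming the same cohort and
#' emitting the same prediction schema:
#' * `"dc"`, `"bd"`, `"bdc"` — node centralities (degree; + betweenness;
#'   + closeness) fed to a linear SVM trained on the source site;
#' * `"dnn"` — strict upper-triangle vectorization, PCA to 64 components
#'   (fit on source and target jointly), then a 64→16→2 network trained on
#'   source cross entropy;
#' * `"gcn"` — the graph convolutional backbone and classifier without
#'   attention and without any alignment loss;
#' * `"dnnc"` — the DNN input pipeline with a 64→32→2 network plus a CORAL
#'   penalty between source and target hidden features;
#' * `"mmd"` — the full attention architecture with both discrepancy
#'   losses replaced by a multi-kernel maximum mean discrepancy;
#' * `"dann"` — the attention architecture trained adversarially with a
#'   domain classifier behind a gradient reversal layer.
#'
#' @param method one of `"dc"`, `"bd"`, `"bdc"`, `"dnn"`, `"gcn"`,
#'   `"dnnc"`, `"mmd"`, `"dann"`.
#' @inheritParams a2gcn
#' @return an object of class `fcn_baseline`: list with `method`, `pred`
#'   (0/1 target predictions), `score` (class-1 score used for AUC) and
#'   the underlying fit.
#' @export
fit_baseline <- function(method, graphs_source, labels_source = NULL,
                         graphs_target = NULL, config = a2gcn_config(),
                         seed = config$seed) {
  method <- match.arg(tolower(method),
                      c("dc", "bd", "bdc", "dnn", "gcn", "dnnc", "mmd",
                        "dann"))
  if (inherits(graphs_source, "cohort")) {
    cohort <- graphs_source
    graphs_target <- cohort$graphs_target
    labels_source <- cohort$labels_source
    graphs_source <- cohort$graphs_source
  }
  labels_source <- as.integer(labels_source)
  total_epochs <- config$epochs_pretrain + config$epochs_joint

  if (method %in% c("dc", "bd", "bdc")) {
    kinds <- switch(method, dc = "DC", bd = c("DC", "BC"),
                    bdc = c("DC", "BC", "CC"))
    len <- graphs_source[[1L]]$n_rois * length(kinds)
    Fs <- t(vapply(graphs_source, centrality_features, numeric(len),
                   kinds = kinds))
    Ft <- t(vapply(graphs_target, centrality_features, numeric(len),
                   kinds = kinds))
    set.seed(seed)
    sv <- svm_baseline(Fs, labels_source, Ft)
    out <- list(method = method, pred = sv$pred, score = sv$score,
                fit = sv$svm, kinds = kinds)
  } else if (method %in% c("dnn", "dnnc")) {
    set.seed(seed)
    feats <- graphs_to_pca_features(graphs_source, graphs_target)
    net <- if (method == "dnn")
      mlp_train(feats$s, labels_source, hidden = 16L,
                epochs = total_epochs, lr = config$lr,
                batch_size = config$batch_size, dropout = config$dropout)
    else
      mlp_train(feats$s, labels_source, feats$t, hidden = 32L,
                coral_weight = 0.5, epochs = total_epochs, lr = config$lr,
                batch_size = config$batch_size, dropout = config$dropout)
    prob <- net$predict_prob(feats$t)
    out <- list(method = method, pred = as.integer(prob[, 2L] > 0.5),
                score = prob[, 2L], prob = prob, fit = net, pca = feats$pca)
  } else {
    cfg <- config
    if (method == "gcn") {
      cfg$use_attention <- FALSE; cfg$use_mae <- FALSE
      cfg$use_coral <- FALSE; cfg$align_loss <- "mae_coral"
    } else if (method == "mmd") {
      cfg$align_loss <- "mmd"
    } else if (method == "dann") {
      cfg$align_loss <- "dann"
    }
    fit <- a2gcn(graphs_source, labels_source, graphs_target, cfg,
                 seed = seed)
    prob <- fit$target$prob
    out <- list(method = method, pred = as.integer(prob[, 2L] > 0.5),
                score = prob[, 2L], prob = prob, fit = fit)
  }
  class(out) <- "fcn_baseline"
  out
}

#' @export
print.fcn_baseline <- function(x, ...) {
  cat(sprintf("<fcn_baseline> method=%s  target subjects=%d\n",
              x$method, length(x$pred)))
  invisible(x)
}

#' Fit an ablation variant of the full model
#'
#' Three reduced models isolate the contribution of the attention and
#' alignment modules:
#' * `"a2gcn_a"` — attention but no domain adaptation (source-only
#'   training, cross entropy alone);
#' * `"a2gcn_m"` — attention plus the MAE alignment term only;
#' * `"a2gcn_c"` — no attention, CORAL alignment on the readout only.
#'
#' @param variant one of `"a2gcn_a"`, `"a2gcn_m"`, `"a2gcn_c"`.
#' @inheritParams a2gcn
#' @return a fitted `a2gcn` object.
#' @export
fit_ablation <- function(variant, graphs_source, labels_source = NULL,
                         graphs_target = NULL, config = a2gcn_config(),
                         seed = config$seed) {
  variant <- match.arg(tolower(variant),
                       c("a2gcn_a", "a2gcn_m", "a2gcn_c"))
  cfg <- config
  cfg$align_loss <- "mae_coral"
  if (variant == "a2gcn_a") {
    cfg$use_attention <- TRUE; cfg$use_mae <- FALSE; cfg$use_coral <- FALSE
  } else if (variant == "a2gcn_m") {
    cfg$use_attention <- TRUE; cfg$use_mae <- TRUE; cfg$use_coral <- FALSE
  } else {
    cfg$use_attention <- FALSE; cfg$use_mae <- FALSE; cfg$use_coral <- TRUE
  }
  a2gcn(graphs_source, labels_source, graphs_target, cfg, seed = seed)
}
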