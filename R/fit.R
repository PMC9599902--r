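#' Fit the attention GCN with unsupervised domain adaptation
#'
#' Trains the model on a labeled source cohort and an unlabeled target
#' cohort of connectivity graphs.  Training is staged: first the node
#' representation and attention modules are pretrained on the alignment
#' losses alone (MAE between reweighted node embeddings and CORAL between
#' readout covariances, \eqn{\gamma_1=\gamma_2=1}, classification loss
#' off), then all modules including the classifier head are trained jointly
#' (\eqn{L = L_C + \gamma_1 L_M + \gamma_2 L_A} with
#' \eqn{\gamma_1=\gamma_2=0.5}).  Target labels are never an input:
#' the unsupervised setting is enforced by the interface.
#'
#' When every alignment weight is zero (or `use_mae = use_coral = FALSE`)
#' the pretraining stage is skipped — it would minimize a constant — and
#' the model trains on cross entropy alone for the full epoch budget, which
#' is exactly the plain-GCN baseline when the attention module is also
#' disabled.
#'
#' @param graphs_source list of `brain_graph` for the labeled site, or a
#'   `cohort` object (then the remaining data arguments are taken from it).
#' @param labels_source integer 0/1 vector, one per source graph.
#' @param graphs_target list of `brain_graph` for the unlabeled site.
#' @param config an [a2gcn_config()].
#' @param seed integer seed controlling initialization, batch shuffling and
#'   dropout (default `config$seed`).
#' @return an object of class `a2gcn` with components `params`, `config`,
#'   `history` (per-epoch loss table), `target` (eval-mode predictions,
#'   readouts and attention for the target cohort), `source` (likewise for
#'   the source cohort), `cf_pre`/`cf_post` (covariance-Frobenius site
#'   shift, measured before adaptation on the PCA-reduced input
#'   representation of the flattened connectivity matrices and after
#'   training on the learned readout representations) and `seed`.
#' @seealso [predict.a2gcn()], [fit_baseline()], [run_experiment()]
#' @export
a2gcn <- function(graphs_source, labels_source = NULL, graphs_target = NULL,
                  config = a2gcn_config(), seed = config$seed) {
  if (inherits(graphs_source, "cohort")) {
    cohort <- graphs_source
    graphs_target <- cohort$graphs_target
    labels_source <- cohort$labels_source
    graphs_source <- cohort$graphs_source
  }
  stopifnot(is.list(graphs_source), length(graphs_source) >= 2L)
  labels_source <- as.integer(labels_source)
  if (length(labels_source) != length(graphs_source))
    stop("one label per source graph required")
  if (!all(labels_source %in% c(0L, 1L))) stop("labels must be 0/1")

  align <- config$align_loss
  use_target <- !is.null(graphs_target) && length(graphs_target) > 0L
  mae_on <- config$use_mae &&
    (config$gamma1 > 0 || config$gamma1_pretrain > 0)
  coral_on <- config$use_coral &&
    (config$gamma2 > 0 || config$gamma2_pretrain > 0)
  has_align <- use_target && (
    (align == "mae_coral" && (mae_on || coral_on)) ||
      align %in% c("mmd", "dann"))
  if (use_target && length(graphs_target) < 2L)
    stop("need at least 2 target subjects")

  set.seed(seed)
  prep_s <- engine_prepare(graphs_source, config$norm_mode)
  prep_t <- if (use_target) engine_prepare(graphs_target, config$norm_mode)
            else NULL
  if (!is.null(config$n_rois) && prep_s$N != config$n_rois)
    stop(sprintf("expected %d ROIs, data has %d", config$n_rois, prep_s$N))
  params <- init_a2gcn_params(prep_s$N, config, dann = align == "dann")

  stages <- build_stages(config, has_align, align)

  # pre-adaptation site shift, measured on the model-free input
  # representation: PCA of the vectorized upper-triangle connectivity,
  # fitted on both domains jointly (transductive)
  cf_pre <- if (use_target)
    cf_input_representation(graphs_source, graphs_target) else NA_real_

  fitted <- engine_train(prep_s, labels_source,
                         if (has_align) prep_t else NULL,
                         params, config, stages)
  params <- fitted$params

  src_out <- engine_predict(prep_s, params, config)
  tgt_out <- if (use_target) engine_predict(prep_t, params, config) else NULL
  cf_post <- if (use_target) cf_statistic(src_out$G, tgt_out$G) else NA_real_

  structure(list(
    params = params, config = config, seed = seed,
    history = fitted$history,
    n_rois = prep_s$N,
    roi_names = graphs_source[[1L]]$roi_names,
    labels_source = labels_source,
    source = list(subject_ids = prep_s$subject_ids, prob = src_out$prob,
                  G = src_out$G, attention = src_out$attention),
    target = if (use_target)
      list(subject_ids = prep_t$subject_ids, prob = tgt_out$prob,
           G = tgt_out$G, attention = tgt_out$attention) else NULL,
    cf_pre = cf_pre, cf_post = cf_post),
    class = "a2gcn")
}

build_stages <- function(config, has_align, align) {
  zero_w <- list(ce = 0, mae = 0, coral = 0, mmd = 0, dann = 0)
  if (!has_align) {
    w <- zero_w; w$ce <- 1
    return(list(list(name = "joint", w = w,
                     epochs = config$epochs_pretrain + config$epochs_joint)))
  }
  if (align == "dann") {
    w <- zero_w; w$ce <- 1; w$dann <- config$dann_gamma
    return(list(list(name = "adversarial", w = w,
                     epochs = config$epochs_pretrain + config$epochs_joint)))
  }
  if (align == "mmd") {
    w1 <- zero_w; w1$mmd <- 1
    w2 <- zero_w; w2$ce <- 1; w2$mmd <- 0.5
  } else {
    w1 <- zero_w
    w1$mae <- if (config$use_mae) config$gamma1_pretrain else 0
    w1$coral <- if (config$use_coral) config$gamma2_pretrain else 0
    w2 <- zero_w; w2$ce <- 1
    w2$mae <- if (config$use_mae) config$gamma1 else 0
    w2$coral <- if (config$use_coral) config$gamma2 else 0
  }
  stages <- list()
  if (config$epochs_pretrain > 0L && (w1$mae > 0 || w1$coral > 0 ||
                                      w1$mmd > 0))
    stages <- c(stages, list(list(name = "pretrain", w = w1,
                                  epochs = config$epochs_pretrain)))
  c(stages, list(list(name = "joint", w = w2,
                      epochs = config$epochs_joint)))
}

cf_statistic <- function(Fs, Ft) {
  sqrt(sum((feature_covariance(Fs) - feature_covariance(Ft))^2))
}

cf_input_representation <- function(graphs_s, graphs_t,
                                    n_components = 64L) {
  # rank is silently capped for small cohorts: the statistic is still
  # well defined on however many components the data support
  feats <- suppressWarnings(
    graphs_to_pca_features(graphs_s, graphs_t, n_components))
  cf_statistic(feats$s, feats$t)
}

#' @export
print.a2gcn <- function(x, ...) {
  cat("Attention GCN with domain adaptation\n")
  cat(sprintf("  ROIs: %d   source subjects: %d   target subjects: %s\n",
              x$n_rois, length(x$labels_source),
              if (is.null(x$target)) "none"
              else length(x$target$subject_ids)))
  cat(sprintf("  epochs: %d (final loss %.4f)   seed: %d\n",
              nrow(x$history), x$history$loss[nrow(x$history)], x$seed))
  if (!is.na(x$cf_pre))
    cat(sprintf("  site shift (CF): %.4f (input) -> %.4f (readout)\n",
                x$cf_pre, x$cf_post))
  invisible(x)
}

#' @export
summary.a2gcn <- function(object, ...) {
  h <- object$history
  out <- list(
    n_rois = object$n_rois,
    n_source = length(object$labels_source),
    n_target = if (is.null(object$target)) 0L
               else length(object$target$subject_ids),
    stages = table(h$stage),
    final_losses = h[nrow(h), c("lc", "lm", "la", "loss")],
    cf_pre = object$cf_pre, cf_post = object$cf_post,
    config = object$config)
  class(out) <- "summary.a2gcn"
  out
}

#' @export
print.summary.a2gcn <- function(x, ...) {
  cat("Attention GCN with domain adaptation — fit summary\n")
  cat(sprintf("  %d ROIs, %d labeled source + %d unlabeled target subjects\n",
              x$n_rois, x$n_source, x$n_target))
  cat("  epochs per stage: ",
      paste(sprintf("%s=%d", names(x$stages), x$stages), collapse = ", "),
      "\n", sep = "")
  fl <- x$final_losses
  cat(sprintf("  final losses: LC=%.4f LM=%.4f LA=%.4f total=%.4f\n",
              fl$lc, fl$lm, fl$la, fl$loss))
  if (!is.na(x$cf_pre))
    cat(sprintf("  covariance-Frobenius site shift: %.4f before, %.4f after\n",
                x$cf_pre, x$cf_post))
  invisible(x)
}

#' @export
coef.a2gcn <- function(object, ...) object$params

#' Predict on new connectivity graphs
#'
#' Runs the fitted model in evaluation mode (dropout off, deterministic).
#'
#' @param object a fitted [a2gcn()] model.
#' @param graphs list of `brain_graph` (default: the stored target cohort
#'   predictions are returned without recomputation).
#' @param type `"prob"` (matrix of class probabilities), `"class"` (0/1
#'   labels), `"readout"` (graph-level representations), or `"attention"`
#'   (per-subject ROI attention scores).
#' @param ... unused.
#' @export
predict.a2gcn <- function(object, graphs = NULL,
                          type = c("prob", "class", "readout", "attention"),
                          ...) {
  type <- match.arg(type)
  if (is.null(graphs)) {
    if (is.null(object$target)) stop("no target cohort stored; pass graphs")
    out <- object$target
  } else {
    prep <- engine_prepare(graphs, object$config$norm_mode)
    if (prep$N != object$n_rois)
      stop(sprintf("model fitted with %d ROIs, graphs have %d",
                   object$n_rois, prep$N))
    p <- engine_predict(prep, object$params, object$config)
    out <- list(prob = p$prob, G = p$G, attention = p$attention)
  }
  switch(type,
         prob = out$prob,
         class = as.integer(out$prob[, 2L] > out$prob[, 1L]),
         readout = out$G,
         attention = out$attention)
}

#' Plot training loss trajectories
#'
#' One line per loss component over epochs; the vertical line marks the
#' transition from alignment-only pretraining to joint training.
#'
#' @param x a fitted [a2gcn()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.a2gcn <- function(x, ...) {
  h <- x$history
  comp <- c("lc", "lm", "la", "loss")
  keep <- vapply(comp, function(cc) any(h[[cc]] != 0), logical(1L))
  comp <- comp[keep]
  graphics::matplot(h$epoch, as.matrix(h[comp]), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss", ...)
  if (any(h$stage == "pretrain"))
    graphics::abline(v = max(h$epoch[h$stage == "pretrain"]) + 0.5,
                     lty = 2, col = "grey50")
  graphics::legend("topright", legend = toupper(comp), lty = 1,
                   col = seq_along(comp), bty = "n")
  invisible(x)
}
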