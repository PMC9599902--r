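#' Confusion counts from predicted and true labels
#'
#' The positive class is the patient class, label 1.
#'
#' @param predicted,truth 0/1 integer vectors.
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (!all(c(predicted, truth) %in% c(0L, 1L))) stop("labels must be 0/1")
  list(TP = sum(predicted == 1L & truth == 1L),
       TN = sum(predicted == 0L & truth == 0L),
       FP = sum(predicted == 1L & truth == 0L),
       FN = sum(predicted == 0L & truth == 1L))
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall, F1, balanced accuracy and negative
#' predictive value with the patient class (label 1) as positive:
#' ACC=(TP+TN)/total, Pre=TP/(TP+FP), Rec=TP/(TP+FN), NPV=TN/(TN+FN),
#' BAC=TP/(2(TP+FN))+TN/(2(TN+FP)) i.e. the mean of sensitivity and
#' specificity, F1=2·Pre·Rec/(Pre+Rec).  A metric whose denominator is zero
#' is undefined and reported as `NA` rather than coerced to 0.
#'
#' @param counts list with `TP`, `TN`, `FP`, `FN` (see [confusion_counts()]).
#' @return named numeric vector `ACC`, `Pre`, `Rec`, `F1`, `BAC`, `NPV`.
#' @examples
#' compute_metrics(list(TP = 3, FP = 1, FN = 1, TN = 5))
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop("counts must be non-negative")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- frac(TP + TN, TP + TN + FP + FN)
  pre <- frac(TP, TP + FP)
  rec <- frac(TP, TP + FN)
  spec <- frac(TN, TN + FP)
  npv <- frac(TN, TN + FN)
  bac <- if (is.na(rec) || is.na(spec)) NA_real_ else (rec + spec) / 2
  f1 <- if (is.na(pre) || is.na(rec) || (pre + rec) == 0) NA_real_
        else 2 * pre * rec / (pre + rec)
  c(ACC = acc, Pre = pre, Rec = rec, F1 = f1, BAC = bac, NPV = npv)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann–Whitney) estimate with midrank tie correction: the
#' probability that a random positive scores higher than a random negative,
#' counting ties as one half.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 integer vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Full metric report for a set of scored subjects
#'
#' @param prob probability of class 1 per subject (or M x 2 matrix).
#' @param truth 0/1 labels.
#' @return named vector `ACC`, `Pre`, `Rec`, `F1`, `BAC`, `NPV`, `AUC`.
#' @export
metric_report <- function(prob, truth) {
  if (is.matrix(prob)) prob <- prob[, 2L]
  predicted <- as.integer(prob > 0.5)
  m <- compute_metrics(confusion_counts(predicted, truth))
  auc <- tryCatch(auc_score(prob, truth), error = function(e) NA_real_)
  c(m, AUC = auc)
}

#' Rank ROIs by mean attention
#'
#' Averages the per-subject attention scores of each ROI over the supplied
#' subjects and returns the `top_k` regions in descending order of mean
#' attention (ties broken by ROI index).
#'
#' @param attention M x N matrix of per-subject attention scores (e.g.
#'   `predict(fit, type = "attention")`), or a length-N vector.
#' @param roi_names optional length-N character vector.
#' @param top_k number of regions to return.
#' @return data frame with `rank`, `roi`, `roi_index`, `mean_attention`.
#' @export
rank_rois <- function(attention, roi_names = NULL, top_k = 19L) {
  if (is.vector(attention)) attention <- matrix(attention, nrow = 1L)
  n <- ncol(attention)
  if (top_k > n) stop("top_k exceeds the number of ROIs")
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n))
  if (length(roi_names) != n) stop("roi_names length mismatch")
  mu <- colMeans(attention)
  ord <- order(-mu, seq_len(n))
  sel <- ord[seq_len(top_k)]
  data.frame(rank = seq_len(top_k), roi = roi_names[sel],
             roi_index = sel, mean_attention = mu[sel],
             row.names = NULL)
}

#' Covariance-Frobenius site-shift statistic
#'
#' Measures residual distribution shift between two domains as the
#' Frobenius norm of the difference of their feature covariance matrices.
#' Given a `cohort`, the features are the vectorized strict upper triangles
#' of each subject's connectivity matrix; given two feature matrices
#' (subjects in rows), the statistic is computed on them directly — e.g. on
#' learned readout representations before and after adaptation.
#'
#' @param x a `cohort`, or an M_s x d source feature matrix.
#' @param y ignored for a cohort; otherwise the M_t x d target features.
#' @return non-negative scalar, symmetric in the two domains.
#' @export
shift_severity <- function(x, y = NULL) {
  if (inherits(x, "cohort")) {
    Fs <- t(vapply(x$graphs_source, upper_tri_vec,
                   numeric(n_upper(x$graphs_source[[1L]]$n_rois))))
    Ft <- t(vapply(x$graphs_target, upper_tri_vec,
                   numeric(n_upper(x$graphs_target[[1L]]$n_rois))))
  } else {
    Fs <- as.matrix(x); Ft <- as.matrix(y)
  }
  if (nrow(Fs) < 2L || nrow(Ft) < 2L)
    stop("need at least 2 subjects per domain")
  cf_statistic(Fs, Ft)
}

n_upper <- function(n) n * (n - 1L) / 2L

upper_tri_vec <- function(graph) {
  A <- if (inherits(graph, "brain_graph")) graph$adjacency else graph
  A[upper.tri(A)]
}

#' Export per-subject embeddings with domain tags
#'
#' Collects the learned graph-level representations of both domains into a
#' long table for external distribution inspection (t-SNE, PCA, ...), along
#' with the covariance-Frobenius shift of the representations before and
#' after adaptation as attributes.
#'
#' @param fit a fitted [a2gcn()] model with a stored target cohort.
#' @param path optional TSV output path.
#' @return data frame with `subject_id`, `domain` and embedding columns
#'   `g1..g2D`; attributes `cf_pre` and `cf_post`.
#' @export
export_embeddings <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "a2gcn"))
  if (is.null(fit$target)) stop("fit has no target cohort")
  emb <- rbind(fit$source$G, fit$target$G)
  colnames(emb) <- paste0("g", seq_len(ncol(emb)))
  out <- data.frame(
    subject_id = c(fit$source$subject_ids, fit$target$subject_ids),
    domain = c(rep("source", nrow(fit$source$G)),
               rep("target", nrow(fit$target$G))),
    emb, check.names = FALSE)
  attr(out, "cf_pre") <- fit$cf_pre
  attr(out, "cf_post") <- fit$cf_post
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}
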