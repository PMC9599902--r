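#' Run configuration for model fitting
#'
#' Collects every tunable of the fitting pipeline with the published
#' defaults: two graph-convolution layers of width 32, a 64-wide fully
#' connected classifier head ending in 2 logits, dropout 0.4 on the head,
#' Adam with learning rate 1e-4, a 50-epoch alignment-only pretraining stage
#' (\eqn{\gamma_1=\gamma_2=1}, classification loss off) followed by 100
#' jointly trained epochs (\eqn{\gamma_1=\gamma_2=0.5}).
#'
#' @param gcn_dims output widths of the two graph-convolution layers.
#' @param fc_hidden width of the classifier's hidden fully connected layer.
#' @param dropout dropout rate on the classifier hidden layer, in \[0, 1).
#' @param lr Adam learning rate.
#' @param epochs_pretrain,epochs_joint epochs of the two training stages.
#' @param gamma1_pretrain,gamma2_pretrain alignment weights (MAE, CORAL)
#'   during pretraining.
#' @param gamma1,gamma2 alignment weights during joint training.
#' @param batch_size subjects per optimizer step and domain.  Each epoch
#'   visits every subject once in a seeded random order; the alignment
#'   losses are computed within each step's source/target pair of batches.
#' @param repeats number of repeated fits in [run_experiment()].
#' @param seed master seed; repeat r uses `seed + r - 1`.
#' @param norm_mode adjacency degree normalization: `"absolute"` uses
#'   \eqn{\tilde D_{ii} = \sum_j |A_{ij}|} (always positive for signed
#'   correlation graphs), `"raw"` uses plain row sums and errors if any is
#'   non-positive.
#' @param coral_denom CORAL scaling: `"feature_dim"` divides by
#'   \eqn{4 d^2} with `d` the length of the representation entering the
#'   loss (the concatenated readout, `2 * gcn_dims[2]`); `"node_dim"` uses
#'   the node feature width instead.
#' @param abs_adjacency build graphs from absolute correlations.
#' @param transpose time-series files are ROI x time.
#' @param use_attention include the node attention module.
#' @param use_mae,use_coral include the MAE / CORAL alignment terms.
#' @param align_loss `"mae_coral"` (default), or `"mmd"` to replace both
#'   discrepancy terms by a multi-kernel MMD on the readout vectors, or
#'   `"dann"` for an adversarial domain classifier through a gradient
#'   reversal layer.
#' @param mmd_bandwidths number of RBF bandwidths for the MMD loss.
#' @param dann_gamma weight of the adversarial domain loss.
#' @param n_rois expected ROI count (checked against the data when given).
#' @return a classed list of settings.
#' @export
a2gcn_config <- function(gcn_dims = c(32L, 32L),
                         fc_hidden = 64L,
                         dropout = 0.4,
                         lr = 1e-4,
                         epochs_pretrain = 50L,
                         epochs_joint = 100L,
                         gamma1_pretrain = 1,
                         gamma2_pretrain = 1,
                         gamma1 = 0.5,
                         gamma2 = 0.5,
                         batch_size = 16L,
                         repeats = 10L,
                         seed = 42L,
                         norm_mode = c("absolute", "raw"),
                         coral_denom = c("feature_dim", "node_dim"),
                         abs_adjacency = FALSE,
                         transpose = FALSE,
                         use_attention = TRUE,
                         use_mae = TRUE,
                         use_coral = TRUE,
                         align_loss = c("mae_coral", "mmd", "dann"),
                         mmd_bandwidths = 5L,
                         dann_gamma = 1,
                         n_rois = NULL) {
  norm_mode <- match.arg(norm_mode)
  coral_denom <- match.arg(coral_denom)
  align_loss <- match.arg(align_loss)
  stopifnot(length(gcn_dims) == 2L, all(gcn_dims >= 1L),
            fc_hidden >= 1L,
            dropout >= 0, dropout < 1,
            lr > 0,
            epochs_pretrain >= 0L, epochs_joint > 0L,
            gamma1 >= 0, gamma2 >= 0,
            gamma1_pretrain >= 0, gamma2_pretrain >= 0,
            batch_size >= 2L, repeats >= 1L)
  structure(list(gcn_dims = as.integer(gcn_dims),
                 fc_hidden = as.integer(fc_hidden),
                 dropout = dropout, lr = lr,
                 epochs_pretrain = as.integer(epochs_pretrain),
                 epochs_joint = as.integer(epochs_joint),
                 gamma1_pretrain = gamma1_pretrain,
                 gamma2_pretrain = gamma2_pretrain,
                 gamma1 = gamma1, gamma2 = gamma2,
                 batch_size = as.integer(batch_size),
                 repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 norm_mode = norm_mode, coral_denom = coral_denom,
                 abs_adjacency = abs_adjacency, transpose = transpose,
                 use_attention = use_attention,
                 use_mae = use_mae, use_coral = use_coral,
                 align_loss = align_loss,
                 mmd_bandwidths = as.integer(mmd_bandwidths),
                 dann_gamma = dann_gamma,
                 n_rois = if (is.null(n_rois)) NULL else as.integer(n_rois)),
            class = "a2gcn_config")
}

#' @export
print.a2gcn_config <- function(x, ...) {
  cat("<a2gcn_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
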