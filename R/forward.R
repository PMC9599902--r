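#' Symmetric degree normalization of an adjacency matrix
#'
#' Returns \eqn{\tilde D^{-1/2} A \tilde D^{-1/2}}.  Connectivity graphs are
#' signed, so plain row sums can be zero or negative and their inverse
#' square root undefined; the default degree therefore uses absolute values,
#' \eqn{\tilde D_{ii} = \sum_j |A_{ij}|}, which coincides with the usual
#' normalization whenever \eqn{A \ge 0}.  `mode = "raw"` uses the plain row
#' sums and errors when any is non-positive.
#'
#' @param A symmetric N x N matrix with unit diagonal.
#' @param mode `"absolute"` (default) or `"raw"`.
#' @return symmetric N x N matrix.
#' @examples
#' normalize_adjacency(diag(3))               # identity is a fixed point
#' normalize_adjacency(matrix(1, 2, 2))       # all entries 0.5
#' @export
normalize_adjacency <- function(A, mode = c("absolute", "raw")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  deg <- if (mode == "absolute") rowSums(abs(A)) else rowSums(A)
  if (any(deg <= 0))
    stop("non-positive row degree: normalization undefined (mode=", mode, ")")
  dis <- 1 / sqrt(deg)
  A * outer(dis, dis)
}

glorot_uniform <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters
#'
#' Fan-based uniform (Glorot) initialization of every trainable matrix,
#' zero biases.  Layer widths follow the configuration: graph convolutions
#' N -> d1 -> d2, attention head N -> N -> N, classifier 2*d2 -> fc_hidden
#' -> 2.  Draws come from the current RNG state, so seed beforehand for
#' reproducibility.
#'
#' @param n_rois number of ROIs N.
#' @param config an [a2gcn_config()].
#' @param dann also allocate the adversarial domain-classifier head.
#' @return named list of parameter matrices/vectors (class `a2gcn_params`).
#' @export
init_a2gcn_params <- function(n_rois, config = a2gcn_config(), dann = FALSE) {
  d1 <- config$gcn_dims[1L]; d2 <- config$gcn_dims[2L]
  h <- config$fc_hidden
  p <- list(
    W0 = glorot_uniform(n_rois, d1),
    W1 = glorot_uniform(d1, d2),
    Wa1 = glorot_uniform(n_rois, n_rois), ba1 = numeric(n_rois),
    Wa2 = glorot_uniform(n_rois, n_rois), ba2 = numeric(n_rois),
    Wc1 = glorot_uniform(2L * d2, h), bc1 = numeric(h),
    Wc2 = glorot_uniform(h, 2L), bc2 = numeric(2L))
  if (dann) {
    p$Wd1 <- glorot_uniform(2L * d2, h); p$bd1 <- numeric(h)
    p$Wd2 <- glorot_uniform(h, 2L); p$bd2 <- numeric(2L)
  }
  structure(p, class = "a2gcn_params", n_rois = n_rois)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Two-layer graph convolution forward pass
#'
#' Node embedding of one subject:
#' \eqn{H = \mathrm{ReLU}(\hat A\, \mathrm{ReLU}(\hat A X W^{(0)})\, W^{(1)})}
#' with \eqn{\hat A} the normalized adjacency ([normalize_adjacency()]).
#'
#' @param X N x N node feature matrix (the connectivity profile).
#' @param A_hat normalized N x N adjacency.
#' @param params an `a2gcn_params` list (uses `W0`, `W1`), or any list with
#'   those elements.
#' @return N x d2 embedding matrix H.
#' @export
gcn_forward <- function(X, A_hat, params) {
  if (ncol(X) != nrow(params$W0))
    stop(sprintf("feature width %d does not match W0 input %d",
                 ncol(X), nrow(params$W0)))
  H1 <- relu(A_hat %*% X %*% params$W0)
  relu(A_hat %*% H1 %*% params$W1)
}

#' Node attention scores
#'
#' Each node's embedding row is first reduced to a scalar by max pooling
#' over the feature dimension, giving a length-N summary.  Two fully
#' connected layers of width N (ReLU after the first, sigmoid after the
#' second) map that summary to a score per node in \[0, 1\]:
#' \eqn{a = \sigma(W_{a2}\,\mathrm{ReLU}(W_{a1} m + b_{a1}) + b_{a2})}.
#'
#' @param H N x D node embedding matrix.
#' @param params list with `Wa1`, `ba1`, `Wa2`, `ba2`.
#' @return length-N vector of attention scores in \[0, 1\].
#' @export
node_attention <- function(H, params) {
  m <- apply(H, 1L, max)
  if (length(m) != ncol(params$Wa1))
    stop("embedding row count does not match attention width")
  a1 <- relu(as.numeric(params$Wa1 %*% m) + params$ba1)
  stats::plogis(as.numeric(params$Wa2 %*% a1) + params$ba2)
}

#' Residual attention reweighting
#'
#' \eqn{Z = a \odot H + H}: row i of the embedding is scaled by
#' \eqn{1 + a_i}, so zero attention passes the embedding through unchanged
#' and the model never loses a node entirely.
#'
#' @param H N x D embedding matrix.
#' @param att length-N attention vector.
#' @return N x D reweighted embedding Z.
#' @export
reweight <- function(H, att) {
  if (nrow(H) != length(att)) stop("attention length must equal node count")
  H * (1 + att)
}

#' Graph-level readout
#'
#' Concatenates the column means and column maxima of the node embedding:
#' a length-2D vector (mean-pool then max-pool).
#'
#' @param Z N x D (reweighted) node embedding.
#' @return numeric vector of length 2D.
#' @export
readout <- function(Z) {
  Z <- as.matrix(Z)
  c(colMeans(Z), apply(Z, 2L, max))
}

#' Classifier head
#'
#' Two fully connected layers mapping the readout vector to 2 logits:
#' ReLU and dropout (training mode only) after the hidden layer, identity
#' on the output.  Class probabilities are the softmax of the logits.
#'
#' @param G readout vector (length `2 * d2`) or matrix of stacked readouts
#'   (subjects in rows).
#' @param params list with `Wc1`, `bc1`, `Wc2`, `bc2`.
#' @param training apply dropout (drawn from the current RNG state).
#' @param dropout dropout rate.
#' @return list with `logits` (M x 2) and `prob` (M x 2 softmax rows).
#' @export
classify <- function(G, params, training = FALSE, dropout = 0.4) {
  G <- if (is.matrix(G)) G else matrix(G, nrow = 1L)
  if (ncol(G) != nrow(params$Wc1))
    stop(sprintf("readout length %d does not match classifier input %d",
                 ncol(G), nrow(params$Wc1)))
  F1 <- relu(sweep(G %*% params$Wc1, 2L, params$bc1, "+"))
  if (training && dropout > 0) {
    mask <- matrix(stats::runif(length(F1)) >= dropout, nrow(F1), ncol(F1))
    F1 <- F1 * mask / (1 - dropout)
  }
  logits <- sweep(F1 %*% params$Wc2, 2L, params$bc2, "+")
  list(logits = logits, prob = softmax_rows(logits))
}

softmax_rows <- function(logits) {
  z <- exp(logits - apply(logits, 1L, max))
  z / rowSums(z)
}
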