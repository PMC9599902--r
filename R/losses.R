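#' Mean absolute error between paired node embeddings of two domains
#'
#' \eqn{L_M = \frac{1}{NMD} \sum |Z^s - Z^t|} over M paired subjects with
#' N x D embeddings each.  The pairing of (unrelated) source and target
#' subjects is decided upstream by the trainer, which re-pairs at random
#' every epoch so the expected loss is a distribution-level discrepancy;
#' the loss itself requires equal sample counts.
#'
#' @param Zs,Zt arrays of identical shape: either N x D (single pair) or
#'   M x N x D stacks, or lists of N x D matrices.
#' @return non-negative scalar.
#' @export
mae_loss <- function(Zs, Zt) {
  Zs <- stack_embeddings(Zs); Zt <- stack_embeddings(Zt)
  if (!identical(dim(Zs), dim(Zt)))
    stop("domain embedding shapes differ: ",
         paste(dim(Zs), collapse = "x"), " vs ",
         paste(dim(Zt), collapse = "x"))
  mean(abs(Zs - Zt))
}

stack_embeddings <- function(Z) {
  if (is.list(Z)) {
    Z <- do.call(rbind, Z)
  }
  as.array(Z)
}

#' Sample covariance of stacked feature vectors
#'
#' \eqn{C = \frac{1}{M-1}\left(G^\top G - \frac{(1^\top G)^\top(1^\top G)}{M}\right)}
#' for an M x d matrix of per-subject representations: the usual unbiased
#' sample covariance written with uncentred inner products.
#'
#' @param G M x d numeric matrix, M >= 2.
#' @return symmetric positive semidefinite d x d matrix.
#' @export
feature_covariance <- function(G) {
  G <- as.matrix(G)
  M <- nrow(G)
  if (M < 2L) stop("need at least 2 samples for a covariance")
  s <- colSums(G)
  (crossprod(G) - tcrossprod(s) / M) / (M - 1)
}

#' CORAL loss: covariance distance between two domains
#'
#' \eqn{L_A = \frac{1}{4 d^2} \lVert C_s - C_t \rVert_F^2} where
#' \eqn{C_s, C_t} are the per-domain feature covariances
#' ([feature_covariance()]).  The sample counts of the two domains may
#' differ.  `denom_dim` overrides the scaling dimension d (by default the
#' actual feature length of `Gs`).
#'
#' @param Gs,Gt M_s x d and M_t x d matrices of per-subject representations.
#' @param denom_dim scaling dimension d (default `ncol(Gs)`).
#' @return non-negative scalar, symmetric in its arguments.
#' @export
coral_loss <- function(Gs, Gt, denom_dim = NULL) {
  Gs <- as.matrix(Gs); Gt <- as.matrix(Gt)
  if (ncol(Gs) != ncol(Gt)) stop("feature dimensions differ")
  if (nrow(Gs) < 2L || nrow(Gt) < 2L)
    stop("need at least 2 subjects per domain")
  d <- if (is.null(denom_dim)) ncol(Gs) else denom_dim
  delta <- feature_covariance(Gs) - feature_covariance(Gt)
  sum(delta^2) / (4 * d^2)
}

#' Two-class cross entropy on source predictions
#'
#' \eqn{L_C = -\frac{1}{M_s}\sum_i \left[ y_i \log \hat p_i +
#' (1-y_i)\log(1-\hat p_i) \right]} with \eqn{\hat p_i} the predicted
#' probability of class 1.  Probabilities are clipped at `1e-12` (with a
#' warning) to keep the logarithm finite.
#'
#' @param prob predicted probability of class 1 per subject (vector), or an
#'   M x 2 matrix of class probabilities whose second column is class 1.
#' @param labels 0/1 integer vector.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(prob, labels) {
  if (is.matrix(prob)) prob <- prob[, 2L]
  if (length(prob) != length(labels)) stop("length mismatch")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  p_true <- ifelse(labels == 1L, prob, 1 - prob)
  if (any(p_true <= 0)) {
    warning("probability 0 for a true class; clipping at 1e-12")
    p_true <- pmax(p_true, 1e-12)
  }
  -mean(log(pmin(p_true, 1)))
}

#' Combined training objective
#'
#' \eqn{L = L_C + \gamma_1 L_M + \gamma_2 L_A}.  During the pretraining
#' stage the classification term is excluded (`stage = "pretrain"` sets its
#' coefficient to zero), matching the schedule in which node representation
#' and attention are first trained on the alignment losses alone.
#'
#' @param lc,lm,la the classification, MAE and CORAL loss values.
#' @param gamma1,gamma2 non-negative balance weights.
#' @param stage `"joint"` (default) or `"pretrain"`.
#' @return scalar objective.
#' @export
total_loss <- function(lc, lm, la, gamma1 = 0.5, gamma2 = 0.5,
                       stage = c("joint", "pretrain")) {
  stage <- match.arg(stage)
  if (gamma1 < 0 || gamma2 < 0) stop("gamma weights must be non-negative")
  stopifnot(is.finite(lc), is.finite(lm), is.finite(la))
  (if (stage == "pretrain") 0 else lc) + gamma1 * lm + gamma2 * la
}

#' Multi-kernel maximum mean discrepancy
#'
#' Biased MMD^2 estimate between two samples under a sum of Gaussian
#' kernels whose bandwidths are geometrically spaced around the median
#' pairwise squared distance (the usual multi-kernel convention of deep
#' transfer-learning implementations).
#'
#' @param Gs,Gt M_s x d and M_t x d feature matrices.
#' @param n_kernels number of bandwidths.
#' @param mul geometric spacing factor between consecutive bandwidths.
#' @return non-negative scalar (0 when the samples coincide).
#' @export
mmd_loss <- function(Gs, Gt, n_kernels = 5L, mul = 2) {
  Gs <- as.matrix(Gs); Gt <- as.matrix(Gt)
  if (ncol(Gs) != ncol(Gt)) stop("feature dimensions differ")
  X <- rbind(Gs, Gt)
  d2 <- pairwise_sqdist(X)
  ms <- nrow(Gs); mt <- nrow(Gt); m <- ms + mt
  off <- d2[upper.tri(d2)]
  med <- stats::median(off)
  if (!is.finite(med) || med <= 0) med <- 1
  # center the geometric bandwidth ladder on the median distance
  band <- med * mul^(seq_len(n_kernels) - 1L - (n_kernels - 1L) / 2)
  K <- matrix(0, m, m)
  for (b in band) K <- K + exp(-d2 / b)
  is <- seq_len(ms); it <- ms + seq_len(mt)
  mean(K[is, is]) + mean(K[it, it]) - 2 * mean(K[is, it, drop = FALSE])
}

pairwise_sqdist <- function(X) {
  sq <- rowSums(X^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  d2
}

#' Gradient reversal layer
#'
#' The forward pass is the identity; the backward pass multiplies the
#' upstream gradient by \eqn{-\lambda}.  Used to train a domain classifier
#' adversarially: the domain head minimizes its loss while the feature
#' extractor receives the reversed gradient and maximizes it.
#'
#' @param x input (returned unchanged).
#' @param grad upstream gradient.
#' @param lambda non-negative adaptation weight.
#' @return `grl_forward`: `x`; `grl_backward`: `-lambda * grad`.
#' @export
grl_forward <- function(x) x

#' @rdname grl_forward
#' @export
grl_backward <- function(grad, lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  -lambda * grad
}

#' Adversarial adaptation weight schedule
#'
#' \eqn{\lambda(p) = 2/(1+e^{-10p}) - 1} over training progress
#' \eqn{p \in [0,1]}: ramps smoothly from 0 to (almost) 1 so that the
#' adversarial signal is suppressed early in training.
#'
#' @param p training progress in \[0, 1\].
#' @return lambda in \[0, 1).
#' @export
dann_lambda <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  2 / (1 + exp(-10 * p)) - 1
}
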