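#' Simulate a two-site labeled connectome cohort
#'
#' Generates ROI time series for labeled subjects at two "sites" (a source
#' and a target domain) whose functional-connectivity matrices share class
#' structure but differ in distribution — a desk-scale stand-in for
#' multi-site rs-fMRI cohorts.  Each subject's series are T i.i.d. draws
#' from a zero-mean multivariate normal whose correlation matrix is built
#' in three steps:
#'
#' 1. *Base structure*: `n_blocks` equal communities with within-block
#'    correlation `within` and between-block correlation `between`.
#' 2. *Class effect*: the off-diagonal entries of a planted `k_informative`
#'    x `k_informative` block (the first k ROIs) are shifted by
#'    \eqn{+\delta/2} for class 1 and \eqn{-\delta/2} for class 0.
#' 3. *Site effect*: each domain applies its own random congruence
#'    transform \eqn{\Sigma \mapsto (I + sE)\,\Sigma\,(I + sE)^\top} with a
#'    fixed symmetric Gaussian `E` per domain, rescaled back to a
#'    correlation matrix.  `shift = 0` removes the site difference.
#'
#' Any matrix that loses positive definiteness is repaired by clipping its
#' eigenvalues at `1e-6` (re-standardized to unit diagonal); the repair is
#' recorded in the ground truth and an error is raised if it would alter
#' the matrix by more than 50% in Frobenius norm.
#'
#' @param n_rois number of ROIs N (default 116, the AAL parcellation size).
#' @param n_time time points T per subject.
#' @param m_per_class subjects per class per domain.
#' @param k_informative size of the planted informative ROI set.
#' @param delta class effect size: correlation offset between classes in
#'   the informative block.
#' @param shift site effect strength s.
#' @param noise_sd standard deviation of white observation noise added to
#'   the time series (0 = none).
#' @param n_blocks,within,between base community structure.
#' @param seed master seed; the whole cohort is a deterministic function of
#'   the arguments.
#' @return a `sim_cohort` (also a `cohort`): graphs and labels for both
#'   domains, per-subject `time_series`, the in-memory `manifest`, and
#'   `ground_truth` (informative ROI indices, true labels, per-domain/class
#'   correlation matrices, repair log).
#' @examples
#' sim <- simulate_cohort(n_rois = 12, n_time = 40, m_per_class = 4,
#'                        k_informative = 3, delta = 0.4, shift = 0.3,
#'                        seed = 1)
#' sim
#' @export
simulate_cohort <- function(n_rois = 116L, n_time = 150L, m_per_class = 30L,
                            k_informative = 10L, delta = 0.2, shift = 0.3,
                            noise_sd = 0, n_blocks = 4L, within = 0.3,
                            between = 0.05, seed = 1L) {
  stopifnot(n_rois >= 4L, n_time >= 3L, m_per_class >= 1L,
            k_informative >= 1L, k_informative <= n_rois,
            delta >= 0, shift >= 0, noise_sd >= 0)
  set.seed(seed)
  informative <- seq_len(k_informative)
  base <- block_correlation(n_rois, n_blocks, within, between)
  pd_log <- character(0)

  # one congruence transform per domain, shared by its classes
  Es <- lapply(c(source = 1, target = 2), function(i) {
    E <- matrix(stats::rnorm(n_rois^2, sd = 1 / sqrt(n_rois)),
                n_rois, n_rois)
    (E + t(E)) / 2
  })

  sigma_for <- function(domain, class) {
    S <- base
    blk <- S[informative, informative]
    off <- row(blk) != col(blk)
    blk[off] <- blk[off] + if (class == 1L) delta / 2 else -delta / 2
    S[informative, informative] <- blk
    R <- diag(n_rois) + shift * Es[[domain]]
    S <- R %*% S %*% t(R)
    S <- stats::cov2cor(S)
    rep <- repair_pd(S)
    if (rep$adjusted)
      pd_log <<- c(pd_log, sprintf("%s/class%d: eigenvalues clipped (%.2e)",
                                   domain, class, rep$change))
    rep$mat
  }

  sigmas <- list(source = list(sigma_for("source", 0L),
                               sigma_for("source", 1L)),
                 target = list(sigma_for("target", 0L),
                               sigma_for("target", 1L)))
  chols <- lapply(sigmas, function(d) lapply(d, chol))

  ts_list <- list(); graphs <- list(); meta <- list()
  for (domain in c("source", "target")) {
    for (class in c(0L, 1L)) {
      for (m in seq_len(m_per_class)) {
        sid <- sprintf("%s_c%d_%03d", domain, class, m)
        Z <- matrix(stats::rnorm(n_time * n_rois), n_time, n_rois)
        vals <- Z %*% chols[[domain]][[class + 1L]]
        if (noise_sd > 0)
          vals <- vals + matrix(stats::rnorm(n_time * n_rois,
                                             sd = noise_sd),
                                n_time, n_rois)
        colnames(vals) <- paste0("roi", seq_len(n_rois))
        ts <- as_roi_time_series(vals, sid)
        ts_list[[sid]] <- ts
        graphs[[sid]] <- build_graph(ts, label = class)
        meta[[length(meta) + 1L]] <-
          data.frame(subject_id = sid, domain_tag = domain,
                     label = class, path = paste0(sid, ".tsv"))
      }
    }
  }
  manifest <- do.call(rbind, meta)
  manifest$is_source <- manifest$domain_tag == "source"
  class(manifest) <- c("cohort_manifest", "data.frame")

  src <- manifest$is_source
  out <- new_cohort(
    graphs_source = unname(graphs[src]),
    graphs_target = unname(graphs[!src]),
    labels_source = manifest$label[src],
    target_labels_heldout = manifest$label[!src],
    manifest = manifest,
    ground_truth = list(informative_rois = informative,
                        labels = stats::setNames(manifest$label,
                                                 manifest$subject_id),
                        sigmas = sigmas, pd_log = pd_log,
                        config = list(n_rois = n_rois, n_time = n_time,
                                      m_per_class = m_per_class,
                                      k_informative = k_informative,
                                      delta = delta, shift = shift,
                                      noise_sd = noise_sd, seed = seed)))
  out$time_series <- ts_list
  class(out) <- c("sim_cohort", "cohort")
  out
}

block_correlation <- function(n, n_blocks, within, between) {
  blk <- rep(seq_len(n_blocks), each = ceiling(n / n_blocks))[seq_len(n)]
  S <- matrix(between, n, n)
  same <- outer(blk, blk, "==")
  S[same] <- within
  diag(S) <- 1
  S
}

repair_pd <- function(S, floor = 1e-6, max_change = 0.5) {
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) >= floor)
    return(list(mat = S, adjusted = FALSE, change = 0))
  vals <- pmax(ev$values, floor)
  S2 <- ev$vectors %*% (vals * t(ev$vectors))
  S2 <- stats::cov2cor((S2 + t(S2)) / 2)
  change <- sqrt(sum((S2 - S)^2)) / sqrt(sum(S^2))
  if (change > max_change)
    stop(sprintf("covariance repair too large (%.2f Frobenius)", change))
  list(mat = S2, adjusted = TRUE, change = change)
}

#' Write a simulated cohort to a directory
#'
#' Produces a self-contained cohort directory: `manifest.csv`, one
#' tab-separated time-series file per subject, and `ground_truth.json`
#' (informative ROIs, labels, generator settings).
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(sim$time_series))
    write_time_series(sim$time_series[[sid]],
                      file.path(dir, paste0(sid, ".tsv")))
  write_manifest(sim$manifest, file.path(dir, "manifest.csv"))
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(informative_rois = gt$informative_rois,
         labels = as.list(gt$labels),
         pd_log = gt$pd_log, config = gt$config),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
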