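#' Pearson correlation between two ROI time series
#'
#' Functional connectivity between two regions is the Pearson correlation of
#' their mean BOLD time series, computed with mean-centred inner products:
#' \deqn{e_{ij} = \frac{(v_i-\bar v_i)^\top (v_j-\bar v_j)}
#'   {\sqrt{(v_i-\bar v_i)^\top (v_i-\bar v_i)}\,
#'    \sqrt{(v_j-\bar v_j)^\top (v_j-\bar v_j)}}}
#' The value lies in \eqn{[-1, 1]}, is symmetric in its arguments and is
#' invariant to affine rescaling of either series with positive slope.
#'
#' @param vi,vj numeric vectors of equal length (at least 3 time points).
#' @return a single correlation value in \eqn{[-1, 1]}.
#' @examples
#' pearson_edge(c(1, 2, 3), c(3, 2, 1))   # exactly -1
#' @export
pearson_edge <- function(vi, vj) {
  if (!is.numeric(vi) || !is.numeric(vj)) stop("time series must be numeric")
  if (length(vi) != length(vj)) stop("time series lengths differ")
  if (length(vi) < 3L) stop("need at least 3 time points")
  ci <- vi - mean(vi)
  cj <- vj - mean(vj)
  di <- sqrt(sum(ci * ci))
  dj <- sqrt(sum(cj * cj))
  if (di == 0 || dj == 0) stop("constant time series: correlation undefined")
  val <- sum(ci * cj) / (di * dj)
  # guard against rounding just outside [-1, 1]
  max(-1, min(1, val))
}

new_brain_graph <- function(adjacency, subject_id = NA_character_,
                            label = NA_integer_, roi_names = NULL) {
  n <- nrow(adjacency)
  if (is.null(roi_names)) roi_names <- colnames(adjacency)
  if (is.null(roi_names)) roi_names <- paste0("roi", seq_len(n))
  dimnames(adjacency) <- list(roi_names, roi_names)
  structure(
    list(adjacency = adjacency, features = adjacency,
         subject_id = subject_id, label = label, roi_names = roi_names,
         n_rois = n),
    class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("<brain_graph> subject=%s  N=%d ROIs  label=%s\n",
              x$subject_id, x$n_rois,
              if (is.na(x$label)) "unlabeled" else x$label))
  invisible(x)
}

validate_brain_graph <- function(graph, tol = 1e-6) {
  A <- graph$adjacency
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("adjacency must be square")
  if (max(abs(A - t(A))) > tol) stop("adjacency must be symmetric")
  if (max(abs(diag(A) - 1)) > tol) stop("adjacency diagonal must be 1")
  if (max(abs(A)) > 1 + tol) stop("adjacency entries must lie in [-1, 1]")
  invisible(graph)
}

#' Build a functional connectivity graph from ROI time series
#'
#' The subject's graph has one node per ROI; the edge weight between ROIs
#' \eqn{i \ne j} is their Pearson correlation ([pearson_edge()]) and the
#' diagonal is exactly 1.  The node feature matrix equals the adjacency
#' matrix, so each node is described by its connectivity profile.  Negative
#' correlations are kept; set `abs_adjacency = TRUE` to use absolute values.
#'
#' @param ts an object from [read_time_series()] or a plain T x N numeric
#'   matrix (rows = time points, columns = ROIs).
#' @param subject_id,label optional identifiers attached to the graph.
#' @param abs_adjacency take absolute values of the correlations
#'   (default `FALSE`: signed connectivity).
#' @return a `brain_graph`: list with `adjacency` and `features` (both
#'   N x N), `subject_id`, `label`, `roi_names`.
#' @examples
#' ts <- matrix(rnorm(40), 10, 4)
#' g <- build_graph(ts)
#' all(diag(g$adjacency) == 1)
#' @export
build_graph <- function(ts, subject_id = NULL, label = NA_integer_,
                        abs_adjacency = FALSE) {
  if (inherits(ts, "roi_time_series")) {
    values <- ts$values
    if (is.null(subject_id)) subject_id <- ts$subject_id
    roi_names <- ts$roi_names
  } else {
    values <- as.matrix(ts)
    roi_names <- colnames(values)
  }
  if (is.null(subject_id)) subject_id <- NA_character_
  if (nrow(values) < 3L) stop("need at least 3 time points")
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0)) {
    nm <- if (is.null(roi_names)) paste0("roi", which(sds == 0)) else
      roi_names[sds == 0]
    stop("constant ROI ", paste(nm, collapse = ", "),
         ": correlation undefined")
  }
  A <- stats::cor(values)
  A[A > 1] <- 1
  A[A < -1] <- -1
  A <- (A + t(A)) / 2
  diag(A) <- 1
  if (abs_adjacency) A <- abs(A)
  g <- new_brain_graph(A, subject_id = subject_id, label = label,
                       roi_names = roi_names)
  validate_brain_graph(g)
}

#' Load a precomputed connectivity matrix
#'
#' Reads a square connectivity matrix from a delimited text file (header row
#' of ROI names).  Mild asymmetry (up to `1e-6`) is repaired by averaging
#' with the transpose; larger asymmetry, non-square shape or entries outside
#' \eqn{[-1, 1]} raise errors.  The diagonal is forced to 1 when within
#' tolerance of 1.
#'
#' @param path file with an N x N numeric matrix (CSV/TSV, header row).
#' @inheritParams build_graph
#' @return a `brain_graph`.
#' @export
load_precomputed_graph <- function(path, subject_id = NA_character_,
                                   label = NA_integer_) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        sep = guess_sep(path))
  A <- as.matrix(df)
  if (!is.numeric(A)) stop("non-numeric entries in ", path)
  if (nrow(A) != ncol(A))
    stop(sprintf("connectivity matrix must be square, got %dx%d in %s",
                 nrow(A), ncol(A), path))
  if (max(abs(A - t(A))) > 1e-6)
    stop("matrix in ", path, " is not symmetric (tolerance 1e-6)")
  A <- (A + t(A)) / 2
  if (max(abs(A)) > 1 + 1e-6)
    stop("entries outside [-1, 1] in ", path)
  A[A > 1] <- 1
  A[A < -1] <- -1
  if (max(abs(diag(A) - 1)) > 1e-6) diag(A) <- 1
  g <- new_brain_graph(A, subject_id = subject_id, label = label,
                       roi_names = colnames(df))
  validate_brain_graph(g)
}

#' Write a connectivity matrix to a delimited file
#'
#' @param graph a `brain_graph`.
#' @param path output file; comma-separated with a header row of ROI names.
#' @export
write_graph <- function(graph, path) {
  utils::write.csv(as.data.frame(graph$adjacency), path, row.names = FALSE)
  invisible(path)
}
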