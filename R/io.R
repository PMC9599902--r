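guess_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read one subject's ROI time series
#'
#' Expects delimited text (comma or tab, auto-detected) whose first row
#' holds ROI names and whose subsequent rows are time points: rows = time,
#' columns = ROI.  Use `transpose = TRUE` for files written the other way
#' around.  A column with zero variance is rejected, since its Pearson
#' correlations are undefined.
#'
#' @param path input file.
#' @param subject_id identifier attached to the result (default: file name
#'   without extension).
#' @param transpose if `TRUE`, the file is ROI x time and is transposed
#'   after reading.
#' @return an object of class `roi_time_series`: list with `values`
#'   (T x N matrix), `roi_names`, `subject_id`.
#' @export
read_time_series <- function(path, subject_id = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, sep = guess_sep(path),
                        colClasses = NA)
  bad <- which(!vapply(df, is.numeric, logical(1L)))
  if (length(bad))
    stop(sprintf("non-numeric value in column '%s' of %s",
                 names(df)[bad[1L]], path))
  values <- as.matrix(df)
  if (transpose) {
    roi_names <- rownames(values)
    values <- t(values)
    colnames(values) <- NULL
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  as_roi_time_series(values, subject_id)
}

as_roi_time_series <- function(values, subject_id = NA_character_) {
  values <- as.matrix(values)
  if (nrow(values) < 3L)
    stop("need at least 3 time points, got ", nrow(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("roi", seq_len(ncol(values)))
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI ", paste(colnames(values)[sds == 0], collapse = ", "))
  structure(list(values = values, roi_names = colnames(values),
                 subject_id = subject_id, n_time = nrow(values),
                 n_rois = ncol(values)),
            class = "roi_time_series")
}

#' @export
print.roi_time_series <- function(x, ...) {
  cat(sprintf("<roi_time_series> subject=%s  T=%d  N=%d\n",
              x$subject_id, x$n_time, x$n_rois))
  invisible(x)
}

#' Write ROI time series to a tab-separated file
#'
#' Inverse of [read_time_series()] up to floating-point formatting.
#'
#' @param ts a `roi_time_series` or T x N matrix.
#' @param path output file.
#' @export
write_time_series <- function(ts, path) {
  values <- if (inherits(ts, "roi_time_series")) ts$values else as.matrix(ts)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  utils::write.table(values, path, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `domain_tag`, `label`,
#' `path`.  `domain_tag` marks each subject as belonging to the labeled
#' source site or the unlabeled target site (literal `"source"` / `"target"`,
#' or two site names with `source_tag`/`target_tag` naming which is which).
#' Every source subject must carry a 0/1 label; target labels may be present
#' but are held out for evaluation only and are never seen by training.
#'
#' @param path manifest CSV.
#' @param source_tag,target_tag values of `domain_tag` identifying the two
#'   domains (defaults `"source"`, `"target"`).
#' @param check_paths verify that each referenced data file exists.
#' @return a `cohort_manifest` data frame with an extra logical column
#'   `is_source`.
#' @export
read_manifest <- function(path, source_tag = "source", target_tag = "target",
                          check_paths = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character",
                                       domain_tag = "character"))
  need <- c("subject_id", "domain_tag", "label", "path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest misses column(s): ",
                         paste(miss, collapse = ", "))
  validate_manifest(df, source_tag, target_tag,
                    base_dir = dirname(path), check_paths = check_paths)
}

validate_manifest <- function(df, source_tag = "source",
                              target_tag = "target", base_dir = ".",
                              check_paths = TRUE) {
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  tags <- unique(df$domain_tag)
  if (!all(tags %in% c(source_tag, target_tag)))
    stop("unknown domain_tag value(s): ",
         paste(setdiff(tags, c(source_tag, target_tag)), collapse = ", "))
  df$is_source <- df$domain_tag == source_tag
  df$label <- suppressWarnings(as.integer(df$label))
  if (any(df$is_source & is.na(df$label)))
    stop("source subject(s) without label: ",
         paste(df$subject_id[df$is_source & is.na(df$label)], collapse = ", "))
  if (!all(df$label %in% c(0L, 1L, NA_integer_)))
    stop("labels must be 0/1")
  if (check_paths && "path" %in% names(df)) {
    full <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                   file.path(base_dir, df$path))
    gone <- !file.exists(full)
    if (any(gone)) stop("manifest references missing file(s): ",
                        paste(full[gone], collapse = ", "))
    df$resolved_path <- full
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#' @param manifest data frame with columns `subject_id`, `domain_tag`,
#'   `label`, `path`.
#' @param path output CSV.
#' @export
write_manifest <- function(manifest, path) {
  keep <- intersect(c("subject_id", "domain_tag", "label", "path"),
                    names(manifest))
  utils::write.csv(as.data.frame(manifest)[keep], path, row.names = FALSE)
  invisible(path)
}

#' Load a full cohort of graphs from a manifest
#'
#' Reads every subject referenced by the manifest, builds (or loads) its
#' connectivity graph, and partitions the cohort into source and target.
#' Files are treated as ROI time series unless `precomputed = TRUE`, in
#' which case they are read as square connectivity matrices.
#'
#' Target labels present in the manifest are stored separately
#' (`target_labels_heldout`) and attached nowhere else: model fitting
#' receives only the graphs, enforcing the unsupervised setting.
#'
#' @param manifest a `cohort_manifest` (from [read_manifest()]).
#' @param precomputed files are N x N connectivity matrices rather than
#'   time series.
#' @param transpose passed to [read_time_series()].
#' @param abs_adjacency passed to [build_graph()].
#' @return a `cohort` list: `graphs_source`, `graphs_target` (lists of
#'   `brain_graph`; source graphs carry labels, target graphs do not),
#'   `labels_source`, `target_labels_heldout`, `manifest`.
#' @export
load_cohort <- function(manifest, precomputed = FALSE, transpose = FALSE,
                        abs_adjacency = FALSE) {
  stopifnot(inherits(manifest, "cohort_manifest"))
  paths <- if ("resolved_path" %in% names(manifest)) manifest$resolved_path
           else manifest$path
  graphs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    lab <- if (manifest$is_source[i]) manifest$label[i] else NA_integer_
    graphs[[i]] <- if (precomputed) {
      load_precomputed_graph(paths[i], subject_id = manifest$subject_id[i],
                             label = lab)
    } else {
      build_graph(read_time_series(paths[i],
                                   subject_id = manifest$subject_id[i],
                                   transpose = transpose),
                  label = lab, abs_adjacency = abs_adjacency)
    }
  }
  ns <- vapply(graphs, function(g) g$n_rois, integer(1L))
  if (length(unique(ns)) > 1L)
    stop("subjects have differing ROI counts: ",
         paste(unique(ns), collapse = ", "))
  src <- manifest$is_source
  new_cohort(graphs_source = graphs[src],
             graphs_target = graphs[!src],
             labels_source = manifest$label[src],
             target_labels_heldout = manifest$label[!src],
             manifest = manifest)
}

new_cohort <- function(graphs_source, graphs_target, labels_source,
                       target_labels_heldout = NULL, manifest = NULL,
                       ground_truth = NULL) {
  structure(list(graphs_source = graphs_source,
                 graphs_target = graphs_target,
                 labels_source = as.integer(labels_source),
                 target_labels_heldout =
                   if (is.null(target_labels_heldout)) NULL
                   else as.integer(target_labels_heldout),
                 manifest = manifest,
                 ground_truth = ground_truth),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d source (labeled) + %d target subjects, N=%d ROIs\n",
              length(x$graphs_source), length(x$graphs_target),
              if (length(x$graphs_source)) x$graphs_source[[1L]]$n_rois
              else NA_integer_))
  invisible(x)
}

#' Read a run configuration file
#'
#' YAML file whose keys override the defaults of [a2gcn_config()]; unknown
#' keys raise an error.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file (CLI flags).
#' @return an `a2gcn_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("no such config file: ", path)
    yaml::read_yaml(path)
  }
  vals <- utils::modifyList(vals, overrides)
  do.call(a2gcn_config, vals)
}
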