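#' Metrics for a set of scored target predictions
#'
#' @param predicted 0/1 predicted labels.
#' @param scores class-1 scores (probabilities or decision values).
#' @param truth 0/1 held-out labels.
#' @return named vector `ACC`, `Pre`, `Rec`, `F1`, `BAC`, `NPV`, `AUC`.
#' @export
metrics_from_predictions <- function(predicted, scores, truth) {
  m <- compute_metrics(confusion_counts(predicted, truth))
  auc <- tryCatch(auc_score(scores, truth), error = function(e) NA_real_)
  c(m, AUC = auc)
}

#' Repeated seeded fits with aggregated metrics
#'
#' Runs the full pipeline `repeats` times with derived seeds
#' (`seed + repeat - 1`), scores every target subject against the held-out
#' target labels, and reports each of the seven metrics as mean and
#' standard deviation across repeats — the transductive protocol in which
#' all source and target subjects are used for training and every target
#' subject is tested.
#'
#' @param cohort a `cohort` (e.g. from [simulate_cohort()] or
#'   [load_cohort()]) whose `target_labels_heldout` are available for
#'   scoring.
#' @param method `"a2gcn"`, a baseline name accepted by [fit_baseline()],
#'   or an ablation name accepted by [fit_ablation()].
#' @param config an [a2gcn_config()].
#' @param repeats number of repeated fits (default from `config`).
#' @param seed master seed (default from `config`).
#' @return an `fcn_experiment`: `per_repeat` metric matrix, `mean`, `sd`,
#'   per-repeat `cf_pre`/`cf_post` where the method exposes them, and the
#'   last fit.
#' @export
run_experiment <- function(cohort, method = "a2gcn",
                           config = a2gcn_config(),
                           repeats = config$repeats, seed = config$seed) {
  stopifnot(inherits(cohort, "cohort"))
  truth <- cohort$target_labels_heldout
  if (is.null(truth) || all(is.na(truth)))
    warning("no held-out target labels: metrics will be NA")
  method <- tolower(method)
  rows <- list(); cf_pre <- numeric(0); cf_post <- numeric(0)
  last_fit <- NULL
  for (r in seq_len(repeats)) {
    sr <- seed + r - 1L
    fr <- fit_method(method, cohort, config, sr)
    last_fit <- fr$fit
    rows[[r]] <- if (is.null(truth) || all(is.na(truth)))
      c(ACC = NA_real_, Pre = NA_real_, Rec = NA_real_, F1 = NA_real_,
        BAC = NA_real_, NPV = NA_real_, AUC = NA_real_)
    else metrics_from_predictions(fr$pred, fr$score, truth)
    if (!is.null(fr$cf_pre)) {
      cf_pre <- c(cf_pre, fr$cf_pre); cf_post <- c(cf_post, fr$cf_post)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- paste0("repeat", seq_len(repeats))
  structure(list(method = method,
                 per_repeat = per,
                 mean = colMeans(per),
                 sd = apply(per, 2L, stats::sd),
                 cf_pre = cf_pre, cf_post = cf_post,
                 repeats = repeats, seed = seed,
                 last_fit = last_fit),
            class = "fcn_experiment")
}

# One repeat of any method on a cohort: shared predictions schema.
fit_method <- function(method, cohort, config, seed) {
  if (method == "a2gcn") {
    fit <- a2gcn(cohort, config = config, seed = seed)
    prob <- fit$target$prob
    list(pred = as.integer(prob[, 2L] > 0.5), score = prob[, 2L],
         fit = fit, cf_pre = fit$cf_pre, cf_post = fit$cf_post)
  } else if (method %in% c("a2gcn_a", "a2gcn_m", "a2gcn_c")) {
    fit <- fit_ablation(method, cohort$graphs_source, cohort$labels_source,
                        cohort$graphs_target, config, seed)
    prob <- fit$target$prob
    list(pred = as.integer(prob[, 2L] > 0.5), score = prob[, 2L],
         fit = fit, cf_pre = fit$cf_pre, cf_post = fit$cf_post)
  } else {
    bl <- fit_baseline(method, cohort$graphs_source, cohort$labels_source,
                       cohort$graphs_target, config, seed)
    cfp <- if (inherits(bl$fit, "a2gcn")) bl$fit$cf_pre else NULL
    cfq <- if (inherits(bl$fit, "a2gcn")) bl$fit$cf_post else NULL
    list(pred = bl$pred, score = bl$score, fit = bl,
         cf_pre = cfp, cf_post = cfq)
  }
}

#' @export
print.fcn_experiment <- function(x, digits = 4, ...) {
  cat(sprintf("Experiment: %s, %d repeats (seed %d)\n", x$method,
              x$repeats, x$seed))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  if (length(x$cf_pre))
    cat(sprintf("CF shift on readout: %.4f -> %.4f (means over repeats)\n",
                mean(x$cf_pre), mean(x$cf_post)))
  invisible(x)
}
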