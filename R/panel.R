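#' Restrict a signature to secreted / BALF genes
#'
#' Biomarker candidates must be measurable in bronchoalveolar lavage fluid,
#' so the core signature is intersected with the secreted-protein / BALF
#' annotation before the panel search. Core order is preserved.
#'
#' @param core a `gene_signature` or character gene vector.
#' @param secreted character vector of secreted/BALF gene ids.
#' @return character vector of candidate biomarker genes.
#' @export
filter_secreted <- function(core, secreted) {
  if (inherits(core, "gene_signature")) core <- core$genes
  out <- core[core %in% secreted]
  if (length(out) == 0L) {
    stop("no signature gene carries a secreted/BALF annotation; ",
         "check the annotation gene set")
  }
  out
}

#' Rank genes by logistic-coefficient magnitude
#'
#' @param clf a trained `signature_classifier`.
#' @return character vector of genes sorted by decreasing |coefficient|;
#'   ties keep the classifier's gene order.
#' @export
rank_by_coefficient <- function(clf) {
  stopifnot(inherits(clf, "signature_classifier"))
  clf$genes[order(-abs(clf$coefficients))]
}

# threshold maximizing accuracy over the midpoint candidates (highest among
# ties)
.calibrate_threshold_accuracy <- function(scores, labels) {
  labels <- .check_labels(labels)
  cand <- .threshold_candidates(scores)
  acc <- vapply(cand, function(t) mean((scores >= t) == (labels == "disease")),
                numeric(1))
  max(cand[acc == max(acc)])
}

#' Nested biomarker-panel search
#'
#' Trains a series of logistic classifiers on the top 1, 2, ..., `k_max`
#' coefficient-ranked candidate genes; each model's threshold is calibrated
#' (to the sensitivity floor by default, or to maximal accuracy) and its
#' sensitivity/specificity/accuracy recorded. The selected panel is the
#' smallest k whose metrics satisfy specificity > `min_specificity` and
#' sensitivity >= `min_sensitivity`. Metrics are computed on the training
#' cohort predictions; pass a held-out `eval_m`/`eval_labels` pair to score
#' on a validation cohort instead.
#'
#' @param m training genes x samples matrix (unscaled log2) containing the
#'   candidate genes.
#' @param labels per-sample `"control"` / `"disease"`.
#' @param ordered_genes candidate genes in priority order (e.g. from
#'   [rank_by_coefficient()]).
#' @param k_max largest panel size tried (default 50; truncated with a
#'   warning if it exceeds the candidate count).
#' @param min_specificity specificity requirement, strict (default 0.8).
#' @param min_sensitivity sensitivity requirement, inclusive (default 0.9).
#' @param l2_strength ridge penalty for each nested model.
#' @param calibrate `"sensitivity"` (floor at `min_sensitivity`) or
#'   `"accuracy"` (maximize training accuracy).
#' @param eval_m,eval_labels optional evaluation cohort; defaults to the
#'   training data.
#' @param recalibrate when an evaluation cohort is supplied, calibrate each
#'   model's threshold on the evaluation scores instead of the training
#'   scores — the per-validation-cohort sensitivity-floor convention
#'   (ignored without an evaluation cohort).
#' @param seed recorded in the result (fits are deterministic).
#' @return a `panel_search_result`: `ordered_genes`, `trace` (one row per k),
#'   `selected_k`, `panel`, `criterion_met`, `params`.
#' @export
nested_panel_search <- function(m, labels, ordered_genes, k_max = 50L,
                                min_specificity = 0.8,
                                min_sensitivity = 0.9, l2_strength = 1,
                                calibrate = c("sensitivity", "accuracy"),
                                eval_m = NULL, eval_labels = NULL,
                                recalibrate = FALSE, seed = 17L) {
  calibrate <- match.arg(calibrate)
  .check_expression_matrix(m)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- .check_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  missing_genes <- setdiff(ordered_genes, rownames(m))
  if (length(missing_genes)) {
    stop("candidate gene(s) absent from the matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  if (k_max > length(ordered_genes)) {
    warning("k_max truncated to the ", length(ordered_genes),
            " available candidates")
    k_max <- length(ordered_genes)
  }
  if (is.null(eval_m)) {
    eval_m <- m
    eval_labels <- labels
    recalibrate <- FALSE
  } else {
    .check_expression_matrix(eval_m, "eval_m")
    if (!is.null(names(eval_labels))) eval_labels <- eval_labels[colnames(eval_m)]
    eval_labels <- .check_labels(eval_labels)
  }
  trace <- data.frame(k = seq_len(k_max), sensitivity = NA_real_,
                      specificity = NA_real_, accuracy = NA_real_,
                      threshold = NA_real_)
  for (k in seq_len(k_max)) {
    genes_k <- ordered_genes[seq_len(k)]
    m_k <- m[genes_k, , drop = FALSE]
    ref <- fit_minmax(m_k)
    clf <- train_logistic(apply_minmax(m_k, ref), labels,
                          l2_strength = l2_strength, seed = seed)
    clf$scaling <- ref
    calib_scores <- if (recalibrate) {
      predict_scores(clf, eval_m[genes_k, , drop = FALSE])
    } else {
      predict_scores(clf, m_k)
    }
    calib_labels <- if (recalibrate) eval_labels else labels
    clf$threshold <- if (calibrate == "sensitivity") {
      calibrate_threshold(calib_scores, calib_labels, min_sensitivity)
    } else {
      .calibrate_threshold_accuracy(calib_scores, calib_labels)
    }
    rep_k <- evaluate(clf, eval_m[genes_k, , drop = FALSE], eval_labels,
                      cohort = paste0("k", k))
    trace$sensitivity[k] <- rep_k$sensitivity
    trace$specificity[k] <- rep_k$specificity
    trace$accuracy[k] <- rep_k$accuracy
    trace$threshold[k] <- clf$threshold
  }
  meets <- trace$specificity > min_specificity &
    trace$sensitivity >= min_sensitivity
  selected_k <- if (any(meets)) trace$k[which(meets)[1L]] else NA_integer_
  structure(list(
    ordered_genes = ordered_genes[seq_len(k_max)],
    trace = trace,
    selected_k = selected_k,
    panel = if (is.na(selected_k)) character(0) else
      ordered_genes[seq_len(selected_k)],
    criterion_met = !is.na(selected_k),
    params = list(k_max = k_max, min_specificity = min_specificity,
                  min_sensitivity = min_sensitivity,
                  l2_strength = l2_strength, calibrate = calibrate,
                  seed = seed)
  ), class = "panel_search_result")
}

#' @export
print.panel_search_result <- function(x, ...) {
  cat("panel_search_result:", length(x$ordered_genes), "candidates, ")
  if (x$criterion_met) {
    cat("selected panel of", x$selected_k, "gene(s)\n")
  } else {
    cat("no panel met the criterion\n")
  }
  invisible(x)
}
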