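#' Restrict a signature to genes measured in every cohort
#'
#' Validation cohorts come from different platforms and rarely measure every
#' signature gene; the classifier uses the signature's intersection with all
#' cohorts, in signature order.
#'
#' @param signature character vector of gene ids (or a `gene_signature`).
#' @param cohorts list of expression matrices.
#' @return character vector of retained gene ids.
#' @export
restrict_signature <- function(signature, cohorts) {
  if (inherits(signature, "gene_signature")) signature <- signature$genes
  if (length(cohorts) < 1L) stop("need at least one cohort")
  keep <- signature
  for (m in cohorts) {
    .check_expression_matrix(m)
    keep <- keep[keep %in% rownames(m)]
  }
  if (length(keep) == 0L) {
    stop("no signature gene is present in every cohort")
  }
  keep
}

.check_labels <- function(labels, positive = "disease",
                          negative = "control") {
  labels <- as.character(labels)
  bad <- !labels %in% c(positive, negative)
  if (any(bad)) {
    stop("labels must be '", positive, "' or '", negative, "'")
  }
  labels
}

# run expr with a deterministic, isolated RNG stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Train an L2-regularized logistic signature classifier
#'
#' Maximum penalized likelihood for `P(disease | x) = plogis(b0 + x'b)` with
#' ridge penalty `0.5 * l2_strength * ||b||^2` (the intercept is not
#' penalized), fit by BFGS with analytic gradient from a zero start — fully
#' deterministic. Input expression must already be scaled to \[0, 1\] (see
#' [apply_minmax()]).
#'
#' @param m scaled genes x samples matrix restricted to the signature.
#' @param labels per-sample `"control"` / `"disease"`, named by sample id or
#'   aligned with columns.
#' @param l2_strength ridge penalty weight (default 1).
#' @param seed recorded in metadata (the fit itself is deterministic).
#' @return a `signature_classifier`: gene list, coefficients, intercept,
#'   decision threshold (initially 0.5; see [calibrate_threshold()]),
#'   optional scaling reference, metadata.
#' @export
train_logistic <- function(m, labels, l2_strength = 1, seed = 17L) {
  .check_expression_matrix(m)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- .check_labels(labels)
  y <- as.numeric(labels == "disease")
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes")
  }
  x <- t(m)
  p <- ncol(x)
  obj <- function(theta) {
    eta <- theta[1L] + drop(x %*% theta[-1L])
    # log(1 + exp(eta)) computed stably
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    -ll + 0.5 * l2_strength * sum(theta[-1L]^2)
  }
  grad <- function(theta) {
    eta <- theta[1L] + drop(x %*% theta[-1L])
    r <- stats::plogis(eta) - y
    c(sum(r), drop(crossprod(x, r)) + l2_strength * theta[-1L])
  }
  fit <- stats::optim(rep(0, p + 1L), obj, grad, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  coefs <- fit$par[-1L]
  names(coefs) <- rownames(m)
  structure(list(
    genes = rownames(m),
    coefficients = coefs,
    intercept = fit$par[1L],
    scaling = NULL,
    threshold = 0.5,
    meta = list(l2_strength = l2_strength, seed = seed,
                converged = fit$convergence == 0L)
  ), class = "signature_classifier")
}

#' Predicted disease probabilities
#'
#' Applies the classifier's stored min-max scaling (if any) and returns
#' `plogis(b0 + x'b)` per sample.
#'
#' @param clf a `signature_classifier`.
#' @param m genes x samples matrix containing every classifier gene.
#' @return named numeric vector of probabilities.
#' @export
predict_scores <- function(clf, m) {
  .check_expression_matrix(m)
  missing_genes <- setdiff(clf$genes, rownames(m))
  if (length(missing_genes)) {
    stop("cohort is missing classifier gene(s): ",
         paste(utils::head(missing_genes, 5), collapse = ", "),
         "; restrict the signature first")
  }
  if (!is.null(clf$scaling)) {
    m <- apply_minmax(m, clf$scaling)
  }
  m <- m[clf$genes, , drop = FALSE]
  eta <- clf$intercept + drop(crossprod(m, clf$coefficients))
  stats::plogis(eta)
}

#' ROC curve and AUC
#'
#' Thresholds sweep the unique scores (decision rule: score >= threshold is
#' called disease). The AUC is the Mann-Whitney probability that a random
#' disease sample outscores a random control, with ties counted 1/2.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels `"control"` / `"disease"` per score.
#' @return list with `roc` (data.frame fpr, tpr, threshold; monotone
#'   nondecreasing) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- .check_labels(labels)
  pos <- scores[labels == "disease"]
  neg <- scores[labels == "control"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes are required for a ROC curve")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  r <- rank(scores)
  auc <- (sum(r[labels == "disease"]) -
            length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  list(roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Calibrate the decision threshold to a sensitivity floor
#'
#' Candidate thresholds are the midpoints between consecutive unique scores
#' (plus the extremes), so a threshold never sits exactly on an observed
#' score. Among candidates whose sensitivity on the supplied scores is at
#' least `min_sensitivity`, the one maximizing specificity is returned; when
#' several tie on specificity the lowest is chosen, preserving the largest
#' sensitivity margin — the sensitivity floor is the binding clinical
#' constraint, so calibration never gives away sensitivity that costs no
#' specificity.
#'
#' @param scores numeric scores.
#' @param labels `"control"` / `"disease"` per score.
#' @param min_sensitivity sensitivity floor in \[0, 1\] (default 0.9).
#' @return threshold value; decision rule is `score >= threshold`.
#' @export
calibrate_threshold <- function(scores, labels, min_sensitivity = 0.9) {
  labels <- .check_labels(labels)
  if (min_sensitivity > 1) stop("min_sensitivity cannot exceed 1")
  pos <- scores[labels == "disease"]
  neg <- scores[labels == "control"]
  if (length(pos) == 0L) stop("no disease samples to calibrate on")
  cand <- .threshold_candidates(scores)
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- if (length(neg)) {
    vapply(cand, function(t) mean(neg < t), numeric(1))
  } else {
    rep(1, length(cand))
  }
  ok <- sens >= min_sensitivity
  if (!any(ok)) stop("no threshold reaches the sensitivity floor")
  best_spec <- max(spec[ok])
  min(cand[ok & spec == best_spec])
}

# midpoints between consecutive unique scores, plus the extremes: the lowest
# candidate admits every sample, the highest (capped at 1) admits none
.threshold_candidates <- function(scores) {
  u <- sort(unique(scores))
  cand <- u[1L]
  if (length(u) > 1L) {
    cand <- c(cand, (u[-1L] + u[-length(u)]) / 2)
  }
  if (max(u) < 1) cand <- c(cand, (max(u) + 1) / 2)
  cand
}

.confusion_metrics <- function(pred_pos, labels) {
  is_pos <- labels == "disease"
  tp <- sum(pred_pos & is_pos)
  fn <- sum(!pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fp <- sum(pred_pos & !is_pos)
  list(
    confusion = list(tp = tp, fp = fp, tn = tn, fn = fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(labels)
  )
}

#' Evaluate a classifier on a cohort
#'
#' Applies the stored scaling and decision threshold and reports the
#' confusion counts, sensitivity, specificity, accuracy, ROC points and AUC.
#'
#' @param clf a `signature_classifier` (its genes must all be present in the
#'   cohort; restrict first otherwise).
#' @param m cohort genes x samples matrix (unscaled; the classifier's
#'   training scaling is applied).
#' @param labels per-sample `"control"` / `"disease"`.
#' @param cohort cohort name recorded in the report.
#' @return an `eval_report` list: cohort, auc, sensitivity, specificity,
#'   accuracy, threshold, confusion, roc.
#' @export
evaluate <- function(clf, m, labels, cohort = "cohort") {
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- .check_labels(labels)
  scores <- predict_scores(clf, m)
  roc <- roc_curve(scores, labels)
  metrics <- .confusion_metrics(scores >= clf$threshold, labels)
  structure(c(list(cohort = cohort, auc = roc$auc,
                   threshold = clf$threshold),
              metrics, list(roc = roc$roc, scores = scores)),
            class = "eval_report")
}

#' Stratified k-fold cross-validation of a signature classifier
#'
#' Folds are stratified by class and drawn deterministically from `seed`.
#' Within each fold, min-max scaling is fit on the training part only, the
#' classifier is trained and its threshold calibrated on training scores,
#' and the held-out part is evaluated — so no information leaks from the test
#' fold.
#'
#' @param m unscaled genes x samples matrix restricted to the signature.
#' @param labels per-sample `"control"` / `"disease"`.
#' @param folds number of folds (default 2); each class must have at least
#'   `folds` members.
#' @param seed fold-assignment seed (default 17).
#' @param l2_strength ridge penalty.
#' @param min_sensitivity threshold-calibration floor.
#' @return list of per-fold `eval_report`s (with `fold_assignment`
#'   attribute).
#' @export
cross_validate <- function(m, labels, folds = 2L, seed = 17L,
                           l2_strength = 1, min_sensitivity = 0.9) {
  .check_expression_matrix(m)
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  labels <- .check_labels(labels)
  if (any(table(labels) < folds)) {
    stop("each class needs at least `folds` samples")
  }
  n <- ncol(m)
  fold_id <- integer(n)
  .with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  reports <- lapply(seq_len(folds), function(f) {
    tr <- fold_id != f
    ref <- fit_minmax(m[, tr, drop = FALSE])
    m_tr <- apply_minmax(m[, tr, drop = FALSE], ref)
    clf <- train_logistic(m_tr, labels[tr], l2_strength = l2_strength,
                          seed = seed)
    clf$scaling <- ref
    clf$threshold <- calibrate_threshold(predict_scores(clf,
                                                        m[, tr, drop = FALSE]),
                                         labels[tr], min_sensitivity)
    evaluate(clf, m[, !tr, drop = FALSE], labels[!tr],
             cohort = paste0("fold", f))
  })
  attr(reports, "fold_assignment") <- stats::setNames(fold_id, colnames(m))
  reports
}

#' Train and calibrate the final signature classifier
#'
#' The production path: restrict the signature to the training cohort, learn
#' min-max scaling on all training samples, fit the L2 logistic model, and
#' calibrate the decision threshold on the full training scores to the
#' sensitivity floor.
#'
#' @param m training genes x samples matrix (unscaled log2).
#' @param labels per-sample `"control"` / `"disease"`.
#' @param signature gene ids (already restricted across cohorts if needed).
#' @param l2_strength ridge penalty.
#' @param min_sensitivity calibration floor (default 0.9).
#' @param seed recorded in metadata.
#' @return a calibrated `signature_classifier`.
#' @export
build_signature_classifier <- function(m, labels, signature,
                                       l2_strength = 1,
                                       min_sensitivity = 0.9, seed = 17L) {
  .check_expression_matrix(m)
  if (inherits(signature, "gene_signature")) signature <- signature$genes
  signature <- restrict_signature(signature, list(m))
  if (!is.null(names(labels))) labels <- labels[colnames(m)]
  m_sig <- m[signature, , drop = FALSE]
  ref <- fit_minmax(m_sig)
  clf <- train_logistic(apply_minmax(m_sig, ref), labels,
                        l2_strength = l2_strength, seed = seed)
  clf$scaling <- ref
  clf$threshold <- calibrate_threshold(predict_scores(clf, m_sig), labels,
                                       min_sensitivity)
  clf
}
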