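#' Severity grouping from lung function
#'
#' The baseline, clustering-free stratification: a patient with
#' FVC >= 55% predicted or DLCO >= 40% predicted is mild-to-moderate,
#' otherwise severe. A sample missing both measures is `unknown`; if only one
#' measure is present the rule is evaluated on it alone.
#'
#' @param cl clinical `data.frame`.
#' @return character vector (`"mild_moderate"`, `"severe"`, `"unknown"`)
#'   named by sample id.
#' @export
severity_group <- function(cl) {
  .check_clinical(cl)
  fvc <- if ("fvc_pct" %in% names(cl)) cl$fvc_pct else NA_real_
  dlco <- if ("dlco_pct" %in% names(cl)) cl$dlco_pct else NA_real_
  mild <- (!is.na(fvc) & fvc >= 55) | (!is.na(dlco) & dlco >= 40)
  unknown <- is.na(fvc) & is.na(dlco)
  out <- ifelse(unknown, "unknown", ifelse(mild, "mild_moderate", "severe"))
  names(out) <- cl$sample_id
  out
}

#' Fit PCA on disease samples and project all samples
#'
#' Principal components are computed from the disease samples only — so the
#' axes capture variation among patients, not the patient-vs-control
#' contrast — and every sample (control and disease) is projected onto them.
#' Centering uses the disease-sample gene means.
#'
#' @param disease_m genes x disease-samples matrix.
#' @param all_m genes x all-samples matrix; same genes, same order; disease
#'   samples must be a subset of its columns.
#' @param n_components number of components to return; at most
#'   `min(n_genes, n_disease - 1)`.
#' @return list with `model` (`loadings` genes x components, `centers`,
#'   `explained` variance fractions) and `scores` (all samples x components).
#' @export
fit_pca_project <- function(disease_m, all_m, n_components) {
  .check_expression_matrix(disease_m, "disease_m")
  .check_expression_matrix(all_m, "all_m")
  if (!identical(rownames(disease_m), rownames(all_m))) {
    stop("disease and full matrices must share identical, ordered gene ids")
  }
  if (!all(colnames(disease_m) %in% colnames(all_m))) {
    stop("disease samples must be a subset of the full matrix samples")
  }
  max_comp <- min(nrow(disease_m), ncol(disease_m) - 1L)
  if (n_components > max_comp || n_components < 1L) {
    stop("n_components must be in [1, ", max_comp, "]")
  }
  fit <- stats::prcomp(t(disease_m), center = TRUE, scale. = FALSE)
  expl <- fit$sdev^2 / sum(fit$sdev^2)
  loadings <- fit$rotation[, seq_len(n_components), drop = FALSE]
  scores <- sweep(t(all_m), 2L, fit$center, "-") %*% loadings
  list(
    model = list(loadings = loadings, centers = fit$center,
                 explained = expl[seq_len(n_components)],
                 explained_all = expl),
    scores = scores
  )
}

#' Ward hierarchical clustering cut at k clusters
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances (`hclust` method `"ward.D2"`, which implements the
#' Ward criterion on unsquared distances), cut into `k` groups.
#'
#' @param points samples x dims numeric matrix.
#' @param k number of clusters, `1 <= k <= nrow(points)`.
#' @return integer cluster labels (1..k) named by rownames of `points`.
#' @export
ward_cluster <- function(points, k) {
  points <- as.matrix(points)
  if (k < 1L) stop("k must be >= 1")
  if (k > nrow(points)) stop("k cannot exceed the number of samples")
  hc <- stats::hclust(stats::dist(points), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Clinical separation of a patient clustering
#'
#' Quantifies how well a clustering separates lung function: for each measure
#' (FEV1, FVC, DLCO % predicted) the range of cluster means is divided by the
#' pooled within-cluster standard deviation, and the available measures are
#' averaged. Samples missing a measure are dropped for that measure;
#' measures with no data (or no within-cluster variance information) are
#' skipped.
#'
#' @param labels cluster labels named by sample id (disease samples).
#' @param cl clinical `data.frame` covering those samples.
#' @param measures clinical columns to use.
#' @return nonnegative scalar; larger = clusters more clinically distinct.
#' @export
clinical_separation_score <- function(labels, cl,
                                      measures = c("fev1_pct", "fvc_pct",
                                                   "dlco_pct")) {
  .check_clinical(cl)
  if (length(unique(labels)) < 2L) {
    stop("separation score needs >= 2 clusters")
  }
  cl_idx <- match(names(labels), cl$sample_id)
  if (anyNA(cl_idx)) stop("labels contain sample ids absent from the table")
  per_measure <- vapply(measures, function(msr) {
    if (!msr %in% names(cl)) return(NA_real_)
    x <- cl[[msr]][cl_idx]
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    grp <- split(x[ok], labels[ok])
    grp <- grp[lengths(grp) > 0L]
    if (length(grp) < 2L) return(NA_real_)
    mns <- vapply(grp, mean, numeric(1))
    df_within <- sum(lengths(grp) - 1L)
    if (df_within == 0L) return(NA_real_)
    ss_within <- sum(vapply(grp, function(g) sum((g - mean(g))^2),
                            numeric(1)))
    pooled_sd <- sqrt(ss_within / df_within)
    if (pooled_sd == 0) {
      if (diff(range(mns)) == 0) return(0)
      return(Inf)
    }
    diff(range(mns)) / pooled_sd
  }, numeric(1))
  per_measure <- per_measure[!is.na(per_measure)]
  if (length(per_measure) == 0L) {
    stop("no clinical measure with usable data for any cluster")
  }
  mean(per_measure)
}

#' Choose the cluster count by clinical separation
#'
#' For each candidate k the disease samples are Ward-clustered and scored
#' with [clinical_separation_score()]; the selected k is the smallest one
#' whose score comes within `tolerance` (relative) of the best score over the
#' whole range — the smallest number of clusters that attains (essentially)
#' maximal separation of the average lung-function measures.
#'
#' @param points samples x dims matrix fed to Ward clustering (rownames =
#'   sample ids).
#' @param cl clinical `data.frame`.
#' @param k_min,k_max candidate range (defaults 2 and 10).
#' @param tolerance relative slack on the maximal score (default 0.05).
#' @param measures clinical columns scored.
#' @return list with `k` (selected count) and `trace` (data.frame of k,
#'   score).
#' @export
select_cluster_count <- function(points, cl, k_min = 2L, k_max = 10L,
                                 tolerance = 0.05,
                                 measures = c("fev1_pct", "fvc_pct",
                                              "dlco_pct")) {
  points <- as.matrix(points)
  if (k_min < 2L) stop("k_min must be >= 2")
  if (k_max < k_min) stop("k_max must be >= k_min")
  k_max <- min(k_max, nrow(points))
  ks <- seq.int(k_min, k_max)
  hc <- stats::hclust(stats::dist(points), method = "ward.D2")
  scores <- vapply(ks, function(k) {
    labels <- stats::cutree(hc, k = k)
    tryCatch(clinical_separation_score(labels, cl, measures),
             error = function(e) NA_real_)
  }, numeric(1))
  trace <- data.frame(k = ks, score = scores)
  ok <- is.finite(scores)
  if (!any(ok)) stop("no candidate k produced a valid separation score")
  best <- max(scores[ok])
  eligible <- ok & scores >= (1 - tolerance) * best
  list(k = ks[which(eligible)[1L]], trace = trace)
}

#' Order clusters from mildest to most severe
#'
#' Renames cluster labels to C1..Ck so that mean % predicted DLCO is
#' nonincreasing in the label index (ties broken by FVC, then FEV1): C1 is
#' the mildest cluster, Ck the most severe.
#'
#' @param labels cluster labels named by sample id.
#' @param cl clinical `data.frame`.
#' @return list with `labels` (named character vector, values `"C1"`...),
#'   `k`, and `cluster_means` (data.frame of per-cluster mean measures in
#'   C1..Ck order).
#' @export
order_clusters_by_severity <- function(labels, cl) {
  .check_clinical(cl)
  cl_idx <- match(names(labels), cl$sample_id)
  if (anyNA(cl_idx)) stop("labels contain sample ids absent from the table")
  uniq <- sort(unique(labels))
  mean_of <- function(msr, lab) {
    if (!msr %in% names(cl)) return(NA_real_)
    x <- cl[[msr]][cl_idx][labels == lab]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }
  key <- data.frame(
    old = uniq,
    dlco = vapply(uniq, function(l) mean_of("dlco_pct", l), numeric(1)),
    fvc = vapply(uniq, function(l) mean_of("fvc_pct", l), numeric(1)),
    fev1 = vapply(uniq, function(l) mean_of("fev1_pct", l), numeric(1))
  )
  ord <- order(-key$dlco, -key$fvc, -key$fev1)
  key <- key[ord, , drop = FALSE]
  key$new <- paste0("C", seq_len(nrow(key)))
  new_labels <- key$new[match(labels, key$old)]
  names(new_labels) <- names(labels)
  list(labels = new_labels, k = length(uniq),
       cluster_means = data.frame(cluster = key$new, mean_dlco = key$dlco,
                                  mean_fvc = key$fvc, mean_fev1 = key$fev1))
}

#' Discover patient subgroups from expression and clinical data
#'
#' The full subtype-discovery step: select the most variable genes, fit PCA on
#' disease samples (projecting all samples), retain components to a cumulative
#' explained-variance target, Ward-cluster the disease-sample scores, select
#' the cluster count by clinical separation, and order the clusters by
#' severity.
#'
#' @param m preprocessed (log2, median-centered) genes x samples matrix.
#' @param cl clinical `data.frame` covering all samples.
#' @param variance_fraction fraction of most-variable genes used (default
#'   0.25).
#' @param explained_variance cumulative explained-variance target deciding how
#'   many components feed clustering (default 0.9).
#' @param k_min,k_max,tolerance passed to [select_cluster_count()].
#' @return list with `assignment` (see [order_clusters_by_severity()]),
#'   `selection` (k + trace), `pca`, and `scores` for all samples.
#' @export
cluster_patients <- function(m, cl, variance_fraction = 0.25,
                             explained_variance = 0.9,
                             k_min = 2L, k_max = 10L, tolerance = 0.05) {
  .check_expression_matrix(m)
  .check_clinical(cl)
  disease_ids <- cl$sample_id[cl$group == "disease"]
  disease_ids <- intersect(colnames(m), disease_ids)
  if (length(disease_ids) < max(3L, k_min)) {
    stop("too few disease samples to cluster")
  }
  disease_m <- m[, disease_ids, drop = FALSE]
  genes <- top_variable_genes(disease_m, variance_fraction)
  disease_sub <- disease_m[genes, , drop = FALSE]
  all_sub <- m[genes, , drop = FALSE]
  # decide component count from full spectrum, then refit/project
  full <- fit_pca_project(disease_sub, all_sub,
                          min(nrow(disease_sub), ncol(disease_sub) - 1L))
  n_comp <- which(cumsum(full$model$explained_all) >= explained_variance)[1L]
  if (is.na(n_comp)) n_comp <- length(full$model$explained_all)
  scores <- full$scores[, seq_len(n_comp), drop = FALSE]
  disease_scores <- scores[disease_ids, , drop = FALSE]
  sel <- select_cluster_count(disease_scores, cl, k_min = k_min,
                              k_max = k_max, tolerance = tolerance)
  labels <- ward_cluster(disease_scores, sel$k)
  assignment <- order_clusters_by_severity(labels, cl)
  list(assignment = assignment, selection = sel,
       pca = list(model = full$model, n_components = n_comp,
                  genes = genes),
       scores = scores)
}
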