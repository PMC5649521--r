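#' Default end-to-end run configuration
#'
#' Returns the full option list consumed by [run_pipeline()], with every
#' stage at its default. Override entries as needed, e.g.
#' `cfg <- default_run_config(); cfg$clustering$k_max <- 8`.
#'
#' @param seed master seed for the run (default 17); every stochastic step
#'   (simulation, fold assignment) derives from it.
#' @return nested list of stage options.
#' @export
default_run_config <- function(seed = 17L) {
  list(
    seed = as.integer(seed),
    simulate = list(enabled = TRUE),   # or supply data$expr / data$clinical
    data = list(expr = NULL, clinical = NULL, annotation = NULL,
                training = NULL, secreted = NULL, validation = NULL),
    preprocess = list(aggregate = "median", log2_offset = 0),
    clustering = list(variance_fraction = 0.25, explained_variance = 0.9,
                      k_min = 2L, k_max = 10L, tolerance = 0.05),
    de = list(fdr_max = 0.05, lfc_min = 1),
    signatures = list(n_modules = 3L),
    classifier = list(l2_strength = 1, folds = 2L, min_sensitivity = 0.9),
    prioritization = list(top_fraction = 0.10),
    panel = list(k_max = 50L, min_specificity = 0.8, min_sensitivity = 0.9,
                 calibrate = "sensitivity", recalibrate = TRUE),
    out_dir = NULL
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the complete stratification workflow
#'
#' Orchestrates preprocess -> patient clustering -> per-cluster differential
#' expression -> signature construction -> classifier validation ->
#' candidate prioritization -> biomarker panel search, from either a
#' simulated cohort (default) or user-supplied matrices. Returns a
#' machine-readable report with one summary per stage; when `out_dir` is set
#' the stage artifacts (labels CSV, DE table TSV, signature GMT, JSON
#' reports) are written there as plain files.
#'
#' @param config option list from [default_run_config()]; partial lists are
#'   filled with defaults.
#' @return a report list with elements `preprocess`, `clustering`, `de`,
#'   `signatures`, `classifier`, `prioritization`, `panel`, plus `seed` and
#'   (for simulated runs) `truth`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- utils::modifyList(default_run_config(), config)
  seed <- cfg$seed
  report <- list(seed = seed)

  # --- input / simulation ---------------------------------------------------
  if (!is.null(cfg$data$expr)) {
    expr <- cfg$data$expr
    clinical <- cfg$data$clinical
    truth <- NULL
    ann <- list(db = cfg$data$annotation,
                training = cfg$data$training,
                secreted = cfg$data$secreted)
    validation <- cfg$data$validation
  } else {
    sim_cfg <- .stage("simulate", do.call(
      synthetic_config,
      cfg$simulate[setdiff(names(cfg$simulate), "enabled")]))
    cohort <- .stage("simulate", generate_cohort(sim_cfg, seed = seed))
    expr <- cohort$expr
    clinical <- cohort$clinical
    truth <- cohort$truth
    ann_raw <- generate_annotation_db(truth, seed = seed)
    ann <- list(db = ann_raw$db,
                training = ann_raw$training[[1L]]$genes,
                secreted = ann_raw$secreted[[1L]]$genes)
    validation <- generate_cohort(sim_cfg, seed = seed + 7919L)
    report$truth <- list(K = truth$config$K,
                         n_core = length(truth$core_genes),
                         n_advanced = length(truth$advanced_genes))
  }

  # --- preprocess -----------------------------------------------------------
  m <- .stage("preprocess", {
    m <- aggregate_duplicate_genes(expr, method = cfg$preprocess$aggregate)
    if (cfg$preprocess$log2_offset > 0) {
      m <- log2_transform(m, cfg$preprocess$log2_offset)
    }
    median_center_genes(m)
  })
  report$preprocess <- list(n_genes = nrow(m), n_samples = ncol(m))

  # --- clustering -----------------------------------------------------------
  clust <- .stage("clustering", cluster_patients(
    m, clinical,
    variance_fraction = cfg$clustering$variance_fraction,
    explained_variance = cfg$clustering$explained_variance,
    k_min = cfg$clustering$k_min, k_max = cfg$clustering$k_max,
    tolerance = cfg$clustering$tolerance))
  labels <- clust$assignment$labels
  report$clustering <- list(k = clust$assignment$k,
                            trace = clust$selection$trace,
                            cluster_sizes = as.list(table(labels)))

  # --- differential expression ---------------------------------------------
  groups <- stats::setNames(rep("control", ncol(m)), colnames(m))
  groups[names(labels)] <- labels
  cluster_sizes <- table(labels)
  usable <- names(cluster_sizes)[cluster_sizes >= 2L]
  if (length(usable) < length(cluster_sizes)) {
    warning("cluster(s) with a single sample excluded from differential ",
            "expression: ",
            paste(setdiff(names(cluster_sizes), usable), collapse = ", "))
  }
  de <- .stage("de", run_cluster_de(m, groups, clusters = sort(usable),
                                    fdr_max = cfg$de$fdr_max,
                                    lfc_min = cfg$de$lfc_min))
  sets <- deg_sets(de)
  names(sets) <- sub(" vs control$", "", names(sets))
  report$de <- list(deg_counts = lapply(sets, length),
                    union_size = length(unique(unlist(sets))))

  # --- signatures -----------------------------------------------------------
  sig <- .stage("signatures", {
    core <- core_set(sets, de = de)
    # most severe cluster among those contrasted (Ck unless degenerate)
    most_severe <- names(sets)[which.max(as.integer(sub("^C", "",
                                                        names(sets))))]
    advanced <- unique_set(sets, most_severe, name = "advanced", de = de)
    union_genes <- unique(unlist(sets))
    modules <- if (length(union_genes) >= cfg$signatures$n_modules) {
      gene_modules(m[union_genes, , drop = FALSE],
                   n_modules = cfg$signatures$n_modules)
    } else {
      NULL
    }
    list(core = core, advanced = advanced, modules = modules)
  })
  report$signatures <- list(
    core_size = length(sig$core$genes),
    advanced_size = length(sig$advanced$genes),
    module_sizes = if (is.null(sig$modules)) NULL else
      as.list(table(sig$modules)))

  # --- classifier validation ------------------------------------------------
  clf_res <- .stage("classifier", {
    if (length(sig$core$genes) < 2L) stop("core signature too small")
    sample_groups <- stats::setNames(clinical$group, clinical$sample_id)
    m_sig <- m[sig$core$genes, , drop = FALSE]
    cv <- cross_validate(m_sig, sample_groups,
                         folds = cfg$classifier$folds, seed = seed,
                         l2_strength = cfg$classifier$l2_strength,
                         min_sensitivity = cfg$classifier$min_sensitivity)
    clf <- build_signature_classifier(
      m, sample_groups, sig$core$genes,
      l2_strength = cfg$classifier$l2_strength,
      min_sensitivity = cfg$classifier$min_sensitivity, seed = seed)
    held_out <- NULL
    if (!is.null(validation)) {
      vm <- median_center_genes(validation$expr)
      vg <- stats::setNames(validation$clinical$group,
                            validation$clinical$sample_id)
      genes <- restrict_signature(sig$core$genes, list(vm))
      clf_v <- build_signature_classifier(
        m, sample_groups, genes,
        l2_strength = cfg$classifier$l2_strength,
        min_sensitivity = cfg$classifier$min_sensitivity, seed = seed)
      held_out <- evaluate(clf_v, vm, vg, cohort = "validation")
    }
    list(clf = clf, cv = cv, held_out = held_out)
  })
  report$classifier <- list(
    cv_accuracy = mean(vapply(clf_res$cv, `[[`, numeric(1), "accuracy")),
    threshold = clf_res$clf$threshold,
    validation = if (is.null(clf_res$held_out)) NULL else
      clf_res$held_out[c("auc", "sensitivity", "specificity", "accuracy")])

  # --- prioritization -------------------------------------------------------
  prio <- NULL
  if (!is.null(ann$db) && !is.null(ann$training)) {
    prio <- .stage("prioritization", {
      sig_genes <- unique(c(sig$core$genes, sig$advanced$genes))
      candidates <- setdiff(sig_genes, ann$training)
      if (length(candidates) == 0L) stop("no unknown candidate genes")
      prioritize_candidates(sig_genes, de, ann$training, ann$db,
                            universe = rownames(m),
                            top_fraction = cfg$prioritization$top_fraction)
    })
    report$prioritization <- list(
      n_candidates = nrow(prio),
      top_genes = prio$gene[prio$selected])
  }

  # --- biomarker panel ------------------------------------------------------
  panel <- NULL
  if (!is.null(ann$secreted)) {
    panel <- .stage("panel", {
      candidates <- intersect(ann$secreted, rownames(m))
      if (length(candidates) == 0L) stop("no secreted candidate genes")
      sample_groups <- stats::setNames(clinical$group, clinical$sample_id)
      m_cand <- m[candidates, , drop = FALSE]
      ref <- fit_minmax(m_cand)
      clf0 <- train_logistic(apply_minmax(m_cand, ref), sample_groups,
                             l2_strength = cfg$panel$l2_strength %||% 1,
                             seed = seed)
      ordered <- rank_by_coefficient(clf0)
      eval_m <- NULL
      eval_labels <- NULL
      if (!is.null(validation)) {
        vm <- median_center_genes(validation$expr)
        if (all(ordered %in% rownames(vm))) {
          eval_m <- vm
          eval_labels <- stats::setNames(validation$clinical$group,
                                         validation$clinical$sample_id)
        }
      }
      nested_panel_search(
        m, sample_groups, ordered,
        k_max = min(cfg$panel$k_max, length(ordered)),
        min_specificity = cfg$panel$min_specificity,
        min_sensitivity = cfg$panel$min_sensitivity,
        calibrate = cfg$panel$calibrate,
        eval_m = eval_m, eval_labels = eval_labels,
        recalibrate = isTRUE(cfg$panel$recalibrate), seed = seed)
    })
    report$panel <- list(criterion_met = panel$criterion_met,
                         selected_k = panel$selected_k,
                         panel = panel$panel)
  }

  # --- artifacts ------------------------------------------------------------
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(data.frame(sample_id = names(labels), cluster = labels),
                     file.path(cfg$out_dir, "cluster_labels.csv"),
                     row.names = FALSE)
    utils::write.table(clust$selection$trace,
                       file.path(cfg$out_dir, "cluster_selection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_de_table(de, file.path(cfg$out_dir, "de_table.tsv"))
    write_gmt(signatures_to_collection(list(sig$core, sig$advanced)),
              file.path(cfg$out_dir, "signatures.gmt"))
    report_out <- report
    report_out$clustering$trace <- NULL
    write_json_report(report_out, file.path(cfg$out_dir, "report.json"))
  }

  report$artifacts <- list(de = de, signatures = sig, clustering = clust,
                           classifier = clf_res, prioritization = prio,
                           panel = panel)
  report
}
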