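#' Configuration for a synthetic IPF-like cohort
#'
#' Defines the generative model used throughout the test suite: a small
#' healthy-control arm plus K latent disease subgroups; module-structured
#' up/down expression effects (a core module perturbed in every subgroup,
#' three mixed-pattern co-expression modules, an "advanced" module perturbed
#' only in the most severe subgroup, and a weak disease-wide secreted
#' biomarker module); gene-wise variances drawn from a scaled
#' inverse-chi-square prior so the empirical-Bayes machinery sees its own
#' assumptions; and lung-function measures whose subgroup means decline with
#' severity.
#'
#' Default scale is 2,000 genes x (12 controls + 96 patients in K = 6
#' subgroups of 16) — structured like the study cohort but small enough for
#' seconds-scale simulation; `paper_scale = TRUE` switches to 14,110 genes x
#' (12 + 131) samples.
#'
#' @param n_genes total gene count.
#' @param n_controls healthy-control sample count.
#' @param subgroup_sizes disease sample count per subgroup (length K,
#'   mildest first).
#' @param effect module effect size in log2 units (default 2).
#' @param biomarker_effect effect of each planted secreted biomarker in the
#'   subgroups it covers, log2 units (default 1.7).
#' @param biomarker_coverage number of consecutive subgroups each planted
#'   biomarker is informative for (default 2, assigned cyclically across the
#'   11 biomarkers). Because no single biomarker covers every subgroup, a
#'   sensitivity floor over the whole cohort can only be met by a panel that
#'   jointly covers all subgroups — individually insufficient, jointly
#'   informative, like the secreted markers the panel search is meant to
#'   find.
#' @param d0,s02 variance-prior degrees of freedom and scale;
#'   `sigma_g^2 ~ d0 * s02 / chisq(d0)` (defaults 16 and 0.25: typical
#'   residual SD ~0.5 on the log2 scale with moderate gene-to-gene spread).
#' @param modules optional named list of
#'   `list(n = gene count, pattern = length-K multiplier on `effect`)`;
#'   the default (for K = 6) plants core up/down, Gm-style mixed patterns and
#'   an advanced (most-severe-only) module.
#' @param clinical optional list with `disease_means` (3 x K matrix, rows
#'   fev1/fvc/dlco), `disease_sd`, `control_means`, `control_sd`.
#' @param n_secreted_null number of uninformative genes added to the
#'   secreted/BALF annotation alongside the 11 planted biomarkers
#'   (default 49, for 60 candidates).
#' @param n_known number of core genes exported as "known" disease genes
#'   (training set; default 15).
#' @param n_planted_candidates core genes set up to be recoverable by
#'   knowledge-based prioritization: annotated with the training set's
#'   disease-like terms and boosted in effect (default 10).
#' @param candidate_boost multiplier on `effect` for the planted candidates
#'   (default 1.5), so they rank highly on fold change as well as
#'   similarity.
#' @param paper_scale use the full study dimensions instead of the test
#'   scale.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 2000L, n_controls = 12L,
                             subgroup_sizes = rep(16L, 6L),
                             effect = 2, biomarker_effect = 1.7,
                             biomarker_coverage = 2L,
                             d0 = 16, s02 = 0.25,
                             modules = NULL, clinical = NULL,
                             n_secreted_null = 49L, n_known = 15L,
                             n_planted_candidates = 10L,
                             candidate_boost = 1.5,
                             paper_scale = FALSE) {
  if (paper_scale) {
    n_genes <- 14110L
    n_controls <- 12L
    subgroup_sizes <- c(22L, 22L, 22L, 22L, 22L, 21L)
  }
  K <- length(subgroup_sizes)
  if (any(subgroup_sizes < 2L) || n_controls < 2L || n_genes < 10L) {
    stop("invalid config: need >= 2 samples per group and >= 10 genes")
  }
  if (d0 <= 0 || s02 <= 0) stop("variance prior requires d0 > 0, s02 > 0")
  if (is.null(modules)) {
    if (K != 6L) {
      stop("default module patterns are defined for K = 6; supply `modules`")
    }
    modules <- list(
      core_up = list(n = 80L, pattern = rep(1, 6)),
      core_down = list(n = 40L, pattern = rep(-1, 6)),
      gm1 = list(n = 150L, pattern = c(1, 0, 1, 1, 0.5, 1)),
      gm2 = list(n = 150L, pattern = c(1, 0, 1, 0, 1, 1)),
      gm3 = list(n = 150L, pattern = c(-0.5, 0, -1, -0.5, -1, -1)),
      # every patient cluster also carries its own unique DEG block; the
      # most severe one is the advanced signature
      unique1 = list(n = 60L, pattern = c(1, 0, 0, 0, 0, 0)),
      unique2 = list(n = 60L, pattern = c(0, 1, 0, 0, 0, 0)),
      unique3 = list(n = 60L, pattern = c(0, 0, 1, 0, 0, 0)),
      unique4 = list(n = 60L, pattern = c(0, 0, 0, 1, 0, 0)),
      unique5 = list(n = 60L, pattern = c(0, 0, 0, 0, 1, 0)),
      advanced = list(n = 80L, pattern = c(0, 0, 0, 0, 0, 1))
    )
  }
  for (mod in modules) {
    if (length(mod$pattern) != K) stop("module pattern length must equal K")
  }
  modules <- lapply(modules, function(mod) {
    mod$n <- as.integer(mod$n)
    mod
  })
  n_module_genes <- sum(vapply(modules, `[[`, integer(1), "n")) + 11L +
    n_secreted_null
  if (n_module_genes > n_genes) {
    stop("modules + annotations need ", n_module_genes, " genes but only ",
         n_genes, " configured")
  }
  if (is.null(clinical)) {
    clinical <- list(
      disease_means = rbind(
        fev1_pct = seq(85, 50, length.out = K),
        fvc_pct = seq(80, 45, length.out = K),
        dlco_pct = seq(75, 35, length.out = K)
      ),
      disease_sd = c(fev1_pct = 4, fvc_pct = 4, dlco_pct = 4),
      control_means = c(fev1_pct = 94.33, fvc_pct = 91.75, dlco_pct = 97),
      control_sd = c(fev1_pct = 9.86, fvc_pct = 7.44, dlco_pct = 21.3)
    )
  }
  if (any(apply(clinical$disease_means, 1L, function(x) any(diff(x) > 0)))) {
    stop("disease clinical means must be nonincreasing with severity")
  }
  structure(list(
    n_genes = as.integer(n_genes), n_controls = as.integer(n_controls),
    subgroup_sizes = as.integer(subgroup_sizes), K = K,
    effect = effect, biomarker_effect = biomarker_effect,
    biomarker_coverage = as.integer(biomarker_coverage),
    d0 = d0, s02 = s02, modules = modules, clinical = clinical,
    n_secreted_null = as.integer(n_secreted_null),
    n_known = as.integer(n_known),
    n_planted_candidates = as.integer(n_planted_candidates),
    candidate_boost = candidate_boost
  ), class = "synthetic_config")
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws expression as `baseline_g + effect_{g, subgroup} + N(0, sigma_g^2)`
#' with `sigma_g^2` from the configured scaled inverse-chi-square prior;
#' control samples carry zero effects. Lung-function measures are drawn per
#' subgroup from the configured means/SDs. Deterministic given `seed`.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed.
#' @return list with `expr` (genes x samples, log2-scale intensities),
#'   `clinical` (see [clinical_table()]) and `truth` (subgroup labels,
#'   per-gene module and effect matrix, true core/advanced/secreted/known
#'   sets, variance parameters).
#' @export
generate_cohort <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "synthetic_config"))
  .with_seed(seed, {
    K <- cfg$K
    n_dis <- sum(cfg$subgroup_sizes)
    n <- cfg$n_controls + n_dis
    gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
    sample_ids <- c(sprintf("CTRL%03d", seq_len(cfg$n_controls)),
                    sprintf("IPF%03d", seq_len(n_dis)))
    subgroup <- rep(seq_len(K), cfg$subgroup_sizes)

    # per-gene module membership and effect matrix (genes x K)
    module <- rep("none", cfg$n_genes)
    effects <- matrix(0, nrow = cfg$n_genes, ncol = K,
                      dimnames = list(gene_ids, paste0("S", seq_len(K))))
    cursor <- 0L
    for (mod_name in names(cfg$modules)) {
      mod <- cfg$modules[[mod_name]]
      idx <- cursor + seq_len(mod$n)
      module[idx] <- mod_name
      effects[idx, ] <- matrix(cfg$effect * mod$pattern, nrow = mod$n,
                               ncol = K, byrow = TRUE)
      cursor <- cursor + mod$n
    }
    bm_idx <- cursor + seq_len(11L)
    module[bm_idx] <- "biomarker"
    for (j in seq_along(bm_idx)) {
      covered <- (j - 1L + seq_len(cfg$biomarker_coverage) - 1L) %% K + 1L
      effects[bm_idx[j], covered] <- cfg$biomarker_effect
    }
    cursor <- cursor + 11L
    sec_null_idx <- cursor + seq_len(cfg$n_secreted_null)
    module[sec_null_idx] <- "secreted_null"

    # known training genes and planted prioritization candidates live in the
    # core module; planted candidates get a fold-change boost so they rank
    # highly on both prioritization criteria
    core_idx <- which(module %in% c("core_up", "core_down"))
    n_known <- min(cfg$n_known, length(core_idx))
    known_idx <- core_idx[seq_len(n_known)]
    n_planted <- min(cfg$n_planted_candidates, length(core_idx) - n_known)
    planted_idx <- core_idx[n_known + seq_len(n_planted)]
    effects[planted_idx, ] <- effects[planted_idx, ] * cfg$candidate_boost

    sigma2 <- cfg$d0 * cfg$s02 / stats::rchisq(cfg$n_genes, df = cfg$d0)
    # planted biomarkers carry the typical residual variance, so panel
    # behavior reflects their joint weak effects, not a variance lottery
    sigma2[bm_idx] <- cfg$s02
    baseline <- stats::runif(cfg$n_genes, 4, 12)
    group_of_sample <- c(rep(0L, cfg$n_controls), subgroup)
    mean_mat <- baseline +
      cbind(0, effects)[, group_of_sample + 1L, drop = FALSE]
    expr <- mean_mat + matrix(stats::rnorm(cfg$n_genes * n, sd = sqrt(sigma2)),
                              nrow = cfg$n_genes, ncol = n)
    dimnames(expr) <- list(gene_ids, sample_ids)

    clin_cfg <- cfg$clinical
    draw_measure <- function(msr) {
      ctrl <- stats::rnorm(cfg$n_controls, clin_cfg$control_means[[msr]],
                           clin_cfg$control_sd[[msr]])
      dis <- stats::rnorm(n_dis, clin_cfg$disease_means[msr, subgroup],
                          clin_cfg$disease_sd[[msr]])
      pmin(pmax(c(ctrl, dis), 0), 200)
    }
    clinical <- clinical_table(
      sample_id = sample_ids,
      group = c(rep("control", cfg$n_controls), rep("disease", n_dis)),
      fev1_pct = draw_measure("fev1_pct"),
      fvc_pct = draw_measure("fvc_pct"),
      dlco_pct = draw_measure("dlco_pct"),
      age = c(stats::rnorm(cfg$n_controls, 64.1, 8.2),
              stats::rnorm(n_dis, 62.6, 12.2)),
      sex = sample(c("male", "female"), n, replace = TRUE),
      smoking = sample(c("ever", "never"), n, replace = TRUE)
    )

    deg_mask <- abs(effects) >= 1  # module genes expected to pass the filter
    core_genes <- gene_ids[rowSums(deg_mask) == K]
    advanced_genes <- gene_ids[deg_mask[, K] & rowSums(deg_mask) == 1L]
    known_genes <- gene_ids[known_idx]
    truth <- list(
      subgroup = stats::setNames(subgroup, sample_ids[-seq_len(cfg$n_controls)]),
      groups = stats::setNames(
        c(rep("control", cfg$n_controls), paste0("S", subgroup)), sample_ids),
      module = stats::setNames(module, gene_ids),
      effects = effects,
      core_genes = core_genes,
      advanced_genes = advanced_genes,
      biomarker_genes = gene_ids[bm_idx],
      secreted_genes = gene_ids[c(bm_idx, sec_null_idx)],
      known_genes = known_genes,
      planted_candidates = gene_ids[planted_idx],
      sigma2 = stats::setNames(sigma2, gene_ids),
      config = cfg, seed = seed
    )
    list(expr = expr, clinical = clinical, truth = truth)
  })
}

#' Generate a synthetic annotation database
#'
#' Builds term-to-gene annotation categories consistent with the cohort's
#' ground truth: each category carries one planted "disease-like" term
#' containing all known (training) genes plus the planted candidate genes —
#' so the planted term is enriched in the training set and annotates the
#' candidates meant to rank highly — plus random background terms. Also
#' returns the training and secreted gene sets as collections ready for GMT
#' export. Deterministic given `seed`.
#'
#' @param truth the `truth` element of [generate_cohort()].
#' @param n_background_terms random terms per category (default 20).
#' @param term_size gene count of each background term (default 25).
#' @param seed integer seed.
#' @return list with `db` (an [annotation_db()]), `training`
#'   (known-gene [gene_set_collection()]) and `secreted`.
#' @export
generate_annotation_db <- function(truth, n_background_terms = 20L,
                                   term_size = 25L, seed = 1L) {
  .with_seed(seed + 1000L, {
    gene_ids <- names(truth$module)
    planted_genes <- unique(c(truth$known_genes, truth$planted_candidates))
    categories <- c("biological_process", "cellular_component",
                    "human_phenotype", "mouse_phenotype", "pathway",
                    "disease")
    db <- lapply(categories, function(cat) {
      sets <- list()
      sets[[paste0(cat, "_fibrosis_like")]] <- list(
        description = "planted disease-like term", genes = planted_genes)
      for (i in seq_len(n_background_terms)) {
        sets[[sprintf("%s_bg%02d", cat, i)]] <- list(
          description = "background term",
          genes = sample(gene_ids, term_size))
      }
      gene_set_collection(sets)
    })
    names(db) <- categories
    list(
      db = annotation_db(db),
      training = gene_set_collection(list(known_disease_genes = list(
        description = "planted known disease genes",
        genes = truth$known_genes))),
      secreted = gene_set_collection(list(secreted_balf = list(
        description = "planted secreted/BALF annotation",
        genes = truth$secreted_genes)))
    )
  })
}
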