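#' Per-gene two-group linear models
#'
#' Fits, for every gene, the two-group model behind the moderated t-statistic:
#' effect = mean(A) - mean(B) (log2 fold change when the data are log2),
#' pooled residual variance s2 on d = nA + nB - 2 degrees of freedom, and the
#' unscaled variance of the effect v = 1/nA + 1/nB.
#'
#' @param m genes x samples matrix (log2 scale).
#' @param groups character vector of group labels, named by sample id or
#'   aligned with `colnames(m)`.
#' @param contrast length-2 character vector `c(groupA, groupB)`; the effect
#'   is A minus B.
#' @return data.frame with columns gene, diff, s2, d, v.
#' @export
fit_gene_models <- function(m, groups, contrast) {
  .check_expression_matrix(m)
  if (!is.null(names(groups))) {
    groups <- groups[colnames(m)]
  } else if (length(groups) != ncol(m)) {
    stop("groups must be named by sample id or have one entry per column")
  }
  stopifnot(length(contrast) == 2L)
  a_idx <- which(!is.na(groups) & groups == contrast[1L])
  b_idx <- which(!is.na(groups) & groups == contrast[2L])
  if (length(a_idx) < 2L || length(b_idx) < 2L) {
    stop("each contrast group needs >= 2 samples (",
         contrast[1L], ": ", length(a_idx), ", ",
         contrast[2L], ": ", length(b_idx), ")")
  }
  ma <- m[, a_idx, drop = FALSE]
  mb <- m[, b_idx, drop = FALSE]
  mean_a <- rowMeans(ma)
  mean_b <- rowMeans(mb)
  ss_a <- rowSums((ma - mean_a)^2)
  ss_b <- rowSums((mb - mean_b)^2)
  d <- length(a_idx) + length(b_idx) - 2L
  data.frame(
    gene = rownames(m),
    diff = mean_a - mean_b,
    s2 = (ss_a + ss_b) / d,
    d = d,
    v = 1 / length(a_idx) + 1 / length(b_idx),
    stringsAsFactors = FALSE
  )
}

# Newton inversion of the trigamma function (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Models the per-gene residual variances as draws from a scaled
#' inverse-chi-square prior with `d0` degrees of freedom and scale `s02`, and
#' estimates both hyperparameters by matching the first two moments of
#' log(s2) to those of a scaled F distribution (digamma/trigamma moment
#' equations). When the observed spread of log variances does not exceed what
#' sampling alone explains, the prior is degenerate: `d0 = Inf` and `s02` the
#' common variance implied by the mean of the log variances.
#'
#' @param s2 per-gene residual variances (>= 10 genes).
#' @param d residual degrees of freedom, a scalar or one value per gene.
#' @return an `eb_prior`: list with `d0` (possibly `Inf`) and `s02`.
#' @export
estimate_eb_prior <- function(s2, d) {
  if (all(s2 == 0, na.rm = TRUE)) {
    stop("all residual variances are zero; cannot estimate a variance prior")
  }
  d <- rep_len(d, length(s2))
  ok <- !is.na(s2) & s2 > 0 & d >= 1
  if (sum(ok) < 10L) stop("need >= 10 genes with positive variance and df >= 1")
  if (sum(ok) < length(s2)) {
    warning(length(s2) - sum(ok),
            " gene(s) with zero/invalid variance excluded from prior fit")
  }
  s2 <- s2[ok]
  d <- d[ok]
  z <- log(s2)
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(d / 2))
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  structure(list(d0 = d0, s02 = s02), class = "eb_prior")
}

#' Moderated t-statistic
#'
#' Shrinks each gene's residual variance toward the prior,
#' `s2_post = (d0 * s02 + d * s2) / (d0 + d)`, and tests the effect with
#' `t = diff / sqrt(s2_post * v)` on `d0 + d` degrees of freedom. With
#' `d0 = 0` this is the ordinary two-sample t; with `d0 = Inf` the posterior
#' variance is the prior scale and the reference distribution is normal.
#'
#' @param diff per-gene effect (difference of group means).
#' @param s2 per-gene residual variance.
#' @param d residual degrees of freedom (scalar or per gene).
#' @param v unscaled effect variance (scalar or per gene), > 0.
#' @param prior an `eb_prior` (or `list(d0 =, s02 =)`).
#' @return data.frame with columns t, p (two-sided), df.
#' @export
moderated_t <- function(diff, s2, d, v, prior) {
  if (any(v <= 0)) stop("v must be positive")
  d0 <- prior$d0
  s02 <- prior$s02
  if (is.null(d0) || is.null(s02) || d0 < 0 || s02 <= 0) {
    stop("invalid eb prior")
  }
  d <- rep_len(d, length(diff))
  v <- rep_len(v, length(diff))
  if (is.infinite(d0)) {
    s2_post <- rep_len(s02, length(diff))
    df <- rep_len(Inf, length(diff))
  } else {
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
    df <- d0 + d
  }
  t_stat <- diff / sqrt(s2_post * v)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  data.frame(t = t_stat, p = p, df = df)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param p p-values in \[0, 1\].
#' @return BH-adjusted p-values (FDR), same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when its FDR-adjusted p-value is <= `fdr_max` and its
#' absolute log2 fold change is >= `lfc_min`; both thresholds are inclusive.
#'
#' @param de DE result data.frame with columns `lfc` and `q`.
#' @param fdr_max FDR ceiling (default 0.05).
#' @param lfc_min absolute log2 fold-change floor (default 1).
#' @return `de` with logical `deg` and character `direction` (`"up"`,
#'   `"down"`, `NA` for non-DEGs) columns set.
#' @export
call_degs <- function(de, fdr_max = 0.05, lfc_min = 1) {
  stopifnot(all(c("lfc", "q") %in% names(de)))
  de$deg <- de$q <= fdr_max & abs(de$lfc) >= lfc_min
  de$direction <- ifelse(de$deg, ifelse(de$lfc > 0, "up", "down"),
                         NA_character_)
  de
}

#' Differential expression for one contrast
#'
#' Runs the complete moderated-t workflow for one two-group contrast: fit the
#' per-gene models, estimate (or reuse) the variance prior, compute moderated
#' statistics, adjust with BH within the contrast, and flag DEGs.
#'
#' @param m genes x samples log2 matrix.
#' @param groups per-sample group labels (see [fit_gene_models()]).
#' @param contrast `c(groupA, groupB)`; log2 fold change is A minus B.
#' @param prior optional `eb_prior`; estimated from this contrast's residual
#'   variances when `NULL`.
#' @param fdr_max,lfc_min DEG thresholds (see [call_degs()]).
#' @return data.frame with gene, contrast, lfc, t, p, q, deg, direction.
#' @export
run_de_contrast <- function(m, groups, contrast, prior = NULL,
                            fdr_max = 0.05, lfc_min = 1) {
  fit <- fit_gene_models(m, groups, contrast)
  if (is.null(prior)) prior <- estimate_eb_prior(fit$s2, fit$d)
  mt <- moderated_t(fit$diff, fit$s2, fit$d, fit$v, prior)
  de <- data.frame(
    gene = fit$gene,
    contrast = paste(contrast[1L], "vs", contrast[2L]),
    lfc = fit$diff,
    t = mt$t,
    p = mt$p,
    q = bh_adjust(mt$p),
    stringsAsFactors = FALSE
  )
  call_degs(de, fdr_max = fdr_max, lfc_min = lfc_min)
}

#' Per-cluster differential expression against control
#'
#' One contrast per patient cluster versus the control group, BH-adjusted
#' within each contrast (the per-cluster DEG counts are reported per
#' comparison). Returns the row-bound DE table.
#'
#' @param m genes x samples log2 matrix.
#' @param groups per-sample labels mixing cluster names and `control`.
#' @param clusters cluster labels to contrast (default: all non-control
#'   labels, sorted).
#' @param control control label (default `"control"`).
#' @param fdr_max,lfc_min DEG thresholds.
#' @return data.frame as in [run_de_contrast()], one block per cluster.
#' @export
run_cluster_de <- function(m, groups, clusters = NULL, control = "control",
                           fdr_max = 0.05, lfc_min = 1) {
  if (is.null(names(groups)) && length(groups) != ncol(m)) {
    stop("groups must be named by sample id or aligned with columns")
  }
  if (is.null(clusters)) {
    clusters <- sort(setdiff(unique(groups[!is.na(groups)]), control))
  }
  do.call(rbind, lapply(clusters, function(cluster) {
    run_de_contrast(m, groups, c(cluster, control),
                    fdr_max = fdr_max, lfc_min = lfc_min)
  }))
}

#' Extract per-contrast DEG sets from a DE table
#'
#' @param de DE table with columns contrast, gene, deg.
#' @return named list: contrast -> character vector of DEG ids.
#' @export
deg_sets <- function(de) {
  stopifnot(all(c("gene", "contrast", "deg") %in% names(de)))
  lapply(split(de, de$contrast), function(block) block$gene[block$deg])
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance, computed from group means, SDs and sizes
#' as printed in a demographics table.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- if (se == 0) {
    if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    (m1 - m2) / se
  }
  list(t = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df = df))
}

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction, df = 1 — the test used to compare, e.g.,
#' sex proportions between groups.
#'
#' @param a,b,c,d nonnegative integer cell counts, rows = groups.
#' @return list with `chi2` and `p`.
#' @export
pearson_chi2_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  tab <- matrix(counts, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all row and column margins must be positive")
  }
  res <- stats::chisq.test(tab, correct = FALSE)
  list(chi2 = unname(res$statistic), p = unname(res$p.value))
}
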