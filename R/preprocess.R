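#' Aggregate duplicate gene rows
#'
#' Microarray exports typically carry several probes per gene symbol; the
#' analysis matrix needs one row per gene. Duplicate rows are collapsed
#' per sample with the median (default; robust to a single aberrant probe) or
#' the mean. Output genes keep first-occurrence order.
#'
#' @param m numeric matrix (genes x samples), rownames may repeat.
#' @param method `"median"` or `"mean"`.
#' @return matrix with unique rownames.
#' @export
aggregate_duplicate_genes <- function(m, method = c("median", "mean")) {
  method <- match.arg(method)
  .check_expression_matrix(m)
  genes <- rownames(m)
  if (!anyDuplicated(genes)) return(m)
  keep <- unique(genes)
  fun <- if (method == "median") stats::median else mean
  idx <- split(seq_along(genes), factor(genes, levels = keep))
  out <- matrix(NA_real_, nrow = length(keep), ncol = ncol(m),
                dimnames = list(keep, colnames(m)))
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    out[g, ] <- if (length(rows) == 1L) m[rows, ] else
      apply(m[rows, , drop = FALSE], 2L, fun)
  }
  out
}

#' Log2-transform intensities
#'
#' @param m numeric matrix of raw intensities.
#' @param offset nonnegative pseudo-count added before the log. Use 1 for raw
#'   intensities and 0 for data that are already on the log2 scale (in which
#'   case skip this step entirely).
#' @return `log2(m + offset)`.
#' @export
log2_transform <- function(m, offset = 1) {
  .check_expression_matrix(m)
  if (offset < 0) stop("offset must be nonnegative")
  bad <- rowSums(m + offset <= 0, na.rm = TRUE) > 0
  if (any(bad)) {
    stop("log2 undefined (value + offset <= 0) for gene(s): ",
         paste(utils::head(rownames(m)[bad], 5), collapse = ", "),
         if (sum(bad) > 5) ", ..." else "")
  }
  log2(m + offset)
}

#' Median-center each gene
#'
#' Subtracts the per-gene median across samples so every row has median 0.
#' Idempotent: centering an already-centered matrix is a no-op.
#'
#' @param m numeric matrix (genes x samples) with at least one sample.
#' @return centered matrix.
#' @export
median_center_genes <- function(m) {
  .check_expression_matrix(m)
  if (ncol(m) < 1L) stop("need at least one sample")
  med <- apply(m, 1L, stats::median, na.rm = TRUE)
  sweep(m, 1L, med, "-")
}

#' Learn per-gene min-max scaling on a training cohort
#'
#' The classifier stage scales expression to \[0, 1\] per gene. The reference
#' (per-gene min and max) is learned on the training cohort only and then
#' applied unchanged to validation cohorts, whose out-of-range values are
#' clipped.
#'
#' @param m training matrix (genes x samples).
#' @return a `minmax_ref`: data.frame with gene, min, max.
#' @export
fit_minmax <- function(m) {
  .check_expression_matrix(m)
  out <- data.frame(
    gene = rownames(m),
    min = apply(m, 1L, min, na.rm = TRUE),
    max = apply(m, 1L, max, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  class(out) <- c("minmax_ref", class(out))
  out
}

#' Apply a min-max scaling reference
#'
#' Values map linearly so the training min is 0 and the training max is 1;
#' values outside the training range are clipped to \[0, 1\]. A gene that was
#' constant in training maps to 0.5.
#'
#' @param m matrix to scale; must contain every gene of `ref`.
#' @param ref a `minmax_ref` from [fit_minmax()].
#' @return scaled matrix restricted to `ref` genes, in `ref` gene order.
#' @export
apply_minmax <- function(m, ref) {
  .check_expression_matrix(m)
  missing_genes <- setdiff(ref$gene, rownames(m))
  if (length(missing_genes)) {
    stop("gene(s) absent from matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "))
  }
  m <- m[ref$gene, , drop = FALSE]
  rng <- ref$max - ref$min
  out <- sweep(m, 1L, ref$min, "-")
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 1L, rng, "/")
  out[const, ] <- 0.5
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

#' Select the most variable genes
#'
#' Returns the `ceiling(fraction * n_genes)` genes with the largest unbiased
#' sample variance across samples; ties keep input order. The clustering stage
#' runs on the top quartile by default.
#'
#' @param m numeric matrix with >= 2 samples.
#' @param fraction fraction of genes to keep, in (0, 1\].
#' @return character vector of gene ids, ordered by decreasing variance.
#' @export
top_variable_genes <- function(m, fraction = 0.25) {
  .check_expression_matrix(m)
  if (ncol(m) < 2L) stop("variance needs >= 2 samples")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  v <- apply(m, 1L, stats::var, na.rm = TRUE)
  n_keep <- ceiling(fraction * nrow(m))
  ord <- order(-v)  # stable: ties keep input order
  rownames(m)[ord[seq_len(n_keep)]]
}
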