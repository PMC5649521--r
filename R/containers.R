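#' Construct an expression matrix
#'
#' The package represents expression data the way limma does: a plain numeric
#' matrix with genes in rows (rownames = gene symbols) and samples in columns
#' (colnames = sample ids). This constructor attaches the dimnames and checks
#' the basic shape invariants. Duplicate gene ids are permitted — raw
#' microarray exports often carry several probes per gene — and are resolved
#' later by [aggregate_duplicate_genes()].
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector, one per row. Gene symbols are used
#'   verbatim (case-sensitive) as the join key across all stages.
#' @param sample_ids character vector, one per column; must be unique.
#' @return a numeric matrix with `gene_ids` as rownames and `sample_ids` as
#'   colnames.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric")
  }
  if (length(gene_ids) != nrow(values)) {
    stop("gene_ids length (", length(gene_ids), ") != row count (",
         nrow(values), ")")
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length (", length(sample_ids), ") != column count (",
         ncol(values), ")")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (any(is.na(sample_ids)) || any(sample_ids == "")) {
    stop("missing or empty sample ids")
  }
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  values
}

.check_expression_matrix <- function(m, arg = "m") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(arg, " must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(arg, " must carry gene ids as rownames and sample ids as colnames")
  }
  invisible(m)
}

#' Construct a clinical table
#'
#' Per-sample diagnosis and lung-function measures. Lung function is expressed
#' as percent of the demographically predicted value (lower = more severe);
#' missing measurements are carried as `NA` and never imputed — stages that
#' need a measure drop the samples missing it.
#'
#' @param sample_id character, unique.
#' @param group `"control"` or `"disease"`.
#' @param fev1_pct,fvc_pct,dlco_pct percent-predicted lung function in
#'   \[0, 200\], or `NA`.
#' @param age years, or `NA`.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param smoking free-text smoking status.
#' @return a `data.frame` with one row per sample.
#' @export
clinical_table <- function(sample_id, group,
                           fev1_pct = NA_real_, fvc_pct = NA_real_,
                           dlco_pct = NA_real_, age = NA_real_,
                           sex = "unknown", smoking = NA_character_) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  group <- match.arg(as.character(group), c("control", "disease"),
                     several.ok = TRUE)
  if (length(group) != n) group <- rep_len(group, n)
  sex <- as.character(sex)
  bad_sex <- !sex %in% c("male", "female", "unknown") & !is.na(sex)
  if (any(bad_sex)) stop("sex must be male/female/unknown")
  out <- data.frame(
    sample_id = sample_id,
    group = group,
    fev1_pct = .check_pct(fev1_pct, n, "fev1_pct"),
    fvc_pct = .check_pct(fvc_pct, n, "fvc_pct"),
    dlco_pct = .check_pct(dlco_pct, n, "dlco_pct"),
    age = rep_len(as.numeric(age), n),
    sex = rep_len(sex, n),
    smoking = rep_len(as.character(smoking), n),
    stringsAsFactors = FALSE
  )
  out
}

.check_pct <- function(x, n, name) {
  x <- rep_len(as.numeric(x), n)
  bad <- !is.na(x) & (x < 0 | x > 200)
  if (any(bad)) {
    warning(sum(bad), " ", name,
            " value(s) outside [0, 200] recorded as missing")
    x[bad] <- NA_real_
  }
  x
}

.check_clinical <- function(cl) {
  req <- c("sample_id", "group")
  if (!is.data.frame(cl) || !all(req %in% names(cl))) {
    stop("clinical table must be a data.frame with at least columns ",
         paste(req, collapse = ", "))
  }
  invisible(cl)
}

#' Construct a gene-set collection
#'
#' A named list of gene sets, each with a description and an ordered,
#' duplicate-free gene vector — the in-memory form of a GMT file. Used for the
#' known-disease training genes, the secreted/BALF annotation, and the per-term
#' annotation categories consumed by the prioritization stage.
#'
#' @param sets named list; each element either a character vector of gene ids
#'   or a list with elements `description` and `genes`.
#' @return a `gene_set_collection`: named list of
#'   `list(description =, genes =)`.
#' @export
gene_set_collection <- function(sets) {
  if (length(sets) == 0) {
    out <- list()
    class(out) <- "gene_set_collection"
    return(out)
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  out <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", genes = s)
    genes <- as.character(s$genes)
    if (anyDuplicated(genes)) {
      warning("duplicate genes within a set were deduplicated")
      genes <- genes[!duplicated(genes)]
    }
    list(description = as.character(s$description %||% ""), genes = genes)
  })
  class(out) <- "gene_set_collection"
  out
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with", length(x), "set(s)\n")
  for (nm in utils::head(names(x), 10)) {
    cat("  ", nm, ": ", length(x[[nm]]$genes), " genes\n", sep = "")
  }
  if (length(x) > 10) cat("  ...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
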