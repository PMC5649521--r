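#' Count, per gene, the clusters where it is a DEG
#'
#' The DEG union is partitioned by how many patient clusters call each gene:
#' count k (all clusters) is the core set, count 1 genes are cluster-unique.
#'
#' @param deg_sets named list: cluster -> character vector of DEG ids.
#' @return named integer vector over the DEG union (union order preserved).
#' @export
overlap_groups <- function(deg_sets) {
  if (length(deg_sets) < 1L) stop("need at least one cluster DEG set")
  all_genes <- unique(unlist(deg_sets, use.names = FALSE))
  counts <- integer(length(all_genes))
  names(counts) <- all_genes
  for (s in deg_sets) {
    counts[unique(s)] <- counts[unique(s)] + 1L
  }
  counts
}

.signature_direction <- function(genes, de) {
  if (is.null(de)) return(NULL)
  sub <- de[de$gene %in% genes & de$deg, c("gene", "contrast", "direction")]
  sub[order(match(sub$gene, genes)), , drop = FALSE]
}

#' Core signature: genes differentially expressed in every cluster
#'
#' The intersection of the per-cluster DEG sets. When the DE table is
#' supplied, per-cluster directions are recorded and genes that go up in some
#' clusters but down in others are flagged discordant (recorded, not
#' resolved).
#'
#' @param deg_sets named list: cluster -> DEG ids (all clusters present).
#' @param de optional DE table (for direction provenance).
#' @return a `gene_signature`: list with `name`, `genes`, `direction`,
#'   `discordant`, `provenance`.
#' @export
core_set <- function(deg_sets, de = NULL) {
  if (length(deg_sets) < 1L) stop("need at least one cluster DEG set")
  genes <- Reduce(intersect, deg_sets)
  direction <- .signature_direction(genes, de)
  discordant <- character(0)
  if (!is.null(direction) && nrow(direction)) {
    n_dir <- tapply(direction$direction, direction$gene,
                    function(x) length(unique(x)))
    discordant <- names(n_dir)[n_dir > 1L]
  }
  structure(list(name = "core", genes = genes, direction = direction,
                 discordant = discordant,
                 provenance = list(clusters = names(deg_sets))),
            class = "gene_signature")
}

#' Cluster-unique signature
#'
#' Genes that are DEGs in exactly one, given cluster. The unique set of the
#' most severe cluster is the "advanced" signature: expression changes found
#' only in end-stage disease.
#'
#' @param deg_sets named list: cluster -> DEG ids.
#' @param cluster name of the cluster whose unique set is wanted.
#' @param name signature name; defaults to `<cluster>_unique`.
#' @param de optional DE table (for direction provenance).
#' @return a `gene_signature`.
#' @export
unique_set <- function(deg_sets, cluster, name = NULL, de = NULL) {
  if (!cluster %in% names(deg_sets)) {
    stop("unknown cluster '", cluster, "'")
  }
  others <- unique(unlist(deg_sets[names(deg_sets) != cluster],
                          use.names = FALSE))
  genes <- setdiff(deg_sets[[cluster]], others)
  structure(list(name = name %||% paste0(cluster, "_unique"), genes = genes,
                 direction = .signature_direction(genes, de),
                 discordant = character(0),
                 provenance = list(cluster = cluster)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", length(x$genes), " genes\n",
      sep = "")
  invisible(x)
}

#' Gene co-expression modules
#'
#' Clusters genes (not samples) hierarchically with distance 1 - Pearson
#' correlation across samples and complete linkage, cut into `n_modules`
#' groups — the gene-module view of the DEG union (three major modules by
#' default). A constant gene row has undefined correlation; by convention it
#' is treated as uncorrelated (distance 1 to everything) and a warning is
#' raised.
#'
#' @param m genes x samples matrix restricted to the genes of interest.
#' @param n_modules number of modules to cut (default 3).
#' @return integer module labels (1..n_modules) named by gene.
#' @export
gene_modules <- function(m, n_modules = 3L) {
  .check_expression_matrix(m)
  if (nrow(m) < n_modules) stop("need at least n_modules genes")
  constant <- apply(m, 1L, function(x) stats::sd(x) == 0)
  cc <- suppressWarnings(stats::cor(t(m)))
  if (any(constant)) {
    warning(sum(constant),
            " constant gene row(s): correlation undefined, treated as 0")
    cc[constant, ] <- 0
    cc[, constant] <- 0
    diag(cc) <- 1
  }
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "complete")
  stats::cutree(hc, k = n_modules)
}

#' Export signatures as a gene-set collection
#'
#' @param signatures list of `gene_signature` objects.
#' @return a [gene_set_collection()] keyed by signature name.
#' @export
signatures_to_collection <- function(signatures) {
  sets <- lapply(signatures, function(s) {
    list(description = paste0("signature (", length(s$genes), " genes)"),
         genes = s$genes)
  })
  names(sets) <- vapply(signatures, function(s) s$name, character(1))
  gene_set_collection(sets)
}
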