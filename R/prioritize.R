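#' Assemble an annotation database
#'
#' Categories mirror the feature classes used for knowledge-based gene
#' ranking (biological process, cellular component, phenotypes, pathways,
#' disease). Each category maps term ids to gene sets; on disk each category
#' is one GMT file.
#'
#' @param categories named list: category name -> [gene_set_collection()]
#'   (or a named list of character gene vectors).
#' @return an `annotation_db`.
#' @export
annotation_db <- function(categories) {
  if (is.null(names(categories)) || anyDuplicated(names(categories))) {
    stop("categories must be uniquely named")
  }
  out <- lapply(categories, function(cat) {
    if (!inherits(cat, "gene_set_collection")) cat <- gene_set_collection(cat)
    empty <- vapply(cat, function(s) length(s$genes) == 0L, logical(1))
    if (any(empty)) stop("term gene sets must be nonempty")
    cat
  })
  structure(out, class = "annotation_db")
}

#' Hypergeometric term enrichment
#'
#' One-sided hypergeometric test per term (probability of an overlap at least
#' as large as observed, given term and query sizes within the universe),
#' BH-adjusted within each annotation category. Terms passing the FDR
#' threshold are returned.
#'
#' @param query gene set to test (must be contained in `universe`).
#' @param universe background gene set.
#' @param db an [annotation_db()].
#' @param fdr_max FDR threshold (default 0.05); `Inf` returns all terms.
#' @return data.frame: category, term, overlap, term_size, query_size, p, q.
#' @export
enrich_terms <- function(query, universe, db, fdr_max = 0.05) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (length(query) == 0L) stop("empty query gene set")
  if (!all(query %in% universe)) {
    stop("query must be a subset of the universe")
  }
  n_univ <- length(universe)
  n_query <- length(query)
  blocks <- lapply(names(db), function(cat_name) {
    cat <- db[[cat_name]]
    rows <- lapply(names(cat), function(term) {
      term_genes <- intersect(cat[[term]]$genes, universe)
      k_term <- length(term_genes)
      if (k_term == 0L) return(NULL)
      overlap <- length(intersect(term_genes, query))
      p <- stats::phyper(overlap - 1L, k_term, n_univ - k_term, n_query,
                         lower.tail = FALSE)
      data.frame(category = cat_name, term = term, overlap = overlap,
                 term_size = k_term, query_size = n_query, p = p,
                 stringsAsFactors = FALSE)
    })
    block <- do.call(rbind, rows)
    if (is.null(block)) return(NULL)
    block$q <- bh_adjust(block$p)
    block
  })
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    out <- data.frame(category = character(0), term = character(0),
                      overlap = integer(0), term_size = integer(0),
                      query_size = integer(0), p = numeric(0),
                      q = numeric(0))
  }
  out <- out[out$q <= fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Functional similarity of genes to a training set
#'
#' A documented, deterministic similarity scorer: the training set (known
#' disease genes) is enriched against the annotation database, and each
#' candidate gene scores the sum of `-log10(q)` over enriched terms
#' (q <= `fdr_max`) that also annotate it. A gene carrying none of the
#' enriched annotations scores 0. The scorer sits behind this one function so
#' an alternative (e.g. service-backed) implementation can be swapped in.
#'
#' @param genes candidate gene ids.
#' @param training known disease gene set (nonempty).
#' @param db an [annotation_db()].
#' @param universe background gene set containing the training genes.
#' @param fdr_max enrichment threshold for the training terms (default 0.05).
#' @return named numeric scores, one per candidate gene.
#' @export
functional_similarity <- function(genes, training, db, universe,
                                  fdr_max = 0.05) {
  if (length(training) == 0L) stop("training gene set is empty")
  enriched <- enrich_terms(training, universe, db, fdr_max = fdr_max)
  all_db_genes <- unique(unlist(lapply(db, function(cat) {
    unlist(lapply(cat, `[[`, "genes"), use.names = FALSE)
  }), use.names = FALSE))
  absent <- setdiff(genes, all_db_genes)
  if (length(absent)) {
    warning(length(absent), " gene(s) absent from the annotation database ",
            "score 0")
  }
  scores <- stats::setNames(numeric(length(genes)), genes)
  if (nrow(enriched) == 0L) return(scores)
  for (i in seq_len(nrow(enriched))) {
    term_genes <- db[[enriched$category[i]]][[enriched$term[i]]]$genes
    hit <- genes %in% term_genes
    scores[hit] <- scores[hit] - log10(enriched$q[i])
  }
  scores
}

#' Rank-product aggregation
#'
#' Combines two or more rank vectors over the same genes into
#' `RP = (prod ranks)^(1/K)` — the geometric mean rank — and orders genes by
#' ascending RP (small = consistently top-ranked). Ties get average final
#' ranks.
#'
#' @param rank_lists list (or matrix columns) of positive rank vectors with
#'   identical gene names.
#' @return data.frame: gene, rp, final_rank, sorted by final_rank.
#' @export
rank_product <- function(rank_lists) {
  if (is.matrix(rank_lists)) {
    rank_lists <- lapply(seq_len(ncol(rank_lists)),
                         function(j) rank_lists[, j])
  }
  if (length(rank_lists) < 2L) stop("need at least two rank vectors")
  genes <- names(rank_lists[[1L]])
  if (is.null(genes)) stop("rank vectors must be named by gene")
  for (r in rank_lists) {
    if (is.null(names(r)) || !setequal(names(r), genes) ||
        length(r) != length(genes)) {
      stop("all rank vectors must cover the same gene set")
    }
    if (any(r <= 0)) stop("ranks must be positive")
  }
  mat <- vapply(rank_lists, function(r) r[genes], numeric(length(genes)))
  rp <- exp(rowMeans(log(mat)))
  out <- data.frame(gene = genes, rp = rp,
                    final_rank = rank(rp, ties.method = "average"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$final_rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prioritize novel candidate genes in a signature
#'
#' Knowledge-based ranking of signature genes: genes already in the training
#' set ("known" disease genes) are removed; the remainder are ranked by
#' functional similarity to the training set and, separately, by absolute
#' log2 fold change (the maximum over the contrasts where the gene is a DEG);
#' the two rankings are aggregated with the rank product and the top fraction
#' is selected.
#'
#' @param signature a `gene_signature` or character gene vector.
#' @param de DE table with gene, contrast, lfc, deg columns covering the
#'   signature genes.
#' @param training known disease gene set.
#' @param db an [annotation_db()].
#' @param universe background gene set.
#' @param top_fraction fraction of candidates reported as top (default 0.10).
#' @return data.frame with gene, similarity, sim_rank, abs_lfc, fc_rank, rp,
#'   final_rank, selected (top-fraction flag), sorted by final rank.
#' @export
prioritize_candidates <- function(signature, de, training, db, universe,
                                  top_fraction = 0.10) {
  if (inherits(signature, "gene_signature")) signature <- signature$genes
  candidates <- setdiff(signature, training)
  if (length(candidates) == 0L) {
    stop("every signature gene is already a known training gene")
  }
  sim <- functional_similarity(candidates, training, db, universe)
  abs_lfc <- vapply(candidates, function(g) {
    rows <- de$gene == g & de$deg
    if (!any(rows)) rows <- de$gene == g
    if (!any(rows)) return(NA_real_)
    max(abs(de$lfc[rows]))
  }, numeric(1))
  if (anyNA(abs_lfc)) {
    stop("signature gene(s) missing from the DE table: ",
         paste(utils::head(candidates[is.na(abs_lfc)], 5), collapse = ", "))
  }
  sim_rank <- rank(-sim, ties.method = "average")
  fc_rank <- rank(-abs_lfc, ties.method = "average")
  names(sim_rank) <- names(fc_rank) <- candidates
  rp <- rank_product(list(similarity = sim_rank, fold_change = fc_rank))
  n_top <- ceiling(top_fraction * length(candidates))
  out <- data.frame(
    gene = rp$gene,
    similarity = sim[rp$gene],
    sim_rank = sim_rank[rp$gene],
    abs_lfc = abs_lfc[rp$gene],
    fc_rank = fc_rank[rp$gene],
    rp = rp$rp,
    final_rank = rp$final_rank,
    stringsAsFactors = FALSE
  )
  out$selected <- seq_len(nrow(out)) <= n_top
  rownames(out) <- NULL
  out
}
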