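# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition, not from the package code.

# BH step-up from the textbook definition: q_(i) = min_{j>=i} min(1, m p_(j)/j)
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# AUC by exhaustive pairwise comparison, ties at 1/2
brute_auc <- function(scores, labels) {
  pos <- scores[labels == "disease"]
  neg <- scores[labels == "control"]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Ward agglomeration: merge the pair minimizing the increase in
# within-cluster sum of squares, n_i n_j / (n_i + n_j) * ||c_i - c_j||^2;
# ties broken by lowest index pair. Returns the partition at k clusters.
brute_ward <- function(points, k) {
  points <- as.matrix(points)
  clusters <- lapply(seq_len(nrow(points)), identity)
  while (length(clusters) > k) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        ci <- colMeans(points[clusters[[i]], , drop = FALSE])
        cj <- colMeans(points[clusters[[j]], , drop = FALSE])
        ni <- length(clusters[[i]])
        nj <- length(clusters[[j]])
        cost <- ni * nj / (ni + nj) * sum((ci - cj)^2)
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  labels <- integer(nrow(points))
  for (c_idx in seq_along(clusters)) labels[clusters[[c_idx]]] <- c_idx
  labels
}

# same partition up to label renaming
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# hypergeometric upper tail by exhaustive enumeration over overlap counts
brute_hyper_tail <- function(overlap, term_size, universe_size, query_size) {
  ks <- overlap:min(term_size, query_size)
  sum(choose(term_size, ks) *
        choose(universe_size - term_size, query_size - ks)) /
    choose(universe_size, query_size)
}

# adjusted Rand index from the pair-counting definition
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

jaccard <- function(a, b) {
  if (length(union(a, b)) == 0) return(NA_real_)
  length(intersect(a, b)) / length(union(a, b))
}

# small labelled matrix helper
toy_matrix <- function(values, genes, samples) {
  expression_matrix(matrix(values, nrow = length(genes), byrow = TRUE),
                    genes, samples)
}
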