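test_that("lung-function severity rule handles present and missing measures", {
  cl <- clinical_table(
    sample_id = paste0("P", 1:5),
    group = "disease",
    fvc_pct = c(60, 50, NA, 50, NA),
    dlco_pct = c(30, 39, NA, 45, NA)
  )
  sg <- severity_group(cl)
  expect_equal(unname(sg[1]), "mild_moderate")  # FVC >= 55 rescues low DLCO
  expect_equal(unname(sg[2]), "severe")         # both below cut-offs
  expect_equal(unname(sg[3]), "unknown")        # both missing
  expect_equal(unname(sg[4]), "mild_moderate")  # DLCO >= 40
  # one measure missing, the other failing -> severe
  one <- clinical_table("X", "disease", fvc_pct = 50)
  expect_equal(unname(severity_group(one)), "severe")
})

test_that("PCA fit on disease samples projects consistently", {
  # rank-1: two perfectly correlated genes
  m <- toy_matrix(c(1, 2, 3, 4,
                    2, 4, 6, 8), c("A", "B"), paste0("s", 1:4))
  fit <- fit_pca_project(m, m, 1)
  expect_equal(fit$model$explained[1], 1)

  set.seed(14)
  all_m <- expression_matrix(matrix(rnorm(10 * 12), 10, 12),
                             paste0("G", 1:10), paste0("s", 1:12))
  disease <- all_m[, 1:8]
  fit2 <- fit_pca_project(disease, all_m, 3)
  direct <- stats::prcomp(t(disease))$x[, 1:3]
  # projected disease scores equal fitted scores up to component sign
  for (j in 1:3) {
    expect_equal(abs(unname(fit2$scores[colnames(disease), j])),
                 abs(unname(direct[, j])), tolerance = 1e-8)
  }
  expect_error(fit_pca_project(disease, all_m, 9), "n_components")
})

test_that("PCA loadings equal the closed-form covariance eigenvectors", {
  m <- toy_matrix(c(1, 4, 7,
                    2, 3, 10), c("A", "B"), c("s1", "s2", "s3"))
  fit <- fit_pca_project(m, m, 2)
  ev <- eigen(stats::cov(t(m)))
  for (j in 1:2) {
    expect_equal(abs(unname(fit$model$loadings[, j])),
                 abs(ev$vectors[, j]), tolerance = 1e-8)
  }
  expect_equal(fit$model$explained_all, ev$values / sum(ev$values),
               tolerance = 1e-8)
})

test_that("Ward clustering separates obvious groups and matches the brute-force
           agglomeration on small instances", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1,
                dimnames = list(paste0("s", 1:4), NULL))
  labels <- ward_cluster(pts, 2)
  expect_true(same_partition(labels, c(1, 1, 2, 2)))
  expect_equal(length(unique(ward_cluster(pts, 4))), 4L)
  expect_error(ward_cluster(pts, 0), "k")
  expect_error(ward_cluster(pts, 5), "exceed")

  set.seed(31)
  for (rep_i in 1:8) {
    n <- sample(5:8, 1)
    p <- matrix(rnorm(n * 2), n, 2)
    rownames(p) <- paste0("x", seq_len(n))
    k <- sample(2:(n - 1), 1)
    expect_true(same_partition(ward_cluster(p, k), brute_ward(p, k)))
  }
})

test_that("clinical separation score follows its definition", {
  cl <- clinical_table(paste0("P", 1:8), "disease",
                       dlco_pct = c(38, 42, 44, 36, 58, 62, 64, 56))
  labels <- setNames(rep(1:2, each = 4), cl$sample_id)
  # cluster means 40 and 60; within-cluster pooled SD known in closed form
  grp_sd <- sqrt(sum((c(38, 42, 44, 36) - 40)^2 +
                       (c(58, 62, 64, 56) - 60)^2) / 6)
  expect_equal(clinical_separation_score(labels, cl, "dlco_pct"),
               20 / grp_sd)
  # identical cluster means -> 0
  cl0 <- clinical_table(paste0("Q", 1:4), "disease",
                        dlco_pct = c(40, 60, 40, 60))
  lab0 <- setNames(c(1, 1, 2, 2), cl0$sample_id)
  expect_equal(clinical_separation_score(lab0, cl0, "dlco_pct"), 0)
  # invariance to relabeling
  relab <- setNames(c(7, 7, 7, 7, 2, 2, 2, 2), names(labels))
  expect_equal(clinical_separation_score(relab, cl, "dlco_pct"),
               clinical_separation_score(labels, cl, "dlco_pct"))
  expect_error(clinical_separation_score(setNames(rep(1, 8), cl$sample_id),
                                         cl), ">= 2 clusters")
})

test_that("cluster-count selection picks the smallest near-maximal k", {
  set.seed(8)
  # two clearly separated clinical + point groups
  pts <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  rownames(pts) <- paste0("P", 1:20)
  cl <- clinical_table(paste0("P", 1:20), "disease",
                       fev1_pct = c(rnorm(10, 80, 2), rnorm(10, 40, 2)),
                       fvc_pct = c(rnorm(10, 75, 2), rnorm(10, 42, 2)),
                       dlco_pct = c(rnorm(10, 70, 2), rnorm(10, 35, 2)))
  sel <- select_cluster_count(pts, cl, k_min = 2, k_max = 6,
                              tolerance = 0.05)
  expect_equal(sel$k, 2L)
  expect_equal(nrow(sel$trace), 5L)
  # tolerance 0: the argmax itself (smallest among ties)
  sel0 <- select_cluster_count(pts, cl, k_min = 2, k_max = 6, tolerance = 0)
  expect_equal(sel0$k,
               sel0$trace$k[which.max(sel0$trace$score)])
})

test_that("severity ordering relabels clusters mildest-first by DLCO", {
  cl <- clinical_table(paste0("P", 1:6), "disease",
                       dlco_pct = c(70, 72, 68, 31, 29, 33),
                       fvc_pct = c(80, 78, 82, 45, 44, 46),
                       fev1_pct = c(85, 83, 84, 50, 52, 51))
  labels <- setNames(c(2, 2, 2, 1, 1, 1), cl$sample_id)
  ord <- order_clusters_by_severity(labels, cl)
  expect_equal(unname(ord$labels[1:3]), rep("C1", 3))  # high DLCO = mildest
  expect_equal(unname(ord$labels[4:6]), rep("C2", 3))
  expect_true(all(diff(ord$cluster_means$mean_dlco) <= 0))
  # permuting input label values leaves the assignment unchanged
  relab <- setNames(c(9, 9, 9, 4, 4, 4), cl$sample_id)
  expect_equal(order_clusters_by_severity(relab, cl)$labels, ord$labels)
})

test_that("severity ordering yields nonincreasing DLCO on synthetic cohorts", {
  for (s in 1:3) {
    co <- generate_cohort(synthetic_config(), seed = s)
    tr <- co$truth$subgroup
    ord <- order_clusters_by_severity(tr, co$clinical)
    expect_true(all(diff(ord$cluster_means$mean_dlco) <= 0))
  }
})

test_that("the helper adjusted Rand index agrees with mclust", {
  skip_if_not_installed("mclust")
  set.seed(66)
  for (i in 1:5) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(ari(1:10, 1:10), 1)
})

test_that("subgroup discovery recovers planted structure on one cohort", {
  co <- generate_cohort(synthetic_config(), seed = 42)
  m <- median_center_genes(co$expr)
  cl <- cluster_patients(m, co$clinical)
  expect_equal(cl$assignment$k, 6L)
  tab <- table(cl$assignment$labels, co$truth$subgroup[names(cl$assignment$labels)])
  # each recovered cluster is dominated by one true subgroup
  expect_true(all(apply(tab, 1, max) / rowSums(tab) >= 0.9))
})
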