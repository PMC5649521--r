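test_that("per-gene two-group models recover means and pooled variances", {
  m <- toy_matrix(c(1, 1, 0, 0,
                    5, 5, 5, 5), c("A", "B"), paste0("s", 1:4))
  groups <- setNames(c("x", "x", "y", "y"), colnames(m))
  fit <- fit_gene_models(m, groups, c("x", "y"))
  expect_equal(fit$diff, c(1, 0))
  expect_equal(fit$s2, c(0, 0))
  expect_equal(fit$d, c(2L, 2L))
  expect_equal(fit$v, rep(1, 2))

  set.seed(2)
  r <- expression_matrix(matrix(rnorm(5 * 9), 5, 9),
                         paste0("G", 1:5), paste0("s", 1:9))
  grp <- setNames(c(rep("a", 5), rep("b", 4)), colnames(r))
  f <- fit_gene_models(r, grp, c("a", "b"))
  for (i in 1:5) {
    a <- r[i, 1:5]; b <- r[i, 6:9]
    expect_equal(f$diff[i], mean(a) - mean(b))
    expect_equal(f$s2[i],
                 (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 7)
  }
  expect_error(fit_gene_models(r, setNames(c("a", rep("b", 8)), colnames(r)),
                               c("a", "b")), ">= 2 samples")
})

test_that("variance-prior estimation recovers planted hyperparameters", {
  set.seed(100)
  d0 <- 4; s02 <- 1; d <- 4; n <- 5000
  sigma2 <- d0 * s02 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  prior <- estimate_eb_prior(s2, d)
  expect_lt(abs(prior$d0 - d0) / d0, 0.15)
  expect_lt(abs(prior$s02 - s02) / s02, 0.15)
  # scale equivariance: doubling variances doubles s02, leaves d0 fixed
  prior2 <- estimate_eb_prior(2 * s2, d)
  expect_equal(prior2$d0, prior$d0, tolerance = 1e-10)
  expect_equal(prior2$s02, 2 * prior$s02, tolerance = 1e-10)
  # all-equal variances: degenerate prior
  pr_const <- estimate_eb_prior(rep(3, 100), 4)
  expect_identical(pr_const$d0, Inf)
  expect_equal(pr_const$s02, 3 * exp(-digamma(2) + log(2)), tolerance = 1e-8)
  expect_error(estimate_eb_prior(rep(0, 100), 4), "zero")
})

test_that("moderated t follows the posterior-variance formula", {
  pr <- list(d0 = 4, s02 = 1)
  mt <- moderated_t(1, s2 = 2, d = 4, v = 2 / 3, prior = pr)
  expect_equal(mt$t, 1)
  expect_equal(mt$df, 8)
  expect_equal(mt$p, 2 * pt(-1, 8))
  # zero effect
  expect_equal(moderated_t(0, 2, 4, 1, pr)$p, 1)
  # d0 = 0: ordinary two-sample t
  set.seed(6)
  s2 <- rchisq(50, 3); diff <- rnorm(50)
  ord <- moderated_t(diff, s2, 5, 0.5, list(d0 = 0, s02 = 1))
  expect_equal(ord$t, diff / sqrt(s2 * 0.5), tolerance = 1e-10)
  expect_equal(ord$df, rep(5, 50))
  # d0 = Inf: normal reference
  inf <- moderated_t(2, 99, 4, 1, list(d0 = Inf, s02 = 1))
  expect_equal(inf$t, 2)
  expect_equal(inf$p, 2 * pnorm(-2))
  expect_error(moderated_t(1, 1, 4, -1, pr), "v")
})

test_that("moderated statistics agree with limma on a shared fixture", {
  skip_if_not_installed("limma")
  set.seed(77)
  n_a <- 6; n_b <- 5
  m <- matrix(rnorm(200 * (n_a + n_b)), 200)
  m[1:20, 1:n_a] <- m[1:20, 1:n_a] + 2
  rownames(m) <- paste0("G", 1:200)
  colnames(m) <- paste0("s", 1:(n_a + n_b))
  groups <- setNames(rep(c("A", "B"), c(n_a, n_b)), colnames(m))

  fit <- fit_gene_models(m, groups, c("A", "B"))
  prior <- estimate_eb_prior(fit$s2, fit$d)
  mine <- moderated_t(fit$diff, fit$s2, fit$d, fit$v, prior)

  design <- cbind(1, as.numeric(groups == "A"))
  lf <- limma::eBayes(limma::lmFit(m, design))
  expect_equal(prior$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(prior$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(mine$t, unname(lf$t[, 2]), tolerance = 1e-8)
  expect_equal(mine$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up definition and its properties", {
  p <- c(0.005, 0.011, 0.02, 0.04)
  expect_equal(bh_adjust(p), c(0.02, 0.022, 4 * 0.02 / 3, 0.04),
               tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.03, 7)), rep(0.03, 7))
  set.seed(12)
  rp <- runif(100)
  q <- bh_adjust(rp)
  expect_equal(q, brute_bh(rp))
  # monotone in p order
  expect_true(all(diff(q[order(rp)]) >= -1e-12))
  expect_error(bh_adjust(c(0.2, 1.3)), "0, 1")
})

test_that("DEG calling applies inclusive FDR and fold-change thresholds", {
  de <- data.frame(gene = paste0("G", 1:4),
                   lfc = c(1.0, 0.9, -1.4, 2),
                   q = c(0.05, 0.04, 0.01, 0.2))
  out <- call_degs(de)
  expect_equal(out$deg, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(out$direction, c("up", NA, "down", NA))
  set.seed(4)
  rde <- data.frame(gene = paste0("G", 1:200), lfc = rnorm(200, sd = 1.5),
                    q = runif(200))
  got <- call_degs(rde)$deg
  expect_equal(got, rde$q <= 0.05 & abs(rde$lfc) >= 1)
})

test_that("summary-statistic t-test reproduces printed cohort p-values", {
  # FEV1 and FVC rows of the cohort demographics table
  fev1 <- pooled_t_from_summary(71.37, 19.00, 131, 94.33, 9.86, 12)
  expect_lt(abs(log(fev1$p / 6.3e-5)), log(1.15))
  fvc <- pooled_t_from_summary(64.78, 17.41, 131, 91.75, 7.44, 12)
  expect_lt(abs(log(fvc$p / 4.3e-7)), log(1.15))
  # closed-form toy case
  toy <- pooled_t_from_summary(0, 1, 2, 1, 1, 2)
  expect_equal(abs(toy$t), 1)
  expect_equal(toy$df, 2)
  expect_equal(toy$p, 0.4226, tolerance = 1e-3)
  eq <- pooled_t_from_summary(5, 2, 10, 5, 3, 12)
  expect_equal(eq$t, 0)
  expect_equal(eq$p, 1)
})

test_that("2x2 chi-square matches the O-E formula without correction", {
  same <- pearson_chi2_2x2(10, 10, 30, 30)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  sep <- pearson_chi2_2x2(10, 0, 0, 10)
  expect_equal(sep$chi2, 20)
  expect_equal(sep$p, pchisq(20, 1, lower.tail = FALSE))
  set.seed(18)
  for (i in 1:5) {
    cells <- rpois(4, 8) + 1
    got <- suppressWarnings(
      pearson_chi2_2x2(cells[1], cells[2], cells[3], cells[4]))
    tab <- matrix(cells, 2, byrow = TRUE)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got$chi2, sum((tab - expected)^2 / expected))
  }
  expect_error(pearson_chi2_2x2(0, 0, 3, 4), "margins")
})

test_that("per-contrast pipeline flags planted effects and respects BH scope", {
  set.seed(55)
  m <- matrix(rnorm(300 * 20, sd = 0.5), 300)
  rownames(m) <- paste0("G", 1:300)
  colnames(m) <- paste0("s", 1:20)
  m[1:15, 1:10] <- m[1:15, 1:10] + 2
  groups <- setNames(rep(c("case", "control"), each = 10), colnames(m))
  de <- run_de_contrast(m, groups, c("case", "control"))
  expect_true(all(de$q >= de$p))
  called <- de$gene[de$deg]
  expect_gte(length(intersect(called, paste0("G", 1:15))), 14)
  expect_lte(length(setdiff(called, paste0("G", 1:15))), 2)
  sets <- deg_sets(de)
  expect_equal(sets[["case vs control"]], called)
})
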