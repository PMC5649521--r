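make_two_class <- function(n_per = 20, n_genes = 10, n_signal = 4,
                           effect = 2, sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  m <- matrix(rnorm(n_genes * n, sd = sd), n_genes, n)
  m[seq_len(n_signal), seq_len(n_per)] <-
    m[seq_len(n_signal), seq_len(n_per)] + effect
  rownames(m) <- paste0("G", seq_len(n_genes))
  colnames(m) <- paste0("s", seq_len(n))
  labels <- setNames(rep(c("disease", "control"), each = n_per), colnames(m))
  list(m = m, labels = labels)
}

test_that("signatures restrict to the genes shared by all cohorts", {
  m1 <- toy_matrix(1:6, c("A", "C", "D"), c("s1", "s2"))
  m2 <- toy_matrix(1:6, c("A", "B", "C"), c("t1", "t2"))
  expect_equal(restrict_signature(c("A", "B", "C"), list(m1, m2)),
               c("A", "C"))
  expect_equal(restrict_signature(c("C", "A"), list(m2)), c("C", "A"))
  expect_error(restrict_signature(c("Z"), list(m1)), "no signature gene")
})

test_that("L2 logistic training is deterministic with sensible coefficients", {
  tc <- make_two_class()
  ref <- fit_minmax(tc$m)
  ms <- apply_minmax(tc$m, ref)
  clf <- train_logistic(ms, tc$labels)
  clf2 <- train_logistic(ms, tc$labels)
  expect_identical(clf$coefficients, clf2$coefficients)
  # signal genes (up in disease) get positive weights dominating noise genes
  expect_true(all(clf$coefficients[1:4] > 0))
  expect_gt(min(abs(clf$coefficients[1:4])),
            max(abs(clf$coefficients[5:10])))
  expect_error(train_logistic(ms, setNames(rep("disease", ncol(ms)),
                                           colnames(ms))), "both classes")
})

test_that("one-gene logistic fit solves the penalized score equation", {
  # tiny problem solvable by brute-force 1-D search over the profile
  x <- matrix(c(0, 1), 1, 2, dimnames = list("G1", c("a", "b")))
  labels <- setNames(c("control", "disease"), colnames(x))
  lambda <- 2
  clf <- train_logistic(x, labels, l2_strength = lambda)
  # at the optimum the penalized gradient vanishes; verify against an
  # independent grid/optimize solution of the 2-parameter problem
  obj <- function(th) {
    eta <- th[1] + th[2] * c(0, 1)
    -sum(c(0, 1) * eta - log1p(exp(eta))) + 0.5 * lambda * th[2]^2
  }
  brute <- optim(c(0.1, 0.1), obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(clf$intercept, brute$par[1], tolerance = 1e-4)
  expect_equal(unname(clf$coefficients), brute$par[2], tolerance = 1e-4)
})

test_that("ROC and AUC follow the Mann-Whitney definition", {
  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1),
                   c("disease", "disease", "control", "control"))
  expect_equal(sep$auc, 1)
  mixed <- roc_curve(c(0.9, 0.4, 0.6, 0.1),
                     c("disease", "disease", "control", "control"))
  expect_equal(mixed$auc, 0.75)
  ties <- roc_curve(rep(0.5, 6), rep(c("disease", "control"), 3))
  expect_equal(ties$auc, 0.5)
  expect_error(roc_curve(1:3, rep("disease", 3)), "both classes")
  # ROC is monotone nondecreasing in both coordinates
  set.seed(19)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    scores <- round(runif(n), 2)  # force ties
    labels <- sample(c("disease", "control"), n, replace = TRUE,
                     prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    rc <- roc_curve(scores, labels)
    expect_true(all(diff(rc$roc$fpr) >= 0))
    expect_true(all(diff(rc$roc$tpr) >= 0))
    expect_equal(rc$auc, brute_auc(scores, labels))
  }
})

test_that("threshold calibration meets the sensitivity floor at max specificity", {
  # exhaustive-sweep example: all four positives must clear the threshold
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.3, 0.1)
  labels <- c(rep("disease", 4), rep("control", 2))
  thr <- calibrate_threshold(scores, labels, 0.9)
  expect_lte(thr, 0.2)
  expect_equal(mean(scores[labels == "disease"] >= thr), 1)
  expect_equal(mean(scores[labels == "control"] < thr), 0.5)
  # perfectly separated: sensitivity and specificity both 1
  sep_scores <- c(0.9, 0.8, 0.3, 0.2)
  sep_labels <- c("disease", "disease", "control", "control")
  thr2 <- calibrate_threshold(sep_scores, sep_labels, 0.9)
  expect_equal(mean(sep_scores[1:2] >= thr2), 1)
  expect_equal(mean(sep_scores[3:4] < thr2), 1)
  # floor 0 still yields the max-specificity threshold
  thr3 <- calibrate_threshold(sep_scores, sep_labels, 0)
  expect_equal(mean(sep_scores[3:4] < thr3), 1)
  expect_error(calibrate_threshold(sep_scores, sep_labels, 1.5), "exceed")
  # property: the floor is always met on the calibration scores
  set.seed(44)
  for (i in 1:10) {
    sc <- runif(30)
    lb <- sample(c("disease", "control"), 30, replace = TRUE)
    if (sum(lb == "disease") == 0) next
    t_i <- calibrate_threshold(sc, lb, 0.9)
    expect_gte(mean(sc[lb == "disease"] >= t_i), 0.9)
  }
})

test_that("evaluation reports confusion metrics and swaps under label flips", {
  tc <- make_two_class(seed = 3)
  clf <- build_signature_classifier(tc$m, tc$labels, rownames(tc$m))
  ev <- evaluate(clf, tc$m, tc$labels, cohort = "train")
  expect_gte(ev$sensitivity, 0.9)  # calibrated floor holds by construction
  expect_true(all(c(ev$sensitivity, ev$specificity, ev$accuracy) >= 0 &
                    c(ev$sensitivity, ev$specificity, ev$accuracy) <= 1))
  flipped <- ifelse(tc$labels == "disease", "control", "disease")
  ev_flip <- evaluate(clf, tc$m, setNames(flipped, names(tc$labels)))
  expect_equal(ev_flip$sensitivity, 1 - ev$specificity)
  expect_equal(ev_flip$specificity, 1 - ev$sensitivity)
  expect_error(evaluate(clf, tc$m[1:3, ], tc$labels), "missing")
})

test_that("cross-validation stratifies folds and is seed-reproducible", {
  tc <- make_two_class(n_per = 4, n_genes = 3, n_signal = 2, seed = 5)
  reports <- cross_validate(tc$m, tc$labels, folds = 2, seed = 17)
  folds <- attr(reports, "fold_assignment")
  for (f in 1:2) {
    expect_equal(sum(tc$labels[folds == f] == "disease"), 2L)
    expect_equal(sum(tc$labels[folds == f] == "control"), 2L)
  }
  reports2 <- cross_validate(tc$m, tc$labels, folds = 2, seed = 17)
  expect_identical(attr(reports2, "fold_assignment"), folds)
  expect_error(cross_validate(tc$m, tc$labels, folds = 5), "at least")
})

test_that("cross-validated accuracy is high under strong synthetic signal", {
  tc <- make_two_class(n_per = 15, n_genes = 12, n_signal = 8, effect = 3,
                       seed = 9)
  reports <- cross_validate(tc$m, tc$labels, folds = 2, seed = 17)
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  expect_gt(mean(acc), 0.9)
})
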