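# ROC/AUC with the closest-to-corner threshold, Wilcoxon rank-sum,
# Pearson correlation, and the cross-validation machinery.

test_that("perfect and anti-perfect separation give the expected ROC", {
  labels <- c("benign", "benign", "malignant", "malignant")
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), labels, orientation = "higher")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # reversed scores: AUC 0 under the fixed orientation, 1 after auto-flip
  r0 <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), labels, orientation = "higher")
  expect_equal(r0$auc, 0)
  r1 <- roc_analysis(c(0.9, 0.8, 0.2, 0.1), labels, orientation = "auto")
  expect_equal(r1$auc, 1)
  expect_identical(r1$orientation, "lower")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair count with ties", {
  labels <- c("benign", "malignant", "benign", "malignant", "malignant")
  scores <- c(1, 2, 2, 3, 4)
  r <- roc_analysis(scores, labels, orientation = "higher")
  expect_equal(r$auc, oracle_auc_pairs(scores, labels == "malignant"))
  set.seed(12)
  for (k in 1:50) {
    n <- sample(4:12, 1)
    y <- c(TRUE, FALSE, runif(n - 2) > 0.5)  # both classes guaranteed
    s <- sample(1:5, n, replace = TRUE)      # heavy ties
    lab <- ifelse(y, "malignant", "benign")
    r <- roc_analysis(s, lab, orientation = "higher")
    expect_equal(r$auc, oracle_auc_pairs(s, y), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(4)
  s <- rnorm(40)
  lab <- ifelse(runif(40) > 0.4, "malignant", "benign")
  a0 <- roc_analysis(s, lab)$auc
  expect_equal(roc_analysis(exp(s), lab)$auc, a0)
  expect_equal(roc_analysis(5 * s + 3, lab)$auc, a0)
})

test_that("AUC of a score and its negation sum to one", {
  set.seed(13)
  for (k in 1:20) {
    n <- sample(6:30, 1)
    s <- sample(1:6, n, replace = TRUE)
    y <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    lab <- ifelse(y, "malignant", "benign")
    a_hi <- roc_analysis(s, lab, orientation = "higher")$auc
    a_lo <- roc_analysis(-s, lab, orientation = "higher")$auc
    expect_equal(a_hi + a_lo, 1, tolerance = 1e-12)
  }
})

test_that("the optimal operating point is the deterministic corner choice", {
  labels <- rep(c("benign", "malignant"), each = 4)
  scores <- c(1, 2, 3, 5, 4, 6, 7, 8)
  r <- roc_analysis(scores, labels, orientation = "higher")
  # recompute the corner distance over every achievable operating point;
  # the reported threshold is the midpoint of its equivalence interval
  u <- sort(unique(scores), decreasing = TRUE)
  mid <- c((u[-length(u)] + u[-1]) / 2, u[length(u)])
  sens <- sapply(u, function(t) mean(scores[labels == "malignant"] >= t))
  spec <- sapply(u, function(t) mean(scores[labels == "benign"] < t))
  d <- sqrt((1 - sens)^2 + (1 - spec)^2)
  best <- order(d, -spec, mid)[1]
  expect_equal(r$threshold, mid[best])
  expect_equal(r$sensitivity, sens[best])
  expect_equal(r$specificity, spec[best])
  expect_equal(r$accuracy, (sens[best] * 4 + spec[best] * 4) / 8)
  # repeated evaluation is identical (tie-break is deterministic)
  expect_identical(r$threshold,
                   roc_analysis(scores, labels, orientation = "higher")$threshold)
  expect_error(roc_analysis(1:4, rep("malignant", 4)), "both classes")
})

test_that("ROC curve runs monotonically from (0,0) to (1,1)", {
  set.seed(77)
  s <- sample(1:8, 30, replace = TRUE)
  lab <- ifelse(c(TRUE, FALSE, runif(28) > 0.3), "malignant", "benign")
  cv <- roc_analysis(s, lab)$curve
  expect_equal(cv$fpr[1], 0)
  expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[nrow(cv)], 1)
  expect_equal(cv$tpr[nrow(cv)], 1)
  expect_true(all(diff(cv$fpr) >= 0))
  expect_true(all(diff(cv$tpr) >= 0))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(21)
  s <- rnorm(60)
  lab <- ifelse(runif(60) > 0.4, "malignant", "benign")
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = lab, predictor = s, levels = c("benign", "malignant"),
    direction = "<")))
  expect_equal(roc_analysis(s, lab, orientation = "higher")$auc,
               as.numeric(ref), tolerance = 1e-12)
})

test_that("Wilcoxon enumeration reproduces the exact small-sample p", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$statistic, 6)
  expect_equal(w$p, 0.1)   # 2 of the 20 assignments are as extreme
  expect_identical(w$method, "exact enumeration")
  tied <- wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$p, 1)
  expect_equal(tied$z, 0)
})

test_that("Wilcoxon agrees with the reference implementation", {
  # exact route, no ties
  a <- c(1.1, 3.2, 4.8, 7.4)
  b <- c(2.0, 5.5, 6.1, 8.8, 9.9)
  w <- wilcoxon_rank_sum(a, b)
  ref <- wilcox.test(a, b, exact = TRUE)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)
  # approximate route with ties (continuity-corrected, as is standard)
  set.seed(6)
  x <- sample(1:6, 25, replace = TRUE)
  y <- sample(2:7, 30, replace = TRUE)
  w2 <- wilcoxon_rank_sum(x, y)
  ref2 <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(w2$p, ref2$p.value, tolerance = 1e-10)
})

test_that("exact enumeration and normal approximation agree for n >= 10", {
  set.seed(14)
  for (k in 1:5) {
    a <- rnorm(10)
    b <- rnorm(10, mean = runif(1, 0, 1.5))
    pe <- wilcoxon_rank_sum(a, b, exact = TRUE)$p
    pa <- wilcoxon_rank_sum(a, b, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("Pearson correlation matches hand-computed values", {
  x <- 1:4
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  expect_equal(pearson_correlation(x, c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson_correlation(x, rep(2, 4)), "variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})

test_that("the 11-fold plan partitions 116 lesions into balanced folds", {
  ids <- sprintf("L%03d", 1:116)
  labels <- c(rep("benign", 35), rep("malignant", 81))
  plan <- make_cv_plan(ids, labels, n_folds = 11, seed = 5)
  sizes <- as.vector(table(plan$fold))
  expect_identical(sort(sizes), c(rep(10L, 5), rep(11L, 6)))
  expect_setequal(plan$id, ids)            # exact coverage, once each
  expect_identical(anyDuplicated(plan$id), 0L)
  # every fold sees both classes under stratification
  tab <- table(plan$fold, plan$label)
  expect_true(all(tab > 0))
  # same seed, same plan; different seed, different plan
  expect_identical(plan, make_cv_plan(ids, labels, n_folds = 11, seed = 5))
  expect_false(identical(plan$fold,
                         make_cv_plan(ids, labels, n_folds = 11, seed = 6)$fold))
})

test_that("degenerate fold counts are handled", {
  ids <- letters[1:11]
  labels <- rep(c("benign", "malignant"), length.out = 11)
  loo <- make_cv_plan(ids, labels, n_folds = 11, seed = 1)
  expect_identical(sort(as.vector(table(loo$fold))), rep(1L, 11))
  expect_error(make_cv_plan(ids, labels, n_folds = 12, seed = 1), "exceeds")
})

test_that("cross-validation recovers a perfectly separable feature", {
  set.seed(41)
  n <- 44L
  rec <- data.frame(id = sprintf("L%02d", 1:n),
                    label = rep(c("benign", "malignant"), each = n / 2),
                    f = c(rnorm(n / 2, 0, 0.1), rnorm(n / 2, 10, 0.1)))
  plan <- make_cv_plan(rec$id, rec$label, n_folds = 11, seed = 2)
  cv <- cross_validated_auc(rec, "f", plan)
  expect_equal(unname(cv$average["sensitivity"]), 1)
  expect_equal(unname(cv$average["specificity"]), 1)
  expect_identical(nrow(cv$folds), 11L)
  # concatenated test folds tile the cohort exactly once
  expect_identical(sum(table(plan$fold)), n)
})

test_that("a pure-noise feature yields chance-level accuracy", {
  set.seed(9)
  n <- 600
  rec <- data.frame(id = sprintf("L%03d", 1:n),
                    label = rep(c("benign", "malignant"), each = n / 2),
                    f = rnorm(n))
  plan <- make_cv_plan(rec$id, rec$label, n_folds = 11, seed = 3)
  cv <- cross_validated_auc(rec, "f", plan)
  expect_lt(abs(unname(cv$average["accuracy"]) - 0.5), 0.05)
})
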