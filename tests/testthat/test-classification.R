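make_ft <- function(n = 40, p = 20, separation = 0, seed = 1) {
  set.seed(seed)
  subjects <- sprintf("sub%03d", 1:n)
  group <- rep(c("patient", "control"), length.out = n)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(subjects, sprintf("f%03d", 1:p)))
  if (separation > 0)
    x[group == "patient", 1:3] <- x[group == "patient", 1:3] + separation
  structure(list(x = x, group = factor(group,
                                       levels = c("control", "patient")),
                 manifest = data.frame(subject = subjects, group = group)),
            class = "feature_table")
}

test_that("stratified folds preserve the class ratio within one subject", {
  y <- factor(rep(c("a", "b"), c(55, 53)))
  fold <- make_folds(y, 5, seed = 3)
  tab <- table(fold, y)
  expect_true(all(abs(tab[, 1] - 11) <= 1))
  expect_true(all(abs(tab[, 2] - 10.6) <= 1))
  expect_error(make_folds(factor(rep(c("a", "b"), c(3, 40))), 5), "too few")
})

test_that("ROC/AUC follow the Mann-Whitney formulation", {
  y <- factor(c("control", "control", "patient", "patient"),
              levels = c("control", "patient"))
  expect_equal(roc_auc(c(0, 0, 1, 1), y), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), y), 0)
  # 4-point toy set from exhaustive pair counting
  s <- c(0.1, 0.4, 0.35, 0.8)
  y2 <- factor(c("control", "control", "patient", "patient"),
               levels = c("control", "patient"))
  expect_equal(roc_auc(s, y2), 0.75)
  expect_equal(roc_auc(s, y2), auc_pairs(s, y2))
  # ties contribute one half
  expect_equal(roc_auc(c(1, 1, 1, 1), y2), 0.5)
})

test_that("AUC properties: complement, order and monotone-transform invariance", {
  set.seed(5)
  s <- rnorm(40)
  y <- factor(sample(rep(c("control", "patient"), 20)),
              levels = c("control", "patient"))
  expect_equal(roc_auc(s, y) + roc_auc(-s, y), 1)
  o <- sample(40)
  expect_equal(roc_auc(s[o], y[o]), roc_auc(s, y))
  expect_equal(roc_auc(exp(s), y), roc_auc(s, y))
  expect_equal(roc_auc(s, y), auc_pairs(s, y))
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  s <- rnorm(60)
  y <- factor(sample(rep(c("control", "patient"), 30)),
              levels = c("control", "patient"))
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, levels = c("control", "patient"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(s, y), ref, tolerance = 1e-12)
})

test_that("an all-positive classifier has sensitivity 1 and specificity 0", {
  truth <- factor(rep(c("control", "patient"), 10),
                  levels = c("control", "patient"))
  pred <- factor(rep("patient", 20), levels = c("control", "patient"))
  m <- classification_metrics(pred, truth, "patient")
  expect_equal(unname(m["sensitivity"]), 1)
  expect_equal(unname(m["specificity"]), 0)
  expect_equal(unname(m["accuracy"]), 0.5)
})

test_that("separable features give perfect fold metrics", {
  ft <- make_ft(40, 10, separation = 8, seed = 7)
  cv <- run_cv(ft, "spearman", kernels = c("linear", "rbf"), n_folds = 5,
               seed = 1, top_frac = 0.2)
  expect_true(all(cv$per_fold$auc == 1))
  expect_true(all(cv$per_fold$accuracy == 1))
  expect_equal(cv$summary$auc, c(1, 1))
})

test_that("cross-validated AUC on pure noise stays near chance", {
  aucs <- vapply(1:10, function(s) {
    ft <- make_ft(60, 15, separation = 0, seed = 100 + s)
    run_cv(ft, "spearman", kernels = "linear", n_folds = 5, seed = s,
           top_frac = 0.1)$summary$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("permutation test is calibrated at the extremes", {
  ft <- make_ft(40, 10, separation = 8, seed = 9)
  pt <- permutation_test(ft, "spearman", "rbf", n_folds = 5, n_perm = 19,
                         seed = 2, top_frac = 0.2)
  expect_equal(pt$observed_auc, 1)
  expect_equal(pt$p_value, 1 / 20)
  expect_error(permutation_test(ft, "spearman", "rbf", n_perm = 0), "n_perm")
})

test_that("frozen-selection permutations reuse one feature set", {
  ft <- make_ft(40, 10, separation = 8, seed = 13)
  pt <- permutation_test(ft, "spearman", "linear", n_folds = 5, n_perm = 5,
                         seed = 3, frozen_selection = TRUE, top_frac = 0.2)
  expect_equal(pt$observed_auc, 1)
  expect_length(pt$perm_auc, 5)
  # fixed_features bypasses selection entirely
  cv <- run_cv(ft, "spearman", kernels = "linear", n_folds = 5, seed = 3,
               fixed_features = c("f001", "f002"))
  expect_true(all(vapply(cv$selected, identical, logical(1),
                         c("f001", "f002"))))
})

test_that("cv metrics stay within [0, 1] and report per-kernel rows", {
  ft <- make_ft(40, 12, separation = 1.5, seed = 11)
  cv <- run_cv(ft, "t_lasso", n_folds = 5, seed = 4)
  expect_equal(nrow(cv$summary), 4)
  for (col in c("auc", "accuracy", "sensitivity", "specificity"))
    expect_true(all(cv$summary[[col]] >= 0 & cv$summary[[col]] <= 1,
                    na.rm = TRUE))
})
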