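#' Stratified cross-validation folds
#'
#' Subjects are shuffled within class and dealt round-robin into `k` folds,
#' so every fold preserves the class ratio to within one subject.
#'
#' @param y class labels.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return integer fold id per subject.
#' @export
make_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  if (any(tabulate(fold, k) < 2) || min(table(y)) < k)
    stop("too few subjects per class for ", k, " folds")
  fold
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC equals the Mann-Whitney U statistic normalized by `n1 * n0` — the
#' probability a random positive outscores a random negative — with ties
#' contributing 1/2. The curve is the standard threshold sweep over the
#' distinct decision values.
#'
#' @param scores continuous decision values (larger = more positive-like).
#' @param labels binary labels; the positive class is the second factor level
#'   (`patient` in cohort tables).
#' @return list with `auc`, and `points` (data.frame fpr/tpr ordered along
#'   the sweep).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) stop("both classes must be present")
  pos <- labels == levels(labels)[2]
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !pos) / n0, tpr = sum(pred & pos) / n1)
  }, numeric(2)))
  list(auc = auc, points = as.data.frame(pts))
}

#' AUC only
#' @inheritParams roc_curve
#' @return numeric AUC.
#' @export
roc_auc <- function(scores, labels) roc_curve(scores, labels)$auc

# orient e1071 decision values so larger means more patient-like
oriented_decision_values <- function(fit, newx, positive) {
  pr <- stats::predict(fit, newx, decision.values = TRUE)
  dv <- drop(attr(pr, "decision.values"))
  lab <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]]
  if (lab[1] != positive) dv <- -dv
  list(scores = dv, class = pr)
}

standardizer <- function(train) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  function(x) scale(x, center = mu, scale = sdv)[, , drop = FALSE]
}

svm_kernel_map <- c(linear = "linear", polynomial = "polynomial",
                    rbf = "radial", sigmoid = "sigmoid")

#' Cross-validated SVM classification with in-fold feature selection
#'
#' Per outer fold: standardize on the training subjects, run the selection
#' strategy on the training subjects only, fit one SVM per kernel (cost 1,
#' kernel scale 1/P on standardized features, polynomial degree 3), score the
#' held-out fold by continuous decision values (AUC via the rank formulation)
#' and by the zero-threshold class assignment (accuracy, sensitivity,
#' specificity; positive class = patient). Fold means are reported.
#'
#' @param ft a `feature_table`, or a list with `x` and `group`.
#' @param strategy selection strategy (see [select_features()]).
#' @param kernels subset of linear, polynomial, rbf, sigmoid.
#' @param n_folds outer folds.
#' @param seed controls the fold split, selection seeds and SVM fitting.
#' @param cost SVM cost parameter.
#' @param fixed_features optional character vector of column names to use in
#'   every fold instead of running the selection strategy (the
#'   selection-frozen fast path of the permutation test).
#' @param ... passed to the selection strategy.
#' @return `cv_metrics`: list with `summary` (data.frame strategy x kernel
#'   with mean AUC/accuracy/sensitivity/specificity), `per_fold`, `roc`
#'   (pooled test-fold decision values per kernel), `selected` (per-fold
#'   selected features), `folds`.
#' @export
run_cv <- function(ft, strategy = "lasso",
                   kernels = c("linear", "polynomial", "rbf", "sigmoid"),
                   n_folds = 5L, seed = 1L, cost = 1,
                   fixed_features = NULL, ...) {
  x <- ft$x
  y <- droplevels(as.factor(ft$group))
  if (nlevels(y) != 2) stop("need exactly 2 classes")
  positive <- levels(y)[2]
  kernels <- match.arg(kernels, names(svm_kernel_map), several.ok = TRUE)
  fold <- make_folds(y, n_folds, seed)
  per_fold <- list()
  selected <- list()
  pooled <- lapply(kernels, function(k) list(scores = numeric(0),
                                             labels = character(0)))
  names(pooled) <- kernels
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    te <- !tr
    std <- standardizer(x[tr, , drop = FALSE])
    xtr <- std(x[tr, , drop = FALSE])
    xte <- std(x[te, , drop = FALSE])
    sel <- if (is.null(fixed_features))
      select_features(strategy, xtr, y[tr], seed = seed + f, ...)
    else fixed_features
    selected[[f]] <- as.character(sel)
    if (!length(sel)) {
      for (k in kernels)
        per_fold[[length(per_fold) + 1]] <-
          data.frame(fold = f, kernel = k, auc = NA_real_,
                     accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, skipped = TRUE)
      next
    }
    xtr_s <- xtr[, sel, drop = FALSE]
    xte_s <- xte[, sel, drop = FALSE]
    for (k in kernels) {
      set.seed(seed + 100L * f)
      fit <- e1071::svm(xtr_s, y[tr], kernel = svm_kernel_map[[k]],
                        cost = cost, gamma = 1 / ncol(xtr_s), degree = 3,
                        scale = FALSE)
      dv <- oriented_decision_values(fit, xte_s, positive)
      yt <- y[te]
      tp <- sum(dv$class == positive & yt == positive)
      tn <- sum(dv$class != positive & yt != positive)
      fn <- sum(dv$class != positive & yt == positive)
      fp <- sum(dv$class == positive & yt != positive)
      auc <- if (nlevels(droplevels(yt)) == 2) roc_auc(dv$scores, yt) else NA_real_
      per_fold[[length(per_fold) + 1]] <-
        data.frame(fold = f, kernel = k, auc = auc,
                   accuracy = (tp + tn) / length(yt),
                   sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                   specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                   skipped = FALSE)
      pooled[[k]]$scores <- c(pooled[[k]]$scores, dv$scores)
      pooled[[k]]$labels <- c(pooled[[k]]$labels, as.character(yt))
    }
  }
  per_fold <- do.call(rbind, per_fold)
  summary <- do.call(rbind, lapply(kernels, function(k) {
    pf <- per_fold[per_fold$kernel == k, ]
    data.frame(strategy = strategy, kernel = k,
               auc = mean(pf$auc, na.rm = TRUE),
               accuracy = mean(pf$accuracy, na.rm = TRUE),
               sensitivity = mean(pf$sensitivity, na.rm = TRUE),
               specificity = mean(pf$specificity, na.rm = TRUE),
               folds_skipped = sum(pf$skipped))
  }))
  structure(list(summary = summary, per_fold = per_fold, roc = pooled,
                 selected = selected, folds = fold),
            class = "cv_metrics")
}

#' Binary classification metrics at the zero threshold
#'
#' @param pred predicted labels.
#' @param truth true labels.
#' @param positive positive-class label.
#' @return named vector accuracy/sensitivity/specificity.
#' @export
classification_metrics <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  c(accuracy = (tp + tn) / length(truth),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp))
}

#' Label-permutation test of a cross-validated AUC
#'
#' Labels are permuted over the whole cohort and the entire pipeline — fold
#' split, in-fold selection, SVM fit, scoring — is re-run per permutation.
#' `p = (1 + #\{perm AUC >= observed\}) / (n_perm + 1)`. A selection-frozen
#' fast mode (features selected once on the observed labels, reused in every
#' permutation) is available for comparison; it is anti-conservative and not
#' the default.
#'
#' @inheritParams run_cv
#' @param kernel single kernel to test.
#' @param n_perm number of permutations (>= 1).
#' @param observed optional precomputed observed `cv_metrics` (same strategy,
#'   kernel set including `kernel`, folds, seed) to avoid refitting.
#' @param frozen_selection reuse one whole-cohort selection across
#'   permutations instead of re-selecting per permutation.
#' @return list with `p_value`, `observed_auc`, `perm_auc` (length `n_perm`).
#' @export
permutation_test <- function(ft, strategy = "lasso", kernel = "rbf",
                             n_folds = 5L, n_perm = 200L, seed = 1L,
                             observed = NULL, frozen_selection = FALSE, ...) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(observed))
    observed <- run_cv(ft, strategy, kernels = kernel, n_folds = n_folds,
                       seed = seed, ...)
  obs_auc <- observed$summary$auc[observed$summary$kernel == kernel]
  if (!length(obs_auc)) stop("kernel ", kernel, " not present in observed metrics")
  frozen <- NULL
  if (frozen_selection) {
    std <- standardizer(ft$x)
    frozen <- as.character(select_features(strategy, std(ft$x), ft$group,
                                           seed = seed, ...))
  }
  perm_auc <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(seed + 531L * p)
    ftp <- ft
    ftp$group <- sample(ft$group)
    m <- run_cv(ftp, strategy, kernels = kernel, n_folds = n_folds,
                seed = seed + p, fixed_features = frozen, ...)
    perm_auc[p] <- m$summary$auc[m$summary$kernel == kernel]
  }
  list(p_value = (1 + sum(perm_auc >= obs_auc, na.rm = TRUE)) / (n_perm + 1),
       observed_auc = obs_auc, perm_auc = perm_auc)
}
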