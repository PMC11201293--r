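#' Spearman-correlation feature screening
#'
#' Features are ranked by the absolute Spearman rank correlation with the
#' binary group label and the top `ceil(top_frac * P)` (at least 1) are kept;
#' ties broken by column order. Constant features get rho = 0. At the
#' canonical 1,267 features and the conventional top 1% this keeps 13.
#'
#' @param x training subjects x features matrix.
#' @param y binary labels (factor or 0/1).
#' @param top_frac fraction of features to keep.
#' @return character vector of selected column names, with the per-feature
#'   `rho` of the selected set as an attribute `score`.
#' @export
select_spearman <- function(x, y, top_frac = 0.01) {
  y <- as.numeric(as.factor(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  rho[is.na(rho)] <- 0
  k <- max(1L, ceiling(top_frac * ncol(x)))
  ord <- order(-abs(rho))  # stable: ties keep column order
  sel <- ord[seq_len(k)]
  structure(colnames(x)[sel], score = as.numeric(rho[sel]))
}

#' LASSO (L1-penalized logistic) feature selection
#'
#' Pure L1 penalty (`alpha = 1`) over a 100-point lambda path; lambda chosen
#' by inner 5-fold cross-validated deviance on the training data, and the
#' features with nonzero coefficients at that lambda are returned. If the
#' chosen lambda keeps nothing, the largest lambda with at least one nonzero
#' coefficient is used instead and the result is flagged.
#'
#' @param x training subjects x features matrix (standardized internally by
#'   glmnet).
#' @param y binary labels.
#' @param n_lambda lambda path length.
#' @param alpha elastic-net mixing (1 = LASSO).
#' @param seed seed for the inner fold split.
#' @return character vector of selected column names with attributes `score`
#'   (coefficients) and `fallback`.
#' @export
select_lasso <- function(x, y, n_lambda = 100L, alpha = 1, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  set.seed(seed)
  # glmnet warns about small class counts at desk-scale fold sizes; those
  # warnings are expected and benign here
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                      nlambda = n_lambda, nfolds = 5,
                      type.measure = "deviance"),
    warning = function(w) {
      if (grepl("fewer than 8|dangerous ground|grouped=FALSE|Convergence",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(cv, s = "lambda.min")[-1, 1]
  fallback <- FALSE
  if (!any(beta != 0)) {
    fit <- cv$glmnet.fit
    nz <- fit$df > 0
    if (any(nz)) {
      beta <- fit$beta[, which(nz)[1]]
      fallback <- TRUE
    }
  }
  sel <- which(beta != 0)
  structure(colnames(x)[sel], score = as.numeric(beta[sel]),
            fallback = fallback)
}

# vectorised two-sample pooled-variance (Student) t-test p-values per column
column_t_pvalues <- function(x, y, var_equal = TRUE) {
  y <- as.factor(y)
  g <- levels(droplevels(y))
  if (length(g) != 2) stop("need exactly 2 classes")
  x1 <- x[y == g[1], , drop = FALSE]
  x2 <- x[y == g[2], , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 subjects per class")
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- apply(x1, 2, stats::var); v2 <- apply(x2, 2, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  p[!is.finite(tt)] <- 1  # constant features never survive
  p
}

#' t-test screening followed by LASSO
#'
#' Features with a two-sided independent-sample Student t-test p-value below
#' `p_cut` (no multiplicity correction) are retained, then [select_lasso()]
#' runs on the survivors. An empty survivor set yields an empty, flagged
#' selection.
#'
#' @inheritParams select_lasso
#' @param p_cut t-test significance threshold.
#' @param var_equal pooled-variance Student test (`TRUE`, the convention
#'   here) or Welch.
#' @return character vector of selected column names with attributes
#'   `survivors` (t-test pass count) and `empty`.
#' @export
select_t_lasso <- function(x, y, p_cut = 0.05, n_lambda = 100L, alpha = 1,
                           seed = 1L, var_equal = TRUE) {
  p <- column_t_pvalues(x, y, var_equal)
  keep <- which(p < p_cut)
  if (!length(keep))
    return(structure(character(0), survivors = 0L, empty = TRUE))
  if (length(keep) == 1L)  # glmnet needs >= 2 columns; a lone survivor stands
    return(structure(colnames(x)[keep], survivors = 1L, empty = FALSE))
  sel <- select_lasso(x[, keep, drop = FALSE], y, n_lambda, alpha, seed)
  structure(as.character(sel), survivors = length(keep), empty = FALSE,
            score = attr(sel, "score"), fallback = attr(sel, "fallback"))
}

#' Dispatch a selection strategy
#'
#' @param strategy `"spearman"`, `"lasso"` or `"t_lasso"`.
#' @param x,y training data and labels.
#' @param seed seed for LASSO inner folds.
#' @param ... strategy-specific arguments.
#' @return selected column names (character vector).
#' @export
select_features <- function(strategy = c("spearman", "lasso", "t_lasso"),
                            x, y, seed = 1L, ...) {
  strategy <- match.arg(strategy)
  switch(strategy,
         spearman = select_spearman(x, y, ...),
         lasso = select_lasso(x, y, seed = seed, ...),
         t_lasso = select_t_lasso(x, y, seed = seed, ...))
}
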