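#' Per-node z-scoring within subject
#'
#' Each node's series is centred and scaled to unit SD within the subject, the
#' standardization applied before group-level HMM fitting so state geometry is
#' comparable across subjects. Zero-variance nodes are left centred at 0.
#'
#' @param x time x nodes matrix.
#' @return standardized matrix.
#' @export
zscore_series <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)[, , drop = FALSE]
}

# per-frame log-densities under diagonal Gaussians: T x K
gauss_logdens <- function(x, means, vars) {
  K <- nrow(means)
  Tn <- nrow(x)
  out <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    v <- vars[k, ]
    cst <- -0.5 * sum(log(2 * pi * v))
    d <- sweep(x, 2, means[k, ])
    out[, k] <- cst - 0.5 * drop(d^2 %*% (1 / v))
  }
  out
}

hmm_init_kmeans <- function(X, K, seed) {
  set.seed(seed)
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = K, nstart = 3,
                                   iter.max = 500, algorithm = "Lloyd")),
    error = function(e) stop("K exceeds the distinct data support: ",
                             conditionMessage(e)))
  means <- km$centers
  vars <- matrix(0, K, ncol(X))
  for (k in seq_len(K)) {
    xs <- X[km$cluster == k, , drop = FALSE]
    vars[k, ] <- if (nrow(xs) > 1) apply(xs, 2, stats::var) else 1
  }
  vars <- regularize_vars(vars)
  # sticky transition prior: diagonal-dominant start
  A <- matrix(0.1 / max(K - 1, 1), K, K)
  diag(A) <- if (K > 1) 0.9 else 1
  pi0 <- rep(1 / K, K)
  list(means = means, vars = vars, A = A, pi = pi0)
}

regularize_vars <- function(vars, floor_frac = 1e-6) {
  ridge <- floor_frac * mean(vars) + 1e-10
  flagged <- any(vars < ridge)
  vars <- vars + ridge
  attr(vars, "regularized") <- flagged
  vars
}

#' Fit a group-level Gaussian hidden Markov model
#'
#' One model is fitted to all subjects' standardized series jointly by
#' Baum-Welch EM with subject boundaries respected (no transition across
#' subjects; every subject contributes to the initial-state distribution).
#' Observation model: multivariate Gaussian with diagonal covariance. The EM
#' log-likelihood is non-decreasing by construction and is tracked;
#' convergence at relative change `tol` or `max_iter` iterations. The best of
#' `restarts` seeded k-means initializations is returned. Near-singular
#' variances are ridge-regularized and flagged.
#'
#' @param series list of time x nodes matrices, one per subject (raw scale;
#'   standardized internally unless `standardize = FALSE`).
#' @param K number of hidden states (the conventional choice here is 6).
#' @param seed RNG seed.
#' @param restarts number of seeded EM restarts.
#' @param max_iter,tol EM stopping rule.
#' @param standardize apply [zscore_series()] per subject first.
#' @return `hmm_model`: list with `pi`, `A`, `means`, `vars`, `loglik`,
#'   `loglik_trace`, `K`, `standardize`.
#' @export
fit_hmm <- function(series, K = 6L, seed = 1L, restarts = 3L,
                    max_iter = 300L, tol = 1e-6, standardize = TRUE) {
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  Xs <- lapply(series, function(s) if (standardize) zscore_series(s) else as.matrix(s))
  Xall <- do.call(rbind, Xs)
  N <- ncol(Xall)
  best <- NULL
  for (r in seq_len(restarts)) {
    par <- hmm_init_kmeans(Xall, K, seed + 7717L * (r - 1L))
    trace <- numeric(0)
    ll_prev <- -Inf
    for (iter in seq_len(max_iter)) {
      logpi <- log(par$pi + 1e-300)
      logA <- log(par$A + 1e-300)
      ll <- 0
      g_sum <- matrix(0, 1, K)        # initial-state responsibilities
      xi_sum <- matrix(0, K, K)
      wsum <- numeric(K)
      msum <- matrix(0, K, N)
      ssum <- matrix(0, K, N)
      gammas <- vector("list", length(Xs))
      for (si in seq_along(Xs)) {
        logB <- gauss_logdens(Xs[[si]], par$means, par$vars)
        es <- hmm_estep_cpp(logB, logpi, logA)
        ll <- ll + es$loglik
        gam <- es$gamma
        gammas[[si]] <- gam
        g_sum <- g_sum + gam[1, , drop = FALSE]
        xi_sum <- xi_sum + es$xi
        wsum <- wsum + colSums(gam)
        msum <- msum + t(gam) %*% Xs[[si]]
        ssum <- ssum + t(gam) %*% (Xs[[si]]^2)
      }
      trace <- c(trace, ll)
      # M-step
      par$pi <- pmax(drop(g_sum), 1e-12)
      par$pi <- par$pi / sum(par$pi)
      if (K > 1) {
        A <- xi_sum + 1e-12
        par$A <- A / rowSums(A)
      }
      means <- msum / pmax(wsum, 1e-12)
      vars <- ssum / pmax(wsum, 1e-12) - means^2
      par$means <- means
      par$vars <- regularize_vars(pmax(vars, 0))
      if (is.finite(ll_prev) && (ll - ll_prev) < tol * abs(ll)) break
      ll_prev <- ll
    }
    if (is.null(best) || trace[length(trace)] > best$loglik) {
      best <- list(pi = par$pi, A = par$A, means = par$means,
                   vars = par$vars, loglik = trace[length(trace)],
                   loglik_trace = trace, K = K,
                   standardize = standardize,
                   vars_regularized = isTRUE(attr(par$vars, "regularized")))
    }
  }
  structure(best, class = "hmm_model")
}

#' Decode a subject's most probable state path
#'
#' Viterbi decoding under a fitted group model, plus the per-subject summary
#' dynamics: fractional occupancy `FO_k = #{t: s_t = k} / T` and switching
#' rate `SR = #{t: s_{t+1} != s_t} / (T - 1)`.
#'
#' @param model an `hmm_model`.
#' @param series time x nodes matrix for one subject (same scale convention
#'   as at fit time; standardized internally if the model was).
#' @param soft_fo also report soft fractional occupancies (mean posterior
#'   state probabilities) alongside the hard Viterbi ones.
#' @return `state_path`: list with `states` (length-T integer), `fo`
#'   (K-vector summing to 1), `sr`, and `fo_soft` when requested.
#' @export
decode_states <- function(model, series, soft_fo = FALSE) {
  x <- if (isTRUE(model$standardize)) zscore_series(series) else as.matrix(series)
  if (ncol(x) != ncol(model$means))
    stop("series has ", ncol(x), " nodes but the model expects ", ncol(model$means))
  logB <- gauss_logdens(x, model$means, model$vars)
  path <- hmm_viterbi_cpp(logB, log(model$pi + 1e-300), log(model$A + 1e-300))
  out <- summarize_state_path(path, model$K)
  if (soft_fo) {
    es <- hmm_estep_cpp(logB, log(model$pi + 1e-300), log(model$A + 1e-300))
    out$fo_soft <- colMeans(es$gamma)
  }
  out
}

#' Summaries of an explicit state path
#'
#' @param path integer state sequence (1..K).
#' @param K state count.
#' @return `state_path` list with `states`, `fo`, `sr`.
#' @export
summarize_state_path <- function(path, K) {
  Tn <- length(path)
  fo <- tabulate(path, nbins = K) / Tn
  sr <- if (Tn > 1) mean(path[-1] != path[-Tn]) else 0
  structure(list(states = as.integer(path), fo = fo, sr = sr),
            class = "state_path")
}

#' Per-subject HMM feature vectors
#'
#' The 6 fractional occupancies plus the switching rate, the 7 dynamic HMM
#' features appended to the network-flexibility block.
#'
#' @param paths named list of `state_path` objects (one per subject).
#' @param K expected state count; decoded paths must match (the canonical
#'   feature layout assumes K = 6).
#' @return subjects x (K + 1) numeric matrix, columns `FO1..FOK, SR`.
#' @export
hmm_features <- function(paths, K = 6L) {
  K <- as.integer(K)
  bad <- vapply(paths, function(p) length(p$fo) != K, logical(1))
  if (any(bad))
    stop("state paths have ", length(paths[[which(bad)[1]]]$fo),
         " states but K = ", K, " was requested")
  out <- t(vapply(paths, function(p) c(p$fo, p$sr), numeric(K + 1)))
  colnames(out) <- c(sprintf("FO%d", seq_len(K)), "SR")
  rownames(out) <- names(paths)
  out
}

#' Fit and decode HMM dynamics for a cohort
#'
#' Convenience wrapper: fit the group model on all subjects, decode each, and
#' return both the model and the feature matrix.
#'
#' @inheritParams fit_hmm
#' @return list with `model`, `paths`, `features`.
#' @export
hmm_dynamics <- function(series, K = 6L, seed = 1L, restarts = 3L, ...) {
  model <- fit_hmm(series, K = K, seed = seed, restarts = restarts, ...)
  paths <- lapply(series, function(s) decode_states(model, s))
  names(paths) <- names(series)
  list(model = model, paths = paths, features = hmm_features(paths, K))
}
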