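# Independent oracles used to check the package implementations.

# Kendall's coefficient of concordance, straight from the closed form on a
# time x series matrix (center plus neighbors).
brute_kendall_w <- function(X) {
  n <- nrow(X)
  K <- ncol(X)
  R <- apply(X, 2, rank)
  Rsum <- rowSums(R)
  12 * sum((Rsum - mean(Rsum))^2) / (K^2 * (n^3 - n))
}

# All set partitions of n elements as restricted-growth strings.
enum_partitions <- function(n) {
  out <- vector("list", 0)
  a <- integer(n)
  rec <- function(i, maxc) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (c in seq_len(maxc + 1)) {
      a[i] <<- c
      rec(i + 1L, max(maxc, c))
    }
  }
  rec(1L, 0L)
  out
}

# Multilayer modularity computed independently in R from the definition
# (Newman-Girvan null per layer, ordinal coupling between adjacent layers;
# zero-weight layers contribute no null term).
q_multilayer_r <- function(A, labels, gamma, omega) {
  N <- dim(A)[1]
  L <- dim(A)[3]
  twomu <- 0
  q <- 0
  for (s in seq_len(L)) {
    As <- A[, , s]
    k <- rowSums(As)
    twom <- sum(k)
    Bs <- if (twom > 0) As - gamma * outer(k, k) / twom else As * 0
    same <- outer(labels[s, ], labels[s, ], "==")
    q <- q + sum(Bs[same])
    twomu <- twomu + twom
  }
  if (L > 1)
    for (s in seq_len(L - 1))
      q <- q + 2 * omega * sum(labels[s, ] == labels[s + 1, ])
  twomu <- twomu + 2 * omega * N * max(L - 1, 0)
  q / max(twomu, 1)
}

# Exhaustive-search maximum of the multilayer modularity over all joint
# partitions of the N*L node-layer tuples.
exhaustive_best_q <- function(A, gamma, omega) {
  N <- dim(A)[1]
  L <- dim(A)[3]
  parts <- enum_partitions(N * L)
  best <- -Inf
  for (p in parts) {
    labels <- matrix(p, nrow = L, ncol = N, byrow = TRUE)
    q <- q_multilayer_r(A, labels, gamma, omega)
    if (q > best) best <- q
  }
  best
}

# AUC by exhaustive pair counting (ties count 1/2).
auc_pairs <- function(scores, labels) {
  labels <- as.factor(labels)
  pos <- which(labels == levels(labels)[2])
  neg <- which(labels != levels(labels)[2])
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# All permutations of 1..n (tiny n only), for Hungarian-style state matching.
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Best state relabeling of a fitted HMM against true state means
# (maximum total mean-vector correlation over permutations).
match_states <- function(true_means, est_means) {
  K <- nrow(true_means)
  best <- NULL
  best_score <- -Inf
  for (p in all_perms(K)) {
    sc <- sum(vapply(seq_len(K), function(k)
      stats::cor(true_means[k, ], est_means[p[k], ]), numeric(1)))
    if (sc > best_score) {
      best_score <- sc
      best <- p
    }
  }
  best  # est state best[k] corresponds to true state k
}

# True state means in the standardized space the group HMM is fit in:
# z-score each subject's series and average frames by the true state path.
true_means_standardized <- function(cohort, K) {
  zs <- lapply(cohort$node_series, flexstates::zscore_series)
  N <- ncol(zs[[1]])
  sums <- matrix(0, K, N)
  counts <- numeric(K)
  for (i in seq_along(zs)) {
    path <- cohort$truth$paths[i, ]
    for (k in seq_len(K)) {
      idx <- which(path == k)
      if (length(idx)) {
        sums[k, ] <- sums[k, ] + colSums(zs[[i]][idx, , drop = FALSE])
        counts[k] <- counts[k] + length(idx)
      }
    }
  }
  sums / counts
}

# small planted two-clique multilayer instance: two 2-cliques per layer,
# one node swapping sides between layers
planted_swap_instance <- function() {
  A1 <- matrix(0, 4, 4)
  A1[1, 2] <- A1[2, 1] <- 1
  A1[3, 4] <- A1[4, 3] <- 1
  A1[2, 3] <- A1[3, 2] <- 0.25
  A2 <- matrix(0, 4, 4)
  A2[1, 2] <- A2[2, 1] <- 0.25
  A2[1, 3] <- A2[3, 1] <- 1
  A2[2, 4] <- A2[4, 2] <- 1
  array(c(A1, A2), dim = c(4, 4, 2))
}
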