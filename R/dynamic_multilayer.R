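#' Sliding-window correlation networks
#'
#' Rectangular windows of `window` time points advanced by
#' `step = round(window * (1 - overlap))`; per window, the Pearson
#' correlation matrix of the node series with negative entries truncated to 0
#' and the diagonal zeroed. At the conventional window = 40, overlap = 0.975
#' and T = 230 this yields step 1 and L = 191 layers.
#'
#' @param x time x nodes matrix (filtered parcel series).
#' @param window window length in time points.
#' @param overlap fractional overlap of consecutive windows in \[0, 1).
#' @return `multilayer_network`: list with `layers` (N x N x L array),
#'   `window`, `step`.
#' @export
sliding_windows <- function(x, window = 40L, overlap = 0.975) {
  x <- as.matrix(x)
  Tn <- nrow(x)
  window <- as.integer(window)
  if (Tn < window)
    stop(sprintf("T = %d is shorter than the window (%d)", Tn, window))
  step <- as.integer(round(window * (1 - overlap)))
  if (step < 1) stop("overlap too large: step must be >= 1")
  L <- (Tn - window) %/% step + 1L
  N <- ncol(x)
  layers <- array(0, dim = c(N, N, L))
  for (l in seq_len(L)) {
    idx <- ((l - 1L) * step + 1L):((l - 1L) * step + window)
    r <- suppressWarnings(stats::cor(x[idx, , drop = FALSE]))
    r[is.na(r)] <- 0
    r[r < 0] <- 0
    diag(r) <- 0
    layers[, , l] <- r
  }
  structure(list(layers = layers, window = window, step = step),
            class = "multilayer_network")
}

#' Multilayer modularity via an iterated Louvain optimizer
#'
#' Maximizes the multilayer modularity with a Newman-Girvan null model per
#' layer (resolution `gamma`) and ordinal inter-layer coupling `omega`
#' between a node and itself in adjacent layers. Optimization is Louvain-style
#' on node-layer tuples: seeded random single-node move sweeps to local
#' convergence, then greedy community merges, iterated; the best of
#' `restarts` seeded runs is kept. Layers with zero total weight contribute no
#' null-model term and are flagged.
#'
#' @param net a `multilayer_network` or an N x N x L array.
#' @param gamma intra-layer resolution.
#' @param omega ordinal inter-layer coupling.
#' @param seed RNG seed controlling node sweep order.
#' @param restarts seeded restarts; the partition with the highest quality is
#'   returned.
#' @return `community_sequence`: list with `labels` (L x N integer matrix),
#'   `Q`, `Q_trace` of the winning run, and `zero_weight_layers`.
#' @export
multilayer_modularity <- function(net, gamma = 1, omega = 1, seed = 1L,
                                  restarts = 3L) {
  A <- if (inherits(net, "multilayer_network")) net$layers else net
  if (length(dim(A)) == 2) A <- array(A, dim = c(dim(A), 1))
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    fit <- genlouvain_cpp(A, gamma, omega)
    if (is.null(best) || fit$Q > best$Q) best <- fit
  }
  structure(list(labels = best$labels, Q = best$Q, Q_trace = best$Q_trace,
                 zero_weight_layers = best$zero_weight_layers),
            class = "community_sequence")
}

#' Quality of an arbitrary multilayer partition
#'
#' Scores a given layers x nodes label matrix with the same multilayer
#' modularity definition the optimizer maximizes; mainly useful for checking
#' the optimizer against exhaustive search on small instances.
#'
#' @inheritParams multilayer_modularity
#' @param labels L x N integer matrix of community assignments.
#' @return the modularity value Q.
#' @export
multilayer_quality <- function(net, labels, gamma = 1, omega = 1) {
  A <- if (inherits(net, "multilayer_network")) net$layers else net
  if (length(dim(A)) == 2) A <- array(A, dim = c(dim(A), 1))
  multilayer_quality_cpp(A, as.matrix(labels), gamma, omega)
}

#' Node flexibility
#'
#' Fraction of adjacent layer pairs at which a node's community assignment
#' changes: `NF(i) = #{l : g[l+1, i] != g[l, i]} / (L - 1)`.
#'
#' @param cs a `community_sequence` or an L x N label matrix.
#' @return numeric vector of per-node flexibilities in \[0, 1\].
#' @export
node_flexibility <- function(cs) {
  labels <- if (inherits(cs, "community_sequence")) cs$labels else as.matrix(cs)
  L <- nrow(labels)
  if (L < 2) stop("node flexibility needs at least 2 layers")
  colMeans(labels[-1, , drop = FALSE] != labels[-L, , drop = FALSE])
}

#' Node flexibility over a (gamma, omega) parameter grid
#'
#' One multilayer-modularity run and flexibility vector per grid cell; at the
#' default 3 x 3 grid on 90 nodes this emits the 810 dynamic
#' network-flexibility features.
#'
#' @param x time x nodes matrix (filtered parcel series).
#' @param gammas,omegas parameter grids.
#' @param window,overlap sliding-window parameters.
#' @param seed RNG seed (each cell uses a distinct derived seed).
#' @param restarts restarts per cell.
#' @return named numeric vector of length `length(gammas) * length(omegas) *
#'   ncol(x)`, names `NF_g{i}_o{j}_parcel{k}` in row-major (gamma-outer)
#'   order.
#' @export
flexibility_grid <- function(x, gammas = c(0.9, 1, 1.1),
                             omegas = c(0.5, 0.75, 1),
                             window = 40L, overlap = 0.975,
                             seed = 1L, restarts = 3L) {
  if (!length(gammas) || !length(omegas)) stop("parameter grids must be non-empty")
  net <- sliding_windows(x, window, overlap)
  N <- ncol(x)
  out <- numeric(0)
  cell <- 0L
  for (gi in seq_along(gammas)) {
    for (oi in seq_along(omegas)) {
      cell <- cell + 1L
      cs <- multilayer_modularity(net, gammas[gi], omegas[oi],
                                  seed = seed + 1000L * cell,
                                  restarts = restarts)
      nf <- node_flexibility(cs)
      names(nf) <- sprintf("NF_g%d_o%d_parcel%03d", gi, oi, seq_len(N))
      out <- c(out, nf)
    }
  }
  out
}
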