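#' Fractional amplitude of low-frequency fluctuation (fALFF)
#'
#' Sum of FFT amplitudes over a frequency band divided by the sum over all
#' positive frequencies of the (detrended, unfiltered) series. Band membership
#' is half-open, `low <= f < high`, so the slow-5 (0.01-0.027 Hz) and slow-4
#' (0.027-0.073 Hz) bands partition the spectrum without double counting.
#' A Hann taper is applied before the FFT by default: the amplitude sum is
#' dominated by sidelobe leakage for off-bin components under a rectangular
#' window, and the taper bounds that leakage while leaving the flat
#' white-noise expectation (band-bin fraction) unchanged.
#'
#' @param x numeric matrix (time x signals) or vector; should be detrended
#'   but not band-pass filtered.
#' @param band length-2 band in Hz.
#' @param tr_seconds repetition time in seconds.
#' @param taper `"hann"` (default) or `"none"` (rectangular).
#' @return named numeric vector of fALFF values in \[0, 1\], one per column;
#'   a flat (zero-amplitude) column gets 0 with attribute
#'   `degenerate` marking it.
#' @export
falff <- function(x, band = c(0.01, 0.027), tr_seconds,
                  taper = c("hann", "none")) {
  taper <- match.arg(taper)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  Tn <- nrow(x)
  nyq <- 1 / (2 * tr_seconds)
  if (band[1] <= 0 || band[2] > nyq + 1e-12 || band[1] >= band[2])
    stop(sprintf("band [%g, %g) Hz must lie within (0, Nyquist = %g]",
                 band[1], band[2], nyq))
  f <- fft_freqs(Tn, tr_seconds)
  pos <- which(f > 0 & f <= nyq + 1e-12)
  inband <- f[pos] >= band[1] - 1e-12 & f[pos] < band[2] - 1e-12
  if (!any(inband))
    stop(sprintf("no FFT bin falls in [%g, %g) Hz at T = %d, TR = %g; increase T",
                 band[1], band[2], Tn, tr_seconds))
  xm <- as.matrix(x)
  flat <- apply(xm, 2, function(cl) max(cl) - min(cl)) == 0
  if (taper == "hann")
    xm <- xm * (0.5 * (1 - cos(2 * pi * (seq_len(Tn) - 1) / (Tn - 1))))
  amp <- Mod(stats::mvfft(xm))[pos, , drop = FALSE]
  denom <- colSums(amp)
  num <- colSums(amp[inband, , drop = FALSE])
  degenerate <- flat | denom <= 0
  out <- ifelse(degenerate, 0, num / denom)
  attr(out, "degenerate") <- degenerate
  out
}

neighborhood_offsets <- function(neighborhood) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  keep <- switch(as.character(neighborhood),
                 "7"  = d <= 1,
                 "19" = d <= 2,
                 "27" = rep(TRUE, 27),
                 stop("neighborhood must be 7, 19 or 27"))
  as.matrix(g[keep, ])
}

#' Regional homogeneity (ReHo) voxel map
#'
#' Kendall's coefficient of concordance W of each voxel's time course with its
#' spatial neighbors: with K in-mask neighbor series (center included) ranked
#' over n time points and per-time rank sums R_t,
#' `W = 12 * sum_t (R_t - mean(R))^2 / (K^2 (n^3 - n))`. Voxels at mask edges
#' use the available in-mask neighbors (K adjusted); no tie correction.
#'
#' @param vol 4D array (x, y, z, t) of band-pass filtered data.
#' @param mask 3D logical/integer array; voxels with value > 0 are in-mask.
#' @param neighborhood 7, 19 or 27 (center plus faces / +edges / +corners).
#' @return 3D array of W values in \[0, 1\] (0 outside the mask).
#' @export
reho <- function(vol, mask, neighborhood = 27) {
  dims <- dim(vol)
  Tn <- dims[4]
  if (Tn < 3) stop("regional homogeneity needs at least 3 time points")
  inmask <- array(mask > 0, dim = dims[1:3])
  vox <- which(inmask)
  V <- length(vox)
  flat <- matrix(aperm(vol, c(4, 1, 2, 3)), nrow = Tn)  # time x all voxels
  ranks <- matrix(0, Tn, prod(dims[1:3]))
  ranks[, vox] <- apply(flat[, vox, drop = FALSE], 2, rank)
  offs <- neighborhood_offsets(neighborhood)
  coord <- arrayInd(vox, dims[1:3])
  rsum <- matrix(0, Tn, V)
  kcount <- integer(V)
  lin <- function(cc) (cc[, 3] - 1) * dims[1] * dims[2] +
    (cc[, 2] - 1) * dims[1] + cc[, 1]
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coord, 2, offs[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    idx <- which(ok)
    nbl <- lin(nb[idx, , drop = FALSE])
    ok2 <- inmask[nbl]
    idx <- idx[ok2]
    nbl <- nbl[ok2]
    if (length(idx)) {
      rsum[, idx] <- rsum[, idx] + ranks[, nbl, drop = FALSE]
      kcount[idx] <- kcount[idx] + 1L
    }
  }
  dev <- sweep(rsum, 2, colMeans(rsum))
  W <- 12 * colSums(dev^2) / (kcount^2 * (Tn^3 - Tn))
  out <- array(0, dim = dims[1:3])
  out[vox] <- pmin(pmax(W, 0), 1)
  out
}

#' Binary and weighted degree centrality
#'
#' Pearson correlation of every in-mask signal with every other; edges are
#' correlations strictly above `r_threshold` (negative correlations never
#' count). BDC counts edges, WDC sums their weights.
#'
#' @param x numeric matrix, time x signals (filtered data).
#' @param r_threshold correlation threshold (default 0.25).
#' @return list with numeric vectors `bdc` and `wdc` (one entry per signal)
#'   and logical `zero_variance` flagging signals with no variance (their
#'   correlations are treated as 0).
#' @export
degree_centrality <- function(x, r_threshold = 0.25) {
  V <- ncol(x)
  if (V < 2) stop("need at least 2 signals")
  sds <- apply(x, 2, stats::sd)
  zero <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 0
  edge <- r > r_threshold
  list(bdc = as.numeric(rowSums(edge)),
       wdc = as.numeric(rowSums(r * edge)),
       zero_variance = zero)
}

#' Aggregate a voxel map to parcel means
#'
#' @param voxel_map 3D numeric array.
#' @param atlas 3D integer label array (0 = background).
#' @return named numeric vector, one arithmetic mean per label, ordered by
#'   label id.
#' @export
parcel_aggregate <- function(voxel_map, atlas) {
  labs <- sort(unique(as.vector(atlas[atlas > 0])))
  expect <- seq_len(max(labs))
  missing <- setdiff(expect, labs)
  if (length(missing))
    stop("empty parcels: ", paste(missing, collapse = ", "))
  out <- vapply(labs, function(l) mean(voxel_map[atlas == l]), numeric(1))
  names(out) <- sprintf("parcel%03d", labs)
  out
}

#' Extract mean parcel time series from a 4D volume
#'
#' @param vol 4D array (x, y, z, t).
#' @param atlas 3D label array.
#' @return time x parcels matrix.
#' @export
extract_parcel_series <- function(vol, atlas) {
  dims <- dim(vol)
  flat <- matrix(aperm(vol, c(4, 1, 2, 3)), nrow = dims[4])
  lab <- as.vector(atlas)
  labs <- sort(unique(lab[lab > 0]))
  out <- vapply(labs, function(l) rowMeans(flat[, lab == l, drop = FALSE]),
                numeric(dims[4]))
  colnames(out) <- sprintf("parcel%03d", labs)
  out
}

# canonical fALFF band definitions (slow-5, slow-4)
falff_bands <- function() list(f1ALFF = c(0.01, 0.027), f2ALFF = c(0.027, 0.073))

#' Voxel-mode static feature block for one subject
#'
#' Runs the temporal preprocessing per voxel, computes the five static metrics
#' (f1ALFF and f2ALFF on the detrended series; ReHo, binary and weighted
#' degree centrality on the filtered series) and averages each voxel map
#' within atlas parcels.
#'
#' @param vol raw 4D array (x, y, z, t).
#' @param atlas 3D label array.
#' @param tr_seconds repetition time.
#' @param n_drop leading volumes to drop.
#' @param r_threshold degree-centrality correlation threshold.
#' @param neighborhood ReHo neighborhood size.
#' @return named numeric vector of `5 * n_parcels` features in block order
#'   f1ALFF, f2ALFF, ReHo, BDC, WDC.
#' @export
static_features_voxel <- function(vol, atlas, tr_seconds, n_drop = 10L,
                                  r_threshold = 0.25, neighborhood = 27) {
  dims <- dim(vol)
  lab <- as.vector(atlas)
  vox <- which(lab > 0)
  flat <- matrix(aperm(vol, c(4, 1, 2, 3)), nrow = dims[4])[, vox, drop = FALSE]
  pp <- preprocess_series(flat, n_drop = n_drop, tr_seconds = tr_seconds)
  bands <- falff_bands()
  f1 <- falff(pp$detrended$data, bands$f1ALFF, tr_seconds)
  f2 <- falff(pp$detrended$data, bands$f2ALFF, tr_seconds)
  to_map <- function(v) {
    m <- array(0, dim = dims[1:3])
    m[vox] <- v
    m
  }
  Tn <- nrow(pp$filtered$data)
  filt_vol <- array(0, dim = c(dims[1:3], Tn))
  filt_flat <- matrix(0, prod(dims[1:3]), Tn)
  filt_flat[vox, ] <- t(pp$filtered$data)
  filt_vol[] <- filt_flat
  mask <- array(FALSE, dims[1:3])
  mask[vox] <- TRUE
  reho_map <- reho(filt_vol, mask, neighborhood)
  dc <- degree_centrality(pp$filtered$data, r_threshold)
  blocks <- list(f1ALFF = parcel_aggregate(to_map(f1), atlas),
                 f2ALFF = parcel_aggregate(to_map(f2), atlas),
                 ReHo = parcel_aggregate(reho_map, atlas),
                 BDC = parcel_aggregate(to_map(dc$bdc), atlas),
                 WDC = parcel_aggregate(to_map(dc$wdc), atlas))
  unlist_feature_blocks(blocks)
}

#' Node-mode static feature block for one subject
#'
#' As [static_features_voxel()] but on parcel time series directly. Regional
#' homogeneity is a voxel-neighborhood quantity and is not defined on a node
#' series; requesting it in node mode is an error.
#'
#' @param series raw time x parcels matrix.
#' @param tr_seconds repetition time.
#' @param n_drop leading volumes to drop.
#' @param r_threshold degree-centrality correlation threshold.
#' @param include_reho must be `FALSE` in node mode.
#' @return named numeric vector of `4 * n_parcels` features (f1ALFF, f2ALFF,
#'   BDC, WDC).
#' @export
static_features_node <- function(series, tr_seconds, n_drop = 10L,
                                 r_threshold = 0.25, include_reho = FALSE) {
  if (isTRUE(include_reho))
    stop("ReHo is undefined on node series: use voxel mode")
  pp <- preprocess_series(series, n_drop = n_drop, tr_seconds = tr_seconds)
  bands <- falff_bands()
  nm <- sprintf("parcel%03d", seq_len(ncol(series)))
  f1 <- stats::setNames(as.numeric(falff(pp$detrended$data, bands$f1ALFF, tr_seconds)), nm)
  f2 <- stats::setNames(as.numeric(falff(pp$detrended$data, bands$f2ALFF, tr_seconds)), nm)
  dc <- degree_centrality(pp$filtered$data, r_threshold)
  blocks <- list(f1ALFF = f1, f2ALFF = f2,
                 BDC = stats::setNames(dc$bdc, nm),
                 WDC = stats::setNames(dc$wdc, nm))
  unlist_feature_blocks(blocks)
}

# flatten named metric blocks into metric_parcel feature names
unlist_feature_blocks <- function(blocks) {
  out <- unlist(lapply(names(blocks), function(m)
    stats::setNames(blocks[[m]], paste0(m, "_", names(blocks[[m]])))))
  out
}
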