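test_that("fALFF handles flat series, band sinusoids and band partitioning", {
  tr <- 2
  tt <- seq_len(230) * tr
  flat <- rep(2, 230)
  out <- falff(flat, c(0.01, 0.027), tr)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
  s <- sin(2 * pi * 0.02 * tt)
  expect_gt(falff(s, c(0.01, 0.027), tr), 0.9)
  # a slow-4 component contributes to f2, not f1
  s4 <- sin(2 * pi * 0.05 * tt)
  expect_gt(falff(s4, c(0.027, 0.073), tr), 0.9)
  expect_lt(falff(s4, c(0.01, 0.027), tr), 0.1)
  expect_error(falff(s, c(0.0001, 0.0002), tr), "bin")
  # disjoint-band property: f1 + f2 never exceeds 1
  set.seed(4)
  x <- matrix(rnorm(230 * 50), 230, 50)
  f1 <- falff(x, c(0.01, 0.027), tr)
  f2 <- falff(x, c(0.027, 0.073), tr)
  expect_true(all(f1 + f2 <= 1 + 1e-9))
  expect_true(all(f1 >= 0 & f1 <= 1))
})

test_that("ReHo is 1 for identical neighbors and matches the brute-force W", {
  # 27 identical series in a full 3x3x3 block
  Tn <- 30
  base <- rnorm(Tn)
  vol <- array(rep(base, each = 27), dim = c(3, 3, 3, Tn))
  vol <- aperm(array(base, dim = c(Tn, 3, 3, 3)), c(2, 3, 4, 1))
  w <- reho(vol, array(1, c(3, 3, 3)), 27)
  expect_equal(w[2, 2, 2], 1, tolerance = 1e-12)
  # random volumes vs independent closed-form evaluation, all neighborhoods,
  # center and corner (edge-truncated) voxels
  set.seed(21)
  for (nb in c(7, 19, 27)) {
    for (Tn in c(20, 50)) {
      vol <- array(rnorm(27 * Tn), dim = c(3, 3, 3, Tn))
      w <- reho(vol, array(1, c(3, 3, 3)), nb)
      offs <- flexstates:::neighborhood_offsets(nb)
      # center voxel (2,2,2): all offsets in-volume
      nbrs <- t(apply(offs, 1, function(o) c(2, 2, 2) + o))
      X <- sapply(seq_len(nrow(nbrs)), function(i)
        vol[nbrs[i, 1], nbrs[i, 2], nbrs[i, 3], ])
      expect_equal(w[2, 2, 2], brute_kendall_w(X), tolerance = 1e-12)
      # corner voxel (1,1,1): truncated neighborhood
      nbrs <- t(apply(offs, 1, function(o) c(1, 1, 1) + o))
      keep <- apply(nbrs, 1, function(v) all(v >= 1 & v <= 3))
      nbrs <- nbrs[keep, , drop = FALSE]
      X <- sapply(seq_len(nrow(nbrs)), function(i)
        vol[nbrs[i, 1], nbrs[i, 2], nbrs[i, 3], ])
      expect_equal(w[1, 1, 1], brute_kendall_w(X), tolerance = 1e-12)
    }
  }
})

test_that("ReHo is invariant under monotone transforms and small under independence", {
  set.seed(22)
  vol <- array(rnorm(27 * 40), dim = c(3, 3, 3, 40))
  mask <- array(1, c(3, 3, 3))
  w1 <- reho(vol, mask, 27)
  w2 <- reho(exp(2 * vol), mask, 27)  # strictly monotone transform
  expect_equal(w1, w2, tolerance = 1e-12)
  # independent series: W concentrates near 0 (null Monte Carlo)
  ws <- replicate(100, {
    v <- array(rnorm(27 * 230), dim = c(3, 3, 3, 230))
    reho(v, mask, 27)[2, 2, 2]
  })
  expect_lt(stats::quantile(ws, 0.99), 0.15)
})

test_that("degree centrality counts and sums suprathreshold positive edges", {
  set.seed(23)
  # all identical signals
  x <- matrix(rep(rnorm(50), 4), 50, 4)
  dc <- degree_centrality(x, 0.25)
  expect_equal(dc$bdc, rep(3, 4))
  expect_equal(dc$wdc, rep(3, 4), tolerance = 1e-12)
  # impossible threshold
  expect_equal(degree_centrality(x, 1.0)$bdc, rep(0, 4))
  # correlated pair found, independent voxel excluded (T large)
  base <- rnorm(230)
  y <- cbind(base, base + rnorm(230, 0, 0.1), rnorm(230))
  dcy <- degree_centrality(y, 0.25)
  expect_gte(dcy$bdc[1], 1)
  expect_gte(dcy$bdc[2], 1)
  # oracle: direct correlation computation
  r <- stats::cor(y)
  expect_equal(dcy$bdc[3], sum(r[3, -3] > 0.25))
  expect_equal(dcy$wdc[1], sum(r[1, -1][r[1, -1] > 0.25]), tolerance = 1e-12)
  # zero-variance signal flagged, no edges
  z <- cbind(rnorm(40), rep(1, 40))
  dcz <- degree_centrality(z, 0.25)
  expect_true(dcz$zero_variance[2])
  expect_equal(dcz$bdc[2], 0)
})

test_that("degree centrality is monotone non-increasing in the threshold", {
  set.seed(24)
  x <- matrix(rnorm(100 * 8), 100, 8) + rnorm(100)
  thr <- c(0, 0.1, 0.25, 0.5, 0.9)
  res <- lapply(thr, function(th) degree_centrality(x, th))
  for (i in seq_along(thr)[-1]) {
    expect_true(all(res[[i]]$bdc <= res[[i - 1]]$bdc))
    expect_true(all(res[[i]]$wdc <= res[[i - 1]]$wdc + 1e-12))
  }
})

test_that("parcel aggregation is an exact group-by mean", {
  atlas <- array(c(1, 1, 2, 2, 3, 3, 0, 0), dim = c(2, 2, 2))
  cmap <- array(5, dim = c(2, 2, 2))
  expect_equal(unname(parcel_aggregate(cmap, atlas)), rep(5, 3))
  set.seed(25)
  vmap <- array(rnorm(8), dim = c(2, 2, 2))
  agg <- parcel_aggregate(vmap, atlas)
  oracle <- tapply(as.vector(vmap)[as.vector(atlas) > 0],
                   as.vector(atlas)[as.vector(atlas) > 0], mean)
  expect_equal(unname(agg), unname(as.numeric(oracle)), tolerance = 1e-12)
  # one-voxel parcels: identity
  atlas1 <- array(1:8, dim = c(2, 2, 2))
  expect_equal(unname(parcel_aggregate(vmap, atlas1)), as.vector(vmap))
  # empty parcel error names the label
  atlas_gap <- array(c(1, 1, 3, 3, 3, 3, 3, 3), dim = c(2, 2, 2))
  expect_error(parcel_aggregate(vmap, atlas_gap), "2")
})

test_that("voxel-mode fALFF on noise-free volumes equals node-mode fALFF", {
  cfg <- sim_config(n_patients = 1, n_controls = 0, n_parcels = 5,
                    n_volumes = 120, n_states = 3, voxel_noise_sd = 0,
                    seed = 31)
  co <- simulate_cohort(cfg, volumes = TRUE)
  vox <- static_features_voxel(co$volumes[[1]], co$atlas, tr_seconds = 2,
                               n_drop = 10)
  nod <- static_features_node(co$node_series[[1]], tr_seconds = 2, n_drop = 10)
  for (blk in c("f1ALFF", "f2ALFF")) {
    vi <- vox[grep(blk, names(vox))]
    ni <- nod[grep(blk, names(nod))]
    expect_equal(unname(vi), unname(ni), tolerance = 1e-8)
  }
})

test_that("node mode refuses ReHo", {
  x <- matrix(rnorm(100 * 4), 100, 4)
  expect_error(static_features_node(x, 2, include_reho = TRUE), "voxel mode")
})
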