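test_that("sliding windows follow the stated layer arithmetic", {
  x <- matrix(rnorm(230 * 4), 230, 4)
  net <- sliding_windows(x, 40, 0.975)
  expect_equal(net$step, 1L)
  expect_equal(dim(net$layers)[3], 191L)
  net0 <- sliding_windows(x, 40, 0)
  expect_equal(net0$step, 40L)
  expect_equal(dim(net0$layers)[3], 5L)
  expect_error(sliding_windows(x[1:30, ], 40), "shorter")
  # negative correlations truncated to zero
  y <- cbind(x[, 1], -x[, 1] + rnorm(230, 0, 1e-6))
  nety <- sliding_windows(y, 40, 0.5)
  expect_true(all(nety$layers[1, 2, ] == 0))
  # diagonals zero, weights non-negative, symmetric
  expect_true(all(apply(net$layers, 3, function(A) all(diag(A) == 0))))
  expect_true(all(net$layers >= 0))
})

test_that("node flexibility is the fraction of adjacent-layer label changes", {
  lab <- matrix(1, 5, 3)
  expect_equal(node_flexibility(lab), c(0, 0, 0))
  alt <- cbind(rep(1:2, length.out = 191), rep(1, 191))
  expect_equal(node_flexibility(alt), c(1, 0))
  one <- matrix(1, 191, 1)
  one[100, 1] <- 2
  # entering and leaving state 2 are two changes
  expect_equal(node_flexibility(one), 2 / 190)
  one2 <- matrix(1, 191, 1)
  one2[191, 1] <- 2
  expect_equal(node_flexibility(one2), 1 / 190)
  expect_error(node_flexibility(matrix(1, 1, 3)), "2 layers")
  # permutation-equivalence: relabeling does not change NF
  set.seed(1)
  lab <- matrix(sample(1:3, 60, TRUE), 10, 6)
  perm <- c(3, 1, 2)
  expect_equal(node_flexibility(lab), node_flexibility(matrix(perm[lab], 10, 6)))
})

test_that("single-layer modularity finds planted cliques with the exact Q", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  cs <- multilayer_modularity(array(A, c(6, 6, 1)), gamma = 1, omega = 0,
                              seed = 1)
  expect_equal(length(unique(cs$labels[1, ])), 2)
  expect_equal(cs$labels[1, 1:3], rep(cs$labels[1, 1], 3))
  # closed form: two equal cliques, Q = 1 - 2 * (6/24)^2... compute directly
  q_hand <- q_multilayer_r(array(A, c(6, 6, 1)),
                           matrix(c(1, 1, 1, 2, 2, 2), 1, 6), 1, 0)
  expect_equal(cs$Q, q_hand, tolerance = 1e-12)
})

test_that("strong coupling freezes communities across layers (NF = 0)", {
  set.seed(2)
  x <- matrix(rnorm(120 * 6), 120, 6)
  net <- sliding_windows(x, 40, 0.5)
  cs <- multilayer_modularity(net, gamma = 1, omega = 100, seed = 1)
  expect_equal(unname(node_flexibility(cs)), rep(0, 6))
})

test_that("optimizer attains the exhaustive optimum on the planted swap instance", {
  A <- planted_swap_instance()
  best <- exhaustive_best_q(A, 1, 0.5)
  cs <- multilayer_modularity(A, gamma = 1, omega = 0.5, seed = 1,
                              restarts = 3)
  expect_equal(cs$Q, best, tolerance = 1e-9)
  # the package's partition scorer agrees with the independent one
  expect_equal(multilayer_quality(A, cs$labels, 1, 0.5), cs$Q,
               tolerance = 1e-12)
})

test_that("modularity trace never decreases and labels relabel-invariantly", {
  set.seed(3)
  x <- matrix(rnorm(150 * 8), 150, 8)
  net <- sliding_windows(x, 50, 0.5)
  cs <- multilayer_modularity(net, 1, 0.75, seed = 4)
  expect_true(all(diff(cs$Q_trace) > -1e-10))
  expect_true(all(cs$labels >= 1))
})

test_that("flexibility grid emits one labelled block per parameter cell", {
  set.seed(5)
  x <- matrix(rnorm(120 * 6), 120, 6)
  nf <- flexibility_grid(x, gammas = c(0.9, 1, 1.1), omegas = c(0.5, 0.75, 1),
                         window = 40, overlap = 0.5, seed = 9, restarts = 2)
  expect_length(nf, 9 * 6)
  expect_equal(names(nf)[1], "NF_g1_o1_parcel001")
  expect_equal(names(nf)[54], "NF_g3_o3_parcel006")
  # single-cell grid equals a direct call
  nf1 <- flexibility_grid(x, gammas = 1, omegas = 0.75, window = 40,
                          overlap = 0.5, seed = 9, restarts = 2)
  net <- sliding_windows(x, 40, 0.5)
  direct <- node_flexibility(
    multilayer_modularity(net, 1, 0.75, seed = 9 + 1000L, restarts = 2))
  expect_equal(unname(nf1), unname(direct))
  # determinism
  expect_identical(nf, flexibility_grid(x, gammas = c(0.9, 1, 1.1),
                                        omegas = c(0.5, 0.75, 1),
                                        window = 40, overlap = 0.5,
                                        seed = 9, restarts = 2))
})

test_that("stronger coupling suppresses flexibility on average", {
  set.seed(6)
  nf_lo <- nf_hi <- numeric(0)
  for (s in 1:12) {
    x <- matrix(rnorm(120 * 6), 120, 6)
    net <- sliding_windows(x, 40, 0.5)
    nf_lo <- c(nf_lo, node_flexibility(
      multilayer_modularity(net, 1, 0.25, seed = s, restarts = 1)))
    nf_hi <- c(nf_hi, node_flexibility(
      multilayer_modularity(net, 1, 2, seed = s, restarts = 1)))
  }
  expect_lte(mean(nf_hi), mean(nf_lo))
})

test_that("a zero-weight layer is flagged and handled", {
  A <- array(0, c(4, 4, 2))
  A[1, 2, 1] <- A[2, 1, 1] <- 1  # layer 2 empty
  cs <- multilayer_modularity(A, 1, 0.5, seed = 1)
  expect_equal(cs$zero_weight_layers, 1L)
  expect_true(is.finite(cs$Q))
})
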