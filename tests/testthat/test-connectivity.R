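test_that("average referencing zeroes the channel mean at every sample", {
  lay <- mini_layout()
  set.seed(1)
  dat <- array(rnorm(2 * nrow(lay) * 256), c(2, nrow(lay), 256))
  ep <- make_epochs(dat, 512, 0, lay, rep("rest", 2))
  out <- average_reference(ep)
  scalp_idx <- match(paste0("S", 1:16), lay$label)
  for (tr in 1:2) {
    expect_equal(max(abs(colMeans(out$data[tr, scalp_idx, ]))), 0,
                 tolerance = 1e-12)
  }
  # arithmetic oracle on one sample
  expect_equal(unname(out$data[1, scalp_idx[3], 10]),
               dat[1, scalp_idx[3], 10] - mean(dat[1, scalp_idx, 10]))
  # a common signal on all scalp channels vanishes
  common <- array(rep(sin(seq_len(256) / 10), each = 2 * nrow(lay)),
                  c(2, nrow(lay), 256))
  out2 <- average_reference(make_epochs(common, 512, 0, lay, rep("rest", 2)))
  expect_equal(max(abs(out2$data[, scalp_idx, ])), 0, tolerance = 1e-12)
})

test_that("PLI hits its definitional limits", {
  fs <- 512
  t <- seq(0, 8 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 10 * t)
  y <- sin(2 * pi * 10 * t - pi / 4)
  expect_equal(pli_pair(x, y, fs = fs, edge_trim = 0.5), 1, tolerance = 1e-6)
  expect_equal(pli_pair(x, x, fs = fs, edge_trim = 0.5), 0)
  # symmetry and amplitude invariance
  set.seed(2)
  a <- rnorm(1024); b <- rnorm(1024)
  expect_equal(pli_pair(a, b), pli_pair(b, a))
  expect_equal(pli_pair(5 * a, 0.1 * b), pli_pair(a, b))
  expect_error(pli_pair(rep(1, 1024), a), "constant")
  expect_error(pli_pair(a, b[1:512]), "equal length")
  expect_error(pli_pair(a[1:32], b[1:32]), "too short")
})

test_that("independent noise gives a small PLI on average", {
  set.seed(3)
  vals <- replicate(100, pli_pair(rnorm(4096), rnorm(4096)))
  expect_lt(mean(vals), 0.05)
})

test_that("subject PLI surfaces an injected coupled pair above the background", {
  lags <- list(alpha = data.frame(ch1 = 2, ch2 = 7, lag = pi / 4, coupling = 0.9))
  truth <- ground_truth(noise_scale = c(wet = 0, dry = 0),
                        resting_phase_lags = lags, seed = 1)
  rec <- simulate_rest_recording(truth, mini_layout(), "wet", duration = 24,
                                 seed = 4)
  ep <- epoch_recording(rec, NULL, rest_len = 8)
  res <- subject_pli(ep, band = "alpha", average_ref = FALSE)
  i <- match(c("S2", "S7"), res$labels)
  off <- res$matrix[upper.tri(res$matrix)]
  expect_gt(res$matrix[i[1], i[2]], stats::median(off) + 3 * stats::mad(off))
  expect_true(all(res$matrix >= 0 & res$matrix <= 1))
  expect_true(res$mean_pli >= 0 && res$mean_pli <= 1)
  expect_equal(res$matrix, t(res$matrix))
  expect_equal(diag(res$matrix), rep(0, nrow(res$matrix)))
  # single-epoch input: matrix equals that epoch's matrix
  ep1 <- ep; ep1$kept[-1] <- FALSE
  res1 <- subject_pli(ep1, band = "alpha", average_ref = FALSE)
  expect_equal(res1$n_epochs, 1)
})

test_that("PLI-to-distance transforms are monotone and hit their endpoints", {
  expect_equal(pli_to_distance(matrix(c(0, 1, 1, 0), 2)), matrix(c(0, 0, 0, 0), 2))
  m0 <- matrix(c(0, 0, 0, 0), 2)
  expect_equal(pli_to_distance(m0)[1, 2], 1)
  expect_equal(pli_to_distance(m0, "inverse")[1, 2], Inf)
  set.seed(5)
  p <- matrix(runif(25), 5); p <- (p + t(p)) / 2; diag(p) <- 0
  d1 <- pli_to_distance(p); d2 <- pli_to_distance(p, "inverse")
  ij <- which(upper.tri(p), arr.ind = TRUE)
  ord <- order(p[upper.tri(p)])
  expect_equal(order(d1[upper.tri(d1)], decreasing = TRUE), ord)
  expect_equal(order(d2[upper.tri(d2)], decreasing = TRUE), ord)
  expect_error(pli_to_distance(matrix(c(0, 2, 2, 0), 2)), "0, 1")
})

test_that("MST diameter matches path and star constructions", {
  d4 <- matrix(10, 4, 4); diag(d4) <- 0
  for (i in 1:3) d4[i, i + 1] <- d4[i + 1, i] <- 1
  m <- mst_diameter(d4)
  expect_equal(m$d, 3); expect_equal(m$M, 3); expect_equal(m$D, 1)
  d5 <- matrix(10, 5, 5); diag(d5) <- 0
  d5[1, 2:5] <- d5[2:5, 1] <- 1
  s <- mst_diameter(d5)
  expect_equal(s$d, 2); expect_equal(s$M, 4); expect_equal(s$D, 0.5)
  expect_equal(nrow(s$edges), 4)
  expect_error(mst_diameter(matrix(c(0, Inf, Inf, 0), 2)), "finite")
})

test_that("Kruskal agrees with an independent MST implementation", {
  skip_if_not_installed("igraph")
  set.seed(6)
  for (k in 1:20) {
    n <- sample(5:10, 1)
    d <- matrix(runif(n * n), n); d <- (d + t(d)) / 2; diag(d) <- 0
    ours <- mst_diameter(d)
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    ig <- igraph::mst(g, algorithm = "prim")
    expect_equal(sum(ours$edges$distance),
                 sum(igraph::E(ig)$weight), tolerance = 1e-12)
  }
})

test_that("the normalized diameter only depends on the weight order", {
  set.seed(7)
  for (k in 1:10) {
    n <- 8
    p <- matrix(runif(n * n, 0.05, 0.95), n); p <- (p + t(p)) / 2; diag(p) <- 0
    D1 <- mst_diameter(pli_to_distance(p))$D
    D2 <- mst_diameter(pli_to_distance(p, "inverse"))$D
    expect_equal(D1, D2)
  }
})
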