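test_that("translation composes source encoder with target decoder", {
  tm <- trained_model(1)
  m <- tm$model
  X1 <- tm$bench$datasets[[1]]
  # self-translation is the autoencoder reconstruction
  self <- translate(X1, m, 1, 1)
  Z <- encode_modality(m, X1, 1)
  expect_equal(self$translated, decode_modality(m, Z, 1), tolerance = 1e-12)

  # cross-translation has the target modality's shape
  tr <- translate(tm$bench$datasets[[2]], m, 2, 1)
  expect_equal(dim(tr$translated), dim(as.matrix(X1)))
  back <- translate(X1, m, 1, 2)
  expect_equal(attr(back$translated, "vol_shape"), c(32L, 32L, 32L))

  # determinism given the same checkpoint and input
  expect_identical(tr$translated, translate(tm$bench$datasets[[2]], m, 2, 1)$translated)
  expect_error(translate(X1, m, 1, 5), "out of range")
})

test_that("translated cells land nearer their true partner than a random cell", {
  tm <- trained_model(1)
  X1 <- as.matrix(tm$bench$datasets[[1]])
  tr <- translate(tm$bench$datasets[[2]], m <- tm$model, 2, 1)$translated
  inv <- match(seq_len(nrow(X1)), tm$bench$pairing)  # m2 row -> m1 row
  hits <- with_seed(99, vapply(seq_len(nrow(tr)), function(k) {
    truth <- sqrt(sum((tr[k, ] - X1[inv[k], ])^2))
    other <- sample(setdiff(seq_len(nrow(X1)), inv[k]), 1)
    truth < sqrt(sum((tr[k, ] - X1[other, ])^2))
  }, logical(1)))
  expect_gt(mean(hits), 0.7)
})

test_that("Welch's t-test matches the textbook formula", {
  a <- c(2, 2, 2, 5, 5, 5)
  w <- welch_t(a, a)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)

  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 8)
  w1 <- welch_t(x, y)
  w2 <- welch_t(y, x)
  expect_equal(w1$t, -w2$t, tolerance = 1e-12)
  expect_equal(w1$p, w2$p, tolerance = 1e-12)
  oracle <- welch_oracle(x, y)
  expect_equal(w1$t, oracle$t, tolerance = 1e-10)
  expect_equal(w1$p, oracle$p, tolerance = 1e-10)

  expect_error(welch_t(1, y), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04),
               tolerance = 1e-12)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  set.seed(6)
  p <- runif(50)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p - 1e-15))
  expect_true(all(adj <= 1))
  expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
  expect_error(benjamini_hochberg(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("marker calling flags planted signals and respects top_n", {
  set.seed(10)
  n <- 400
  X <- matrix(rnorm(n * 30), n, 30)
  labels <- rep(c("A", "B"), each = n / 2)
  null_mt <- marker_genes(X, labels)
  expect_equal(sum(null_mt$marker_group != ""), 0)

  X2 <- X
  X2[labels == "A", 7] <- X2[labels == "A", 7] + 10
  mt <- marker_genes(X2, labels)
  expect_equal(mt$marker_group[7], "A")
  expect_true(all(mt$p_adj >= mt$p - 1e-15))
  # marker flags imply significance and the top-|diff| cut
  flagged <- which(mt$marker_group != "")
  expect_true(all(mt$p_adj[flagged] < 0.05))

  mt0 <- marker_genes(X2, labels, top_n = 0)
  expect_equal(sum(mt0$marker_group != ""), 0)
  expect_equal(nrow(mt0), 30)
  expect_error(marker_genes(X2, rep("A", n)), "exactly 2")
})

test_that("fold-change concordance reduces to a Pearson correlation", {
  set.seed(12)
  X <- matrix(rnorm(100 * 20), 100, 20)
  lab <- rep(1:2, each = 50)
  same <- fold_change_concordance(X, lab, X, lab)
  expect_equal(same$pearson_r, 1, tolerance = 1e-12)

  neg <- fold_change_concordance(X, lab, X, 3 - lab)
  expect_equal(neg$pearson_r, -1, tolerance = 1e-12)

  Y <- matrix(rnorm(100 * 20), 100, 20)
  fc <- fold_change_concordance(X, lab, Y, lab)
  expect_equal(fc$pearson_r, pearson_oracle(fc$predicted_diff,
                                            fc$observed_diff),
               tolerance = 1e-12)
  expect_error(fold_change_concordance(X, lab, Y[, 1:5], lab), "differ")
})

test_that("Welch, BH and Pearson agree with oracles over random draws", {
  set.seed(123)
  for (rep in 1:100) {
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    a <- rnorm(na, sd = runif(1, 0.5, 2))
    b <- rnorm(nb, mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    got <- welch_t(a, b); want <- welch_oracle(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)

    p <- runif(sample(2:20, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-10)

    x <- rnorm(10); y <- rnorm(10)
    expect_equal(stats::cor(x, y), pearson_oracle(x, y), tolerance = 1e-10)
  }
})
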