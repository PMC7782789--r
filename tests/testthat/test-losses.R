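test_that("reconstruction loss is the batch-mean Euclidean distance", {
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(c(0, 0), c(3, 4)), 5)

  set.seed(2)
  a <- matrix(rnorm(8 * 6), 8, 6)
  b <- matrix(rnorm(8 * 6), 8, 6)
  want <- mean(vapply(1:8, function(i) sqrt(sum((a[i, ] - b[i, ])^2)),
                      numeric(1)))
  expect_equal(reconstruction_loss(a, b), want, tolerance = 1e-12)
  want2 <- mean(vapply(1:8, function(i) sum((a[i, ] - b[i, ])^2), numeric(1)))
  expect_equal(reconstruction_loss(a, b, squared = TRUE), want2,
               tolerance = 1e-12)
  expect_error(reconstruction_loss(a, b[, 1:3]), "shapes differ")
})

test_that("discriminative loss matches its closed forms and JS bounds", {
  Zp <- matrix(rnorm(40), 20, 2)
  Zq <- matrix(rnorm(40), 20, 2)
  half <- function(X) rep(0.5, nrow(X))
  expect_equal(discriminative_loss(Zp, Zq, half), -2 * log(2),
               tolerance = 1e-12)

  # identical batches: the inner-maximized value stays at the JS floor
  Z <- with_seed(7, matrix(rnorm(256 * 4), 256, 4))
  est <- adversarial_divergence(Z, Z, seed = 1, epochs = 200)
  expect_lt(abs(est - (-2 * log(2))), 0.05)

  # two far-separated point masses: a trained discriminator saturates
  A <- matrix(0, 64, 2)
  B <- matrix(100, 64, 2)
  est2 <- adversarial_divergence(A, B, seed = 1, epochs = 400)
  expect_gt(est2, -0.05)
  expect_lte(est2, 0)
})

test_that("conditioning the discriminator sharpens swapped-label mixtures", {
  half <- function(X) rep(0.5, nrow(X))
  Zp <- matrix(rnorm(30), 15, 2)
  Zq <- matrix(rnorm(30), 15, 2)
  expect_equal(conditional_discriminative_loss(Zp, rep(1, 15), Zq, rep(1, 15),
                                               half),
               -2 * log(2), tolerance = 1e-12)

  # constant equal conditions reduce to the unconditional loss for any f
  f <- new_discriminator(3, c(8, 8), seed = 5)
  g <- new_discriminator(3, c(8, 8), seed = 5)
  v1 <- conditional_discriminative_loss(Zp, rep(2, 15), Zq, rep(2, 15), f)
  fx <- function(X) discriminator_predict(g, cbind(X, 2))
  expect_equal(v1, discriminative_loss(Zp, Zq, fx), tolerance = 1e-12)

  # equal z-marginals but swapped cluster labels: only the conditional
  # discriminator can see the difference
  n <- 200
  z <- with_seed(3, c(rnorm(n / 2, -3, 0.3), rnorm(n / 2, 3, 0.3)))
  y_p <- rep(c(0, 1), each = n / 2)
  y_q <- rep(c(1, 0), each = n / 2)
  train_est <- function(Zc_p, Zc_q) {
    adversarial_divergence(Zc_p, Zc_q, seed = 2, epochs = 300)
  }
  uncond <- train_est(matrix(z), matrix(z))
  cond <- train_est(cbind(z, y_p), cbind(z, y_q))
  expect_gt(cond - uncond, 0.2)
})

test_that("classifier alignment loss is the label cross-entropy", {
  Z <- matrix(rnorm(12), 6, 2)
  y <- c(1L, 2L, 1L, 3L, 2L, 1L)
  perfect <- function(latents) {
    p <- matrix(1e-12, nrow(latents), 3)
    p[cbind(seq_len(nrow(latents)), y)] <- 1
    p / rowSums(p)
  }
  expect_lt(classifier_alignment_loss(Z, y, perfect), 1e-9)

  uniform <- function(latents) matrix(1 / 3, nrow(latents), 3)
  expect_equal(classifier_alignment_loss(Z, y, uniform), log(3),
               tolerance = 1e-12)

  set.seed(8)
  raw <- matrix(runif(18), 6, 3)
  probs <- raw / rowSums(raw)
  clf_fn <- function(latents) probs
  want <- -mean(log(probs[cbind(1:6, y)]))
  expect_equal(classifier_alignment_loss(Z, y, clf_fn), want,
               tolerance = 1e-12)

  expect_error(classifier_alignment_loss(Z, c(1, 4, 1, 1, 1, 1), clf_fn),
               "out of range")

  # the trainable classifier emits normalized probabilities
  clf <- new_latent_classifier(2, 4, seed = 3)
  p <- classifier_probs(clf, Z)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("anchor loss sums distances over anchored pairs", {
  Zi <- matrix(rnorm(10), 5, 2)
  expect_equal(anchor_loss(Zi, Zi, cbind(1:5, 1:5)), 0)
  expect_equal(anchor_loss(matrix(c(0, 0), 1), matrix(c(3, 4), 1),
                           cbind(1, 1)), 5)
  set.seed(9)
  Za <- matrix(rnorm(12), 6, 2)
  Zb <- matrix(rnorm(12), 6, 2)
  an <- cbind(c(1, 3, 4, 6), c(2, 3, 5, 1))
  want <- sum(vapply(1:4, function(k) {
    sqrt(sum((Za[an[k, 1], ] - Zb[an[k, 2], ])^2))
  }, numeric(1)))
  expect_equal(anchor_loss(Za, Zb, an), want, tolerance = 1e-12)
  expect_message(v <- anchor_loss(Za, Zb, matrix(integer(0), 0, 2)), "empty")
  expect_equal(v, 0)
  expect_error(anchor_loss(Za, Zb, cbind(9, 1)), "out of range")
})
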