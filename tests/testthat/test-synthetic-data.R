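test_that("latent sampling handles empty and degenerate mixtures", {
  cfg1 <- latent_config(3, 1, matrix(0, 1, 3), 1, 0)
  empty <- sample_latent(cfg1, 0, 1)
  expect_equal(dim(empty$latent), c(0L, 3L))
  expect_length(empty$labels, 0)

  five <- sample_latent(cfg1, 5, 7)
  expect_equal(five$latent, matrix(0, 5, 3))
  expect_equal(five$labels, rep(1L, 5))

  expect_error(sample_latent(cfg1, -1, 1), "n must be")
  expect_error(latent_config(2, 2, matrix(0, 3, 2), c(0.5, 0.5), 1),
               "cluster_means")
  expect_error(latent_config(2, 2, matrix(0, 2, 2), c(0.6, 0.6), 1),
               "sum to 1")
})

test_that("mixture proportions match cluster weights at large n", {
  cfg <- latent_config(2, 2, rbind(c(-1, 0), c(1, 0)), c(0.5, 0.5), 0.3)
  draw <- sample_latent(cfg, 10000, 42)
  k <- sum(draw$labels == 1L)
  # central 99% binomial(10000, 0.5) interval
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.5)
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])

  # default (0.6, 0.4) weights
  draw2 <- sample_latent(default_latent_config(), 10000, 42)
  b2 <- qbinom(c(0.005, 0.995), 10000, 0.6)
  expect_gte(sum(draw2$labels == 1L), b2[1])
  expect_lte(sum(draw2$labels == 1L), b2[2])
})

test_that("vector modality applies the declared map plus noise", {
  # identity affine map, no noise: output equals selected latent columns
  d <- 4
  ident <- modality_spec("vector", d,
                         map = list(A = diag(d), b = rep(0, d),
                                    nonlinearity = "linear"),
                         noise_sd = 0, shared_dims = 1:d)
  Z <- matrix(rnorm(20), 5, d)
  expect_equal(generate_vector_modality(Z, ident, 1), Z)

  # explicit 2x3 affine map against a hand-computed product
  A <- matrix(c(1, -2, 0.5, 3, 2, -1), 2, 3)
  b <- c(0.1, -0.2, 0.3)
  spec <- modality_spec("vector", 3, map = list(A = A, b = b,
                                                nonlinearity = "linear"),
                        noise_sd = 0, shared_dims = 1:2)
  Z4 <- matrix(c(1, 0, -1, 2, 0.5, 1, -0.5, 0), 4, 2)
  want <- Z4 %*% A + matrix(b, 4, 3, byrow = TRUE)
  expect_equal(generate_vector_modality(Z4, spec, 1), want, tolerance = 1e-12)

  # Monte-Carlo: noise averages out to the noiseless map
  spec_noisy <- modality_spec("vector", 3, map = list(A = A, b = b,
                                                      nonlinearity = "linear"),
                              noise_sd = 1, shared_dims = 1:2)
  Zrow <- matrix(c(0.3, -0.7), 1, 2)
  acc <- matrix(0, 1, 3)
  for (s in 1:2000) acc <- acc + generate_vector_modality(Zrow, spec_noisy, s)
  expect_equal(as.numeric(acc / 2000),
               as.numeric(Zrow %*% A + b), tolerance = 0.1)

  expect_error(generate_vector_modality(matrix(0, 2, 1), spec, 1),
               "shared_dims")
})

test_that("volume modality renders monotone radial profiles inside the mask", {
  spec <- default_volume_spec()
  lc <- default_latent_config()
  # noise-free render at the two cluster means
  spec0 <- spec; spec0$noise_sd <- 0
  vols <- generate_volume_modality(lc$cluster_means, spec0, 1)
  for (v in vols) {
    expect_true(all(v$volume[v$mask == 0] == 0))
  }
  ring_means <- lapply(vols, function(v) {
    vv <- voxel_volume(v$volume, v$mask, v$spacing_um)
    shells <- erode_shells(vv$mask, vv$spacing_um)
    ring_mean_intensities(vv, shells)
  })
  # ring means are ordered outermost -> innermost: the central-enriched
  # cluster increases inward, the peripheral-enriched one decreases inward
  expect_true(all(diff(ring_means[[1]]) > 0))
  expect_true(all(diff(ring_means[[2]]) < 0))
  # cross-check against per-voxel averaging
  v1 <- voxel_volume(vols[[1]]$volume, vols[[1]]$mask, vols[[1]]$spacing_um)
  sh <- erode_shells(v1$mask, v1$spacing_um)
  expect_equal(ring_mean_intensities(v1, sh),
               ring_means_oracle(v1$intensities, sh), tolerance = 1e-10)

  bad <- spec; bad$map$radius_um <- -1
  expect_error(generate_volume_modality(lc$cluster_means, bad, 1), "radius")
})

test_that("benchmarks couple modalities through one latent draw", {
  bench <- default_bench(5, anchor_fraction = 0.25, n = 60)
  expect_equal(nrow(bench$anchors), 15)
  # anchors are a subset of the true pairing
  expect_true(all(bench$pairing[bench$anchors[, 1]] == bench$anchors[, 2]))
  # label consistency across modalities under the pairing
  expect_equal(bench$labels[[1]], bench$labels[[2]][bench$pairing])

  full <- make_benchmark(default_latent_config(), bench_specs(), 20, 1, 9)
  expect_equal(nrow(full$anchors), 20)
  none <- make_benchmark(default_latent_config(), bench_specs(), 20, 0, 9)
  expect_equal(nrow(none$anchors), 0)

  # determinism: identical seed gives identical benchmarks
  again <- make_benchmark(default_latent_config(), bench_specs(), 20, 1, 9)
  expect_identical(full, again)

  expect_error(make_benchmark(default_latent_config(), bench_specs(), 20, 1.2, 1),
               "anchor_fraction")
  expect_error(make_benchmark(default_latent_config(),
                              bench_specs()[1], 20, 0, 1),
               "at least 2")
})
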