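test_that("pretraining is deterministic and reduces reconstruction loss", {
  bench <- small_vector_bench(21)
  X <- bench$datasets[[1]]
  cfg <- training_config(seed = 21, epochs = 5, pretrain_epochs = 25,
                         batch_size = 16)
  ae0 <- modality_autoencoder("vector", ncol(X), 8, seed = 21)
  a1 <- pretrain_autoencoder(X, ae0, cfg)
  a2 <- pretrain_autoencoder(X, ae0, cfg)
  expect_identical(a1, a2)

  init_loss <- reconstruction_loss(X, ae_decode(ae0, ae_encode(ae0, X)))
  final_loss <- reconstruction_loss(X, ae_decode(a1, ae_encode(a1, X)))
  expect_lt(final_loss, init_loss)
  expect_equal(length(attr(a1, "loss_trace")), 25)

  # epochs = 0 is a no-op
  a0 <- pretrain_autoencoder(X, ae0, cfg, epochs = 0)
  expect_equal(a0$encoder, ae0$encoder)
  expect_equal(a0$decoder, ae0$decoder)
})

test_that("an identity-capable autoencoder drives the loss to ~0", {
  # rank-2 data, single linear layers: an exact reconstruction exists
  set.seed(5)
  basis <- matrix(rnorm(10), 5, 2)
  Z <- matrix(rnorm(80), 40, 2)
  X <- 0.5 * Z %*% t(basis)
  ae <- modality_autoencoder("vector", 5, 3, hidden = integer(0), seed = 2)
  cfg <- training_config(seed = 2, epochs = 5, pretrain_epochs = 5,
                         batch_size = 40, learning_rate = 5e-3,
                         recon_squared = TRUE)
  ae <- pretrain_autoencoder(X, ae, cfg, epochs = 2000)
  expect_lt(reconstruction_loss(X, ae_decode(ae, ae_encode(ae, X))), 1e-3)
})

test_that("the variational option with zero KL and no sampling is exactly deterministic", {
  bench <- small_vector_bench(22)
  X <- bench$datasets[[1]]
  cfg <- training_config(seed = 22, epochs = 5, pretrain_epochs = 15,
                         batch_size = 16, vae_sampling = FALSE)
  det <- modality_autoencoder("vector", ncol(X), 6, seed = 9)
  var0 <- modality_autoencoder("vector", ncol(X), 6, seed = 9,
                               variational = TRUE, kl_weight = 0)
  det_t <- pretrain_autoencoder(X, det, cfg)
  var_t <- pretrain_autoencoder(X, var0, cfg)
  expect_equal(attr(det_t, "loss_trace"), attr(var_t, "loss_trace"),
               tolerance = 1e-12)
  expect_equal(det_t$encoder, var_t$encoder, tolerance = 1e-12)

  # with sampling and a positive KL weight training still runs and the KL
  # head participates
  cfg2 <- training_config(seed = 22, epochs = 5, pretrain_epochs = 10,
                          batch_size = 16, vae_sampling = TRUE)
  vark <- modality_autoencoder("vector", ncol(X), 6, seed = 9,
                               variational = TRUE, kl_weight = 0.01)
  vt <- pretrain_autoencoder(X, vark, cfg2)
  expect_true(all(is.finite(attr(vt, "loss_trace"))))
})

test_that("fit produces a shared-latent model with a full training log", {
  bench <- small_vector_bench(23)
  cfg <- training_config(seed = 23, epochs = 10, pretrain_epochs = 10,
                         batch_size = 16, disc_warmup = 50)
  m <- fit_crossmodal(bench$datasets, cfg)
  expect_s3_class(m, "crossmodal_model")
  for (i in 1:2) {
    Z <- encode_modality(m, bench$datasets[[i]], i)
    expect_equal(ncol(Z), m$latent_dim)
    expect_equal(nrow(Z), bench$n)
  }
  expect_true(all(c("reference", "warmup", "pretrain", "full") %in%
                    m$log$phase))
  expect_true(all(is.finite(m$log$recon)))

  # determinism of the whole fit
  m2 <- fit_crossmodal(bench$datasets, cfg)
  expect_identical(m$log, m2$log)
  expect_equal(m$autoencoders, m2$autoencoders)
})

test_that("alternating mode trains both domains against each other", {
  bench <- small_vector_bench(24)
  cfg <- training_config(seed = 24, epochs = 8, pretrain_epochs = 10,
                         batch_size = 16, mode = "alternating",
                         disc_warmup = 50)
  m <- fit_crossmodal(bench$datasets, cfg)
  expect_true(all(m$log$domain[m$log$phase == "alternating"] %in% 1:2))
  recon_by_domain <- tapply(m$log$recon[m$log$phase == "alternating"],
                            m$log$domain[m$log$phase == "alternating"],
                            function(x) utils::tail(x, 1))
  expect_true(all(is.finite(recon_by_domain)))
})

test_that("a structureless single-cluster benchmark still trains", {
  lc1 <- latent_config(4, 1, matrix(0, 1, 4), 1, 0.5)
  specs <- list(default_vector_spec(latent_dim = 4, n_features = 15, seed = 3),
                default_vector_spec(latent_dim = 4, n_features = 12, seed = 4))
  bench <- make_benchmark(lc1, specs, 60, 0, 31)
  cfg <- training_config(seed = 31, epochs = 6, pretrain_epochs = 12,
                         batch_size = 16, disc_warmup = 50)
  m <- fit_crossmodal(bench$datasets, cfg)
  for (i in 1:2) {
    tr <- m$log$recon[m$log$phase %in% c("reference", "warmup") &
                        m$log$domain == i]
    expect_lt(utils::tail(tr, 1), tr[1])
  }
})

test_that("label and anchor priors are wired into the objective", {
  bench <- small_vector_bench(25)
  cfg <- training_config(seed = 25, epochs = 8, pretrain_epochs = 10,
                         batch_size = 16, disc_warmup = 50)
  m <- fit_crossmodal(bench$datasets, cfg,
                      priors = list(labels = bench$labels,
                                    anchors = bench$anchors))
  expect_false(is.null(m$classifier))
  full <- m$log[m$log$phase == "full", ]
  expect_true(all(is.finite(full$classifier)))
  # anchored-pair latent distance shrinks relative to the warmup-only state
  cfg0 <- training_config(seed = 25, epochs = 1, pretrain_epochs = 10,
                          batch_size = 16, disc_warmup = 10,
                          latent_init = "whiten")
  m0 <- fit_crossmodal(bench$datasets, cfg0)
  adist <- function(model) {
    Z1 <- encode_modality(model, bench$datasets[[1]], 1)
    Z2 <- encode_modality(model, bench$datasets[[2]], 2)
    anchor_loss(Z1, Z2, bench$anchors) / nrow(bench$anchors)
  }
  expect_lt(adist(m), adist(m0))
})

test_that("checkpoints round-trip to identical encodings", {
  bench <- small_vector_bench(26)
  cfg <- training_config(seed = 26, epochs = 4, pretrain_epochs = 8,
                         batch_size = 16, disc_warmup = 20)
  m <- fit_crossmodal(bench$datasets, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(encode_modality(m, bench$datasets[[1]], 1),
                   encode_modality(m2, bench$datasets[[1]], 1))
  expect_identical(m$log, m2$log)
  # corrupted checkpoints fail loudly, naming the file
  bad <- tempfile(fileext = ".rds")
  writeLines("not a checkpoint", bad)
  expect_error(load_checkpoint(bad), basename(bad), fixed = TRUE)
})
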