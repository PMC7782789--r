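# Shared fixtures: benchmarks and trained models are cached per R session so
# several test files can reuse the same (deterministic) training runs.

.xm_cache <- new.env(parent = emptyenv())

bench_specs <- function() {
  list(default_vector_spec(), default_volume_spec())
}

default_bench <- function(seed, anchor_fraction = 0, n = 400) {
  key <- sprintf("bench_%d_%d", seed, n)
  if (is.null(.xm_cache[[key]])) {
    .xm_cache[[key]] <- make_benchmark(default_latent_config(), bench_specs(),
                                       n = n, anchor_fraction = 0, seed = seed)
  }
  bench <- .xm_cache[[key]]
  if (anchor_fraction > 0) {
    # anchors are drawn from an anchor-fraction-independent random stream,
    # so they can be derived without regenerating the (large) datasets
    n_anchor <- round(anchor_fraction * n)
    rows1 <- with_seed(derive_seed(seed, "anchors"),
                       sort(sample.int(n, n_anchor)))
    bench$anchors <- cbind(i = rows1, j = bench$pairing[rows1])
    bench$anchor_fraction <- anchor_fraction
  }
  bench
}

bench_training_config <- function(seed, ...) {
  training_config(seed = seed, normalization = c("none", "scale01"), ...)
}

# fit the default benchmark (with optional anchors) once per (seed, fraction)
trained_model <- function(seed, anchor_fraction = 0) {
  key <- sprintf("model_%d_%g", seed, anchor_fraction)
  if (is.null(.xm_cache[[key]])) {
    bench <- default_bench(seed, anchor_fraction)
    priors <- if (anchor_fraction > 0) list(anchors = bench$anchors) else NULL
    model <- fit_crossmodal(list(bench$datasets[[1]], bench$datasets[[2]]),
                            bench_training_config(seed), priors)
    .xm_cache[[key]] <- list(bench = bench, model = model)
  }
  .xm_cache[[key]]
}

model_latents <- function(tm) {
  list(Z1 = encode_modality(tm$model, tm$bench$datasets[[1]], 1),
       Z2 = encode_modality(tm$model, tm$bench$datasets[[2]], 2))
}

# radial profiles of a benchmark's volumes, cached
bench_profiles <- function(seed, anchor_fraction = 0) {
  key <- sprintf("prof_%d_%g", seed, anchor_fraction)
  if (is.null(.xm_cache[[key]])) {
    bench <- default_bench(seed, anchor_fraction)
    .xm_cache[[key]] <- lapply(bench$datasets[[2]], function(v) {
      extract_profile(voxel_volume(v$volume, v$mask, v$spacing_um))
    })
  }
  .xm_cache[[key]]
}

# held-out divergence estimate: the discriminator is trained on half of
# each latent cloud and the objective evaluated on the other half, so
# memorizing the finite point sets cannot fake separation — the value
# reflects the true distributional mismatch
heldout_divergence <- function(Za, Zb, seed, epochs = 400) {
  n <- nrow(Za)
  tr <- with_seed(derive_seed(seed, "split"), sample.int(n, n %/% 2))
  f <- new_discriminator(ncol(Za), c(32, 32), derive_seed(seed, "hd"))
  st <- xmodal:::adam_new(f$layers)
  for (e in seq_len(epochs)) {
    r <- xmodal:::discriminator_step(f, st, Za[tr, , drop = FALSE],
                                     Zb[tr, , drop = FALSE], 2e-3, 1)
    f <- r$f; st <- r$state
  }
  discriminative_loss(Za[-tr, , drop = FALSE], Zb[-tr, , drop = FALSE], f)
}

# small two-vector-modality benchmark for fast training tests
small_vector_bench <- function(seed, n = 80) {
  key <- sprintf("smallb_%d_%d", seed, n)
  if (is.null(.xm_cache[[key]])) {
    specs <- list(default_vector_spec(n_features = 20, seed = 1),
                  default_vector_spec(n_features = 25, seed = 2))
    .xm_cache[[key]] <- make_benchmark(default_latent_config(), specs,
                                      n = n, anchor_fraction = 0.5, seed = seed)
  }
  .xm_cache[[key]]
}
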