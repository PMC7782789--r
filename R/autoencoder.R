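# Per-modality autoencoders mapping to/from the shared latent space.
#
# Vector data uses fully-connected encoder/decoder stacks. Volume data is
# handled with a fixed strided average-pooling front end (the linear part of
# a convolutional downsampling block), a dense core, and a mirrored
# nearest-neighbour upsampling tail; reconstruction is always scored in the
# full voxel space (computed exactly in pooled coordinates, see
# prepare_domain).

#' Construct a modality autoencoder
#'
#' @param kind `"vector"` or `"volume"`.
#' @param input_shape feature count (vector) or voxel grid shape (volume).
#' @param latent_dim shared latent dimensionality.
#' @param hidden hidden layer sizes of the dense core.
#' @param pool_factor per-axis pooling factor for volumes.
#' @param variational add a log-variance head (variational option); with
#'   `kl_weight = 0` and sampling disabled this reduces exactly to the
#'   deterministic autoencoder.
#' @param kl_weight weight of the KL regularizer when variational.
#' @param modality_id integer tag.
#' @param seed initialisation seed.
#' @return a `modality_autoencoder`.
#' @export
modality_autoencoder <- function(kind = c("vector", "volume"), input_shape,
                                 latent_dim, hidden = NULL, pool_factor = 4L,
                                 variational = FALSE, kl_weight = 0,
                                 modality_id = 1L, seed = 1L) {
  kind <- match.arg(kind)
  if (latent_dim < 1) abort("latent_dim must be >= 1")
  pre <- NULL
  post <- NULL
  if (kind == "vector") {
    if (length(input_shape) != 1) abort("vector input_shape must be scalar")
    if (is.null(hidden)) hidden <- c(64, 32)
    core_in <- input_shape
    out_act <- "linear"
  } else {
    if (length(input_shape) != 3) abort("volume input_shape must have 3 entries")
    if (is.null(hidden)) hidden <- 128
    P <- pooling_matrix(input_shape, pool_factor)
    pre <- fixed_layer(P)
    post <- fixed_layer(upsample_matrix(input_shape, pool_factor))
    core_in <- ncol(P)
    out_act <- "sigmoid"
  }
  encoder <- build_dense_stack(c(core_in, hidden, latent_dim),
                               "tanh", "linear", seed, "enc")
  decoder <- build_dense_stack(c(latent_dim, rev(hidden), core_in),
                               "tanh", out_act, seed, "dec")
  logvar <- if (variational) {
    last_hidden <- if (length(hidden)) hidden[length(hidden)] else core_in
    dense_layer(last_hidden, latent_dim, "linear", derive_seed(seed, "logvar"))
  } else NULL
  structure(
    list(kind = kind, input_shape = as.integer(input_shape),
         latent_dim = as.integer(latent_dim), hidden = hidden,
         pool_factor = as.integer(pool_factor),
         pre = pre, encoder = encoder, decoder = decoder, post = post,
         frame = NULL,
         variational = variational, kl_weight = kl_weight, logvar = logvar,
         modality_id = as.integer(modality_id), seed = as.integer(seed)),
    class = "modality_autoencoder"
  )
}

build_dense_stack <- function(sizes, hidden_act, out_act, seed, tag) {
  layers <- vector("list", length(sizes) - 1)
  for (i in seq_along(layers)) {
    act <- if (i < length(layers)) hidden_act else out_act
    layers[[i]] <- dense_layer(sizes[i], sizes[i + 1], act,
                               derive_seed(seed, paste0(tag, i)))
  }
  layers
}

#' Encode data into the shared latent space
#'
#' @param ae a `modality_autoencoder`.
#' @param X data matrix (volumes flattened to rows, see
#'   [volumes_to_matrix()]).
#' @return `n x latent_dim` matrix (the latent mean for variational models).
#' @export
ae_encode <- function(ae, X) {
  X <- as.matrix(X)
  if (!is.null(ae$pre)) X <- as.matrix(X %*% ae$pre$M)
  frame_apply(ae$frame, mlp_forward(ae$encoder, X))
}

#' Decode latent vectors back to data space
#'
#' @param ae a `modality_autoencoder`.
#' @param Z latent matrix.
#' @return reconstruction matrix with one row per latent row.
#' @export
ae_decode <- function(ae, Z) {
  Zc <- frame_invert(ae$frame, as.matrix(Z))
  out <- mlp_forward(ae$decoder, Zc)
  if (!is.null(ae$post)) out <- as.matrix(out %*% ae$post$M)
  out
}

#' Flatten a list of volumes into a samples-by-voxels matrix
#'
#' @param volumes list of `list(volume, mask, ...)` entries (as produced by
#'   [generate_volume_modality()]) or of plain 3D arrays.
#' @return matrix with one flattened volume per row and a `vol_shape`
#'   attribute.
#' @export
volumes_to_matrix <- function(volumes) {
  vols <- lapply(volumes, function(v) if (is.list(v)) v$volume else v)
  shape <- dim(vols[[1]])
  X <- do.call(rbind, lapply(vols, as.numeric))
  attr(X, "vol_shape") <- shape
  X
}

# Precompute everything the training loop needs for one domain.
#
# For volume autoencoders the decoder ends in block replication U, so the
# full-space squared distance decomposes exactly as
#   ||x - U s||^2 = sum_b w_b (xbar_b - s_b)^2 + (||x||^2 - sum_b w_b xbar_b^2)
# with xbar the block means and w_b the block voxel counts; training can
# therefore run entirely in pooled coordinates while scoring the loss in the
# full voxel space.
prepare_domain <- function(ae, X) {
  X <- as.matrix(X)
  if (is.null(ae$pre)) {
    list(enc_in = X, target = X, w = NULL, resid2 = NULL)
  } else {
    P <- ae$pre$M
    Xp <- as.matrix(X %*% P)
    w <- as.numeric(Matrix::colSums(P != 0))
    resid2 <- pmax(rowSums(X^2) - as.numeric((Xp^2) %*% w), 0)
    list(enc_in = Xp, target = Xp, w = w, resid2 = resid2)
  }
}

# forward + backward of the reconstruction objective on a batch of rows of a
# prepared domain (plus KL when variational); returns loss values, parameter
# grads for the dense cores, and the latent batch
recon_pass <- function(ae, dc, rows, squared = FALSE, sample_noise = FALSE,
                       noise_seed = NULL) {
  Xb <- dc$enc_in[rows, , drop = FALSE]
  enc_fw <- mlp_forward(ae$encoder, Xb, cache = TRUE)
  mu <- enc_fw$out
  nl <- length(ae$encoder)
  kl <- 0
  lv_fw <- NULL
  eps <- NULL
  sigma <- NULL
  if (!is.null(ae$logvar)) {
    pen <- enc_fw$caches[[nl]]$X  # input to the final latent layer
    lv_fw <- mlp_forward(list(ae$logvar), pen, cache = TRUE)
    lv <- lv_fw$out
    if (sample_noise) {
      sigma <- exp(lv / 2)
      eps <- with_seed(noise_seed %||% 1L,
                       matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
      Z <- mu + sigma * eps
    } else {
      Z <- mu
    }
    if (ae$kl_weight > 0) {
      kl <- -0.5 * mean(rowSums(1 + lv - mu^2 - exp(lv)))
    }
  } else {
    Z <- mu
  }
  dec_fw <- mlp_forward(ae$decoder, Z, cache = TRUE)
  S <- dec_fw$out
  Tb <- dc$target[rows, , drop = FALSE]
  n <- length(rows)
  diff <- S - Tb
  if (is.null(dc$w)) {
    q <- rowSums(diff^2)
  } else {
    q <- as.numeric((diff^2) %*% dc$w) + dc$resid2[rows]
  }
  if (squared) {
    loss <- mean(q)
    dS <- 2 * diff / n
    if (!is.null(dc$w)) dS <- sweep(dS, 2, dc$w, "*")
  } else {
    nrm <- sqrt(q)
    loss <- mean(nrm)
    nrm[nrm < 1e-12] <- 1
    dS <- diff / (n * nrm)
    if (!is.null(dc$w)) dS <- sweep(dS, 2, dc$w, "*")
  }
  dec_bk <- mlp_backward(ae$decoder, dec_fw$caches, dS)
  list(loss = loss, kl = kl,
       Z = frame_apply(ae$frame, Z),  # canonical coords, for loss heads
       mu = mu,
       enc_fw = enc_fw, lv_fw = lv_fw, eps = eps, sigma = sigma,
       dec_grads = dec_bk$grads, dZ_recon = dec_bk$dX)
}

# map a gradient w.r.t. canonical latent coordinates back to core
# (pre-frame) coordinates
grad_to_core <- function(ae, dZc) {
  if (is.null(ae$frame)) dZc else dZc %*% t(ae$frame$A)
}

# backpropagate a total latent gradient dZ through the encoder core (and the
# log-variance head when present), honouring KL and reparameterization paths
encoder_backward <- function(ae, pass, dZ) {
  nl <- length(ae$encoder)
  n <- nrow(pass$mu)
  dmu <- dZ
  lv_grads <- NULL
  dPen_lv <- NULL
  if (!is.null(ae$logvar)) {
    lv <- pass$lv_fw$out
    dlv <- matrix(0, n, ncol(lv))
    if (!is.null(pass$eps)) dlv <- dlv + dZ * 0.5 * pass$sigma * pass$eps
    if (ae$kl_weight > 0) {
      dmu <- dmu + ae$kl_weight * pass$mu / n
      dlv <- dlv + ae$kl_weight * 0.5 * (exp(lv) - 1) / n
    }
    if (any(dlv != 0)) {
      lv_bk <- mlp_backward(list(ae$logvar), pass$lv_fw$caches, dlv)
      lv_grads <- lv_bk$grads[[1]]
      dPen_lv <- lv_bk$dX
    }
  }
  last_bk <- mlp_backward(ae$encoder[nl], pass$enc_fw$caches[nl], dmu)
  dPen <- last_bk$dX
  if (!is.null(dPen_lv)) dPen <- dPen + dPen_lv
  if (nl > 1) {
    trunk_bk <- mlp_backward(ae$encoder[seq_len(nl - 1)],
                             pass$enc_fw$caches[seq_len(nl - 1)], dPen)
    enc_grads <- c(trunk_bk$grads, last_bk$grads)
  } else {
    enc_grads <- last_bk$grads
  }
  list(enc_grads = enc_grads, lv_grads = lv_grads)
}

# Attach a fixed affine latent reparameterization z' = (z - mid) %*% A as
# the encoder's (non-trainable) output stage, with its exact inverse
# prepended to the decoder: reconstructions are unchanged, only the shared
# latent coordinates move. Kept out of the trainable weights on purpose —
# per-parameter optimizers take fixed-size steps, and folding a
# high-gain frame into the weights would make those steps huge in the
# frame's sensitive directions.
set_latent_frame <- function(ae, mid, A) {
  ae$frame <- list(mid = mid, A = A, Ainv = solve(A))
  ae
}

frame_apply <- function(frame, Z) {
  if (is.null(frame)) return(Z)
  sweep(Z, 2, frame$mid) %*% frame$A
}

frame_invert <- function(frame, Z) {
  if (is.null(frame)) return(Z)
  sweep(Z %*% frame$Ainv, 2, frame$mid, "+")
}

# Per-dimension standardization of the empirical latents: the embedded
# distribution becomes zero-mean, unit-variance per coordinate, fixing the
# scale of the adversarial game.
whiten_latent <- function(ae, Z) {
  mu <- colMeans(Z)
  sd <- apply(Z, 2, stats::sd)
  sd[sd < 1e-8] <- 1
  set_latent_frame(ae, mu, diag(1 / sd, length(sd)))
}

# Canonical latent frame for bimodal data: split the embedded latents into
# two clusters (ordered by size), and take the frame that simultaneously
# whitens the larger cluster's covariance and diagonalizes the smaller
# one's (generalized eigenvectors), with axis signs pinned by the
# cluster-mean displacement. The frame is invariant to affine
# reparameterizations of the embedding, so two modalities observing the
# same underlying cell states land in approximately the same coordinates —
# the adversarial phase then only has to refine the residual (nonlinear)
# mismatch. Returns NULL when the split is degenerate.
canonical_transform <- function(Z, seed = 1L, shrink = 0.05,
                                min_axis_sd = 0.25) {
  d <- ncol(Z)
  km <- with_seed(derive_seed(seed, "canon_kmeans"),
                  stats::kmeans(Z, centers = 2, nstart = 10, iter.max = 100))
  big <- which.max(km$size)
  rows1 <- km$cluster == big
  if (sum(rows1) < d + 2 || sum(!rows1) < d + 2) return(NULL)
  m1 <- colMeans(Z[rows1, , drop = FALSE])
  m2 <- colMeans(Z[!rows1, , drop = FALSE])
  mid <- (m1 + m2) / 2
  delta <- m2 - m1
  # shrinkage keeps the whitening gain bounded when an embedding is
  # (near-)degenerate along noise axes
  reg <- function(S) S + shrink * mean(diag(S)) * diag(d)
  S1 <- reg(stats::cov(Z[rows1, , drop = FALSE]))
  S2 <- reg(stats::cov(Z[!rows1, , drop = FALSE]))
  E1 <- eigen(S1, symmetric = TRUE)
  vals <- pmax(E1$values, max(E1$values) * 1e-9)
  B <- E1$vectors %*% diag(1 / sqrt(vals), d) %*% t(E1$vectors)  # S1^{-1/2}
  C <- B %*% S2 %*% B
  E2 <- eigen((C + t(C)) / 2, symmetric = TRUE)
  A <- B %*% E2$vectors
  s <- sign(as.numeric(delta %*% A))
  s[s == 0] <- 1
  A <- sweep(A, 2, s, "*")
  # bring each canonical axis to (at most) unit total variance so frames
  # agree in scale across modalities; the floor keeps noise axes from being
  # amplified into instability
  tot_sd <- apply(sweep(Z, 2, mid) %*% A, 2, stats::sd)
  A <- sweep(A, 2, pmax(tot_sd, min_axis_sd), "/")
  list(mid = mid, A = A)
}

# initialize a domain's latent frame after reconstruction warmup
init_latent_frame <- function(ae, Z, method = "canonical", seed = 1L) {
  if (method == "none") return(ae)
  if (method == "canonical") {
    tr <- tryCatch(canonical_transform(Z, seed), error = function(e) NULL)
    if (!is.null(tr) && all(is.finite(tr$A))) {
      return(set_latent_frame(ae, tr$mid, tr$A))
    }
  }
  whiten_latent(ae, Z)
}

ae_opt_new <- function(ae) {
  list(enc = adam_new(ae$encoder), dec = adam_new(ae$decoder),
       lv = if (!is.null(ae$logvar)) adam_new(list(ae$logvar)) else NULL)
}

ae_opt_apply <- function(ae, opt, enc_grads, dec_grads, lv_grads, lr) {
  if (!is.null(enc_grads)) {
    u <- adam_step(ae$encoder, opt$enc, enc_grads, lr)
    ae$encoder <- u$layers; opt$enc <- u$state
  }
  if (!is.null(dec_grads)) {
    u <- adam_step(ae$decoder, opt$dec, dec_grads, lr)
    ae$decoder <- u$layers; opt$dec <- u$state
  }
  if (!is.null(lv_grads)) {
    u <- adam_step(list(ae$logvar), opt$lv, list(lv_grads), lr)
    ae$logvar <- u$layers[[1]]; opt$lv <- u$state
  }
  list(ae = ae, opt = opt)
}

#' Pretrain an autoencoder on reconstruction alone
#'
#' Minibatch Adam on the Euclidean reconstruction loss (plus the KL term for
#' variational models). With a fixed seed two runs are bit-identical;
#' `epochs = 0` returns the model unchanged.
#'
#' @param data data matrix (or list of volumes).
#' @param ae a `modality_autoencoder`.
#' @param cfg a [training_config()] supplying learning rate, batch size and
#'   seed.
#' @param epochs number of epochs (default `cfg$pretrain_epochs`).
#' @return the trained autoencoder, with a `loss_trace` attribute giving the
#'   per-epoch mean reconstruction loss.
#' @export
pretrain_autoencoder <- function(data, ae, cfg, epochs = NULL) {
  X <- if (is.list(data) && !is.data.frame(data)) volumes_to_matrix(data)
       else as.matrix(data)
  if (nrow(X) == 0) abort("data is empty")
  epochs <- epochs %||% cfg$pretrain_epochs
  dc <- prepare_domain(ae, X)
  opt <- ae_opt_new(ae)
  trace <- numeric(epochs)
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    idx <- with_seed(derive_seed(cfg$seed, paste0("pre", ae$modality_id, "_", e)),
                     sample.int(n))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    tot <- 0
    for (b in seq_along(batches)) {
      rows <- batches[[b]]
      pass <- recon_pass(ae, dc, rows, cfg$recon_squared,
                         sample_noise = ae$variational && cfg$vae_sampling,
                         noise_seed = derive_seed(cfg$seed,
                                                  paste0("eps", ae$modality_id,
                                                         "_", e, "_", b)))
      if (!is.finite(pass$loss)) {
        abort("non-finite reconstruction loss at epoch %d (divergence)", e)
      }
      bk <- encoder_backward(ae, pass, pass$dZ_recon)
      upd <- ae_opt_apply(ae, opt, bk$enc_grads, pass$dec_grads, bk$lv_grads,
                          cfg$learning_rate)
      ae <- upd$ae; opt <- upd$opt
      tot <- tot + pass$loss * length(rows)
    }
    trace[e] <- tot / n
  }
  attr(ae, "loss_trace") <- trace
  ae
}
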