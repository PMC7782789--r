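# Training of the full cross-modal model: per-modality autoencoders sharing
# one latent space, with adversarial alignment of the latent distributions
# and optional prior-knowledge losses (latent classifier, anchors,
# conditioned discriminator).

#' Training configuration
#'
#' @param lambda_adv adversarial weight in the full training phase
#'   (the published setting uses 1).
#' @param lambda_pretrain adversarial weight during per-modality pretraining
#'   epochs (the published setting uses 0.1).
#' @param learning_rate Adam learning rate for autoencoder (pre)training
#'   (default 1e-3).
#' @param adv_learning_rate Adam learning rate for autoencoder updates
#'   during adversarial phases. Much smaller than `learning_rate`: after the
#'   latent frame initialisation the encoders only need small refinements,
#'   and per-parameter optimizers otherwise take steps whose latent-space
#'   magnitude exceeds the (unit) scale of the matched distributions.
#' @param disc_learning_rate Adam learning rate for discriminators.
#' @param epochs adversarial training epochs per domain.
#' @param pretrain_epochs reconstruction-only (plus weakly adversarial)
#'   epochs per domain before full training.
#' @param batch_size minibatch size.
#' @param seed run seed; every random stream derives from it.
#' @param mode `"reference_domain"` (estimate the latent prior from one
#'   representative domain, then align the others to it) or `"alternating"`
#'   (alternate the domains' objectives until they agree on an invariant
#'   latent distribution).
#' @param reference_modality index of the reference domain (required for
#'   `mode = "reference_domain"`).
#' @param discriminator_steps_per_ae_step discriminator updates per
#'   autoencoder update.
#' @param latent_dim shared latent dimensionality.
#' @param disc_hidden,clf_hidden hidden sizes of discriminator / classifier.
#' @param anchor_weight,classifier_weight weights of the prior losses.
#' @param normalization per-domain normalization: `"none"`, `"log1p"`
#'   (expression counts) or `"scale01"` (images); recycled across domains.
#' @param recon_squared score reconstruction with squared Euclidean distance.
#' @param vae_sampling draw reparameterization noise for variational
#'   autoencoders (disable for exact deterministic equivalence).
#' @param alternating_per_batch in alternating mode, refresh the target
#'   latent distribution per batch instead of per epoch.
#' @param latent_init how each domain's latent frame is initialized after
#'   its reconstruction warmup, by exact reparameterization of the trained
#'   encoder/decoder: `"canonical"` (simultaneous diagonalization of the two
#'   cluster covariances — affine-invariant, so the domains start out
#'   approximately aligned; falls back to `"whiten"` on degenerate or
#'   unimodal data), `"whiten"` (per-dimension standardization) or
#'   `"none"`.
#' @param disc_input_noise sd of seeded Gaussian instance noise added to
#'   both latent batches seen by the discriminator. Deterministic encoders
#'   embed data on low-dimensional manifolds that a flexible discriminator
#'   can separate perfectly (saturating the divergence estimate); instance
#'   noise smooths both distributions to full support so the adversarial
#'   gradient stays informative. Set 0 to disable.
#' @param disc_warmup discriminator updates run on the initial latents
#'   before the first autoencoder update of each adversarial phase; an
#'   undertrained discriminator early on produces an arbitrary gradient
#'   field that can push the generator far from its (aligned)
#'   initialization.
#' @return a validated `training_config`.
#' @export
training_config <- function(lambda_adv = 1, lambda_pretrain = 0.1,
                            learning_rate = 1e-3, adv_learning_rate = 2e-5,
                            disc_learning_rate = 2e-3,
                            epochs = 150L, pretrain_epochs = 60L,
                            batch_size = 64L, seed = 1L,
                            mode = c("reference_domain", "alternating"),
                            reference_modality = 1L,
                            discriminator_steps_per_ae_step = 3L,
                            latent_dim = 8L, disc_hidden = c(32, 32),
                            clf_hidden = 16L, anchor_weight = 1,
                            classifier_weight = 1,
                            normalization = "none", recon_squared = FALSE,
                            vae_sampling = TRUE,
                            alternating_per_batch = FALSE,
                            latent_init = c("canonical", "whiten", "none"),
                            disc_input_noise = 0.2, disc_warmup = 300L) {
  latent_init <- match.arg(latent_init)
  mode <- match.arg(mode)
  if (lambda_adv <= 0) abort("lambda_adv must be positive")
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (epochs < 1) abort("epochs must be >= 1")
  if (pretrain_epochs < 0) abort("pretrain_epochs must be >= 0")
  if (batch_size < 1) abort("batch_size must be >= 1")
  if (discriminator_steps_per_ae_step < 1) {
    abort("discriminator_steps_per_ae_step must be >= 1")
  }
  if (mode == "reference_domain" && is.null(reference_modality)) {
    abort("reference_modality is required for mode = 'reference_domain'")
  }
  structure(
    list(lambda_adv = lambda_adv, lambda_pretrain = lambda_pretrain,
         learning_rate = learning_rate, adv_learning_rate = adv_learning_rate,
         disc_learning_rate = disc_learning_rate,
         epochs = as.integer(epochs), pretrain_epochs = as.integer(pretrain_epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed),
         mode = mode, reference_modality = reference_modality,
         discriminator_steps_per_ae_step = as.integer(discriminator_steps_per_ae_step),
         latent_dim = as.integer(latent_dim), disc_hidden = disc_hidden,
         clf_hidden = clf_hidden, anchor_weight = anchor_weight,
         classifier_weight = classifier_weight,
         normalization = normalization, recon_squared = recon_squared,
         vae_sampling = vae_sampling,
         alternating_per_batch = alternating_per_batch,
         latent_init = latent_init, disc_input_noise = disc_input_noise,
         disc_warmup = as.integer(disc_warmup)),
    class = "training_config"
  )
}

# ---- normalization -------------------------------------------------------

norm_fit <- function(X, method) {
  switch(method,
    none = list(method = "none"),
    log1p = list(method = "log1p"),
    scale01 = list(method = "scale01", max = max(X)),
    abort("unknown normalization '%s'", method))
}

norm_apply <- function(X, nf) {
  switch(nf$method,
    none = X,
    log1p = log1p(X),
    scale01 = if (nf$max > 0) X / nf$max else X)
}

norm_invert <- function(X, nf) {
  switch(nf$method,
    none = X,
    log1p = expm1(X),
    scale01 = X * nf$max)
}

# ---- fitting -------------------------------------------------------------

as_domain_matrix <- function(d) {
  if (is.list(d) && !is.data.frame(d)) volumes_to_matrix(d) else as.matrix(d)
}

#' Fit a cross-modal autoencoder model
#'
#' Trains one autoencoder per domain into a shared latent space. In
#' `reference_domain` mode the reference autoencoder is trained first on
#' reconstruction alone; its empirical latent distribution becomes the
#' target, and every other autoencoder is trained with reconstruction plus
#' an adversarial term against that fixed target. In `alternating` mode the
#' domains' objectives are optimized in turn, each targeting the other
#' domain's current empirical latent distribution. Prior knowledge, when
#' supplied, adds the corresponding loss to every autoencoder update.
#'
#' @param domains list of >= 2 datasets: matrices (samples in rows) or lists
#'   of volumes.
#' @param cfg a [training_config()].
#' @param priors optional list with any of `labels` (per-domain integer
#'   vectors: latent classifier loss), `conditions` (per-domain numeric
#'   vectors: conditioned discriminator), `anchors` (2-column matrix of
#'   corresponding rows between domains 1 and 2: anchor loss).
#' @param autoencoders optional list of pre-built [modality_autoencoder()]s;
#'   by default they are constructed from the data shapes.
#' @return a `crossmodal_model`: autoencoders, discriminators, per-epoch
#'   training log, normalization metadata, and the resolved config.
#' @export
fit_crossmodal <- function(domains, cfg, priors = NULL, autoencoders = NULL) {
  if (length(domains) < 2) abort("need at least 2 domains")
  K <- length(domains)
  kinds <- vapply(domains, function(d) {
    if (is.list(d) && !is.data.frame(d)) "volume" else "vector"
  }, character(1))
  X <- lapply(domains, as_domain_matrix)
  norm_methods <- rep_len(cfg$normalization, K)
  norms <- mapply(norm_fit, X, norm_methods, SIMPLIFY = FALSE)
  X <- mapply(norm_apply, X, norms, SIMPLIFY = FALSE)

  if (is.null(autoencoders)) {
    autoencoders <- lapply(seq_len(K), function(i) {
      shape <- if (kinds[i] == "volume") attr(X[[i]], "vol_shape") else ncol(X[[i]])
      modality_autoencoder(kinds[i], shape, cfg$latent_dim, modality_id = i,
                           seed = derive_seed(cfg$seed, paste0("ae", i)))
    })
  }
  ldims <- vapply(autoencoders, function(a) a$latent_dim, integer(1))
  if (length(unique(ldims)) != 1) abort("latent dimensions differ across domains")

  log_env <- new.env()
  log_env$rows <- list()
  log_row <- function(phase, domain, epoch, ...) {
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(phase = phase, domain = domain, epoch = epoch, ...,
                 stringsAsFactors = FALSE)
  }

  clf <- NULL
  clf_opt <- NULL
  m_classes <- NULL
  if (!is.null(priors$labels)) {
    m_classes <- max(unlist(priors$labels))
    clf <- new_latent_classifier(cfg$latent_dim, m_classes, cfg$clf_hidden,
                                 derive_seed(cfg$seed, "clf"))
    clf_opt <- adam_new(clf$layers)
  }
  cond_dim <- if (!is.null(priors$conditions)) 1L else 0L

  discs <- vector("list", K)
  disc_opts <- vector("list", K)
  for (i in seq_len(K)) {
    discs[[i]] <- new_discriminator(cfg$latent_dim + cond_dim, cfg$disc_hidden,
                                    derive_seed(cfg$seed, paste0("disc", i)))
    disc_opts[[i]] <- adam_new(discs[[i]]$layers)
  }

  dcs <- mapply(prepare_domain, autoencoders, X, SIMPLIFY = FALSE)
  state <- list(aes = autoencoders, opts = lapply(autoencoders, ae_opt_new),
                discs = discs, disc_opts = disc_opts,
                clf = clf, clf_opt = clf_opt)

  # one adversarial epoch of updates for domain i against target latents;
  # target_fn(rows) returns target latent rows (frozen snapshot or live)
  adversarial_epoch <- function(state, i, epoch, phase, lambda, target_fn,
                                n_target, anchor_map = NULL,
                                anchor_target_fn = NULL,
                                lr = cfg$adv_learning_rate,
                                use_disc = TRUE) {
    ae <- state$aes[[i]]
    opt <- state$opts[[i]]
    f <- state$discs[[i]]
    fst <- state$disc_opts[[i]]
    dc <- dcs[[i]]
    n <- nrow(dc$enc_in)
    idx <- with_seed(derive_seed(cfg$seed, paste0(phase, "_", i, "_", epoch)),
                     sample.int(n))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    acc <- c(recon = 0, kl = 0, adv = 0, disc = 0, clf_loss = 0, anchor = 0)
    nb <- length(batches)
    for (b in seq_len(nb)) {
      rows <- batches[[b]]
      pass <- recon_pass(ae, dc, rows, cfg$recon_squared,
                         sample_noise = ae$variational && cfg$vae_sampling,
                         noise_seed = derive_seed(cfg$seed,
                                                  paste0("eps_", phase, "_", i,
                                                         "_", epoch, "_", b)))
      if (!is.finite(pass$loss)) {
        abort("non-finite loss in domain %d, %s epoch %d (divergence)",
              i, phase, epoch)
      }
      trows <- with_seed(
        derive_seed(cfg$seed, paste0("t_", phase, "_", i, "_", epoch, "_", b)),
        sample.int(n_target, min(length(rows), n_target)))
      ZT <- target_fn(trows)
      Zg <- pass$Z
      if (cfg$disc_input_noise > 0) {
        # instance noise: additive and identity-Jacobian, so generator
        # gradients pass through unchanged
        noise <- with_seed(
          derive_seed(cfg$seed, paste0("in_", phase, "_", i, "_", epoch, "_", b)),
          list(t = matrix(stats::rnorm(length(ZT), sd = cfg$disc_input_noise),
                          nrow(ZT), ncol(ZT)),
               g = matrix(stats::rnorm(length(Zg), sd = cfg$disc_input_noise),
                          nrow(Zg), ncol(Zg))))
        ZT <- ZT + noise$t
        Zg_n <- Zg + noise$g
      } else {
        Zg_n <- Zg
      }
      cond_g <- NULL
      if (cond_dim > 0) {
        cond_g <- priors$conditions[[i]][rows]
        ZT <- cbind(ZT, attr(target_fn, "cond")(trows))
        Zg_d <- cbind(Zg_n, cond_g)
      } else {
        Zg_d <- Zg_n
      }
      if (use_disc) {
        dres <- discriminator_step(f, fst, ZT, Zg_d, cfg$disc_learning_rate,
                                   cfg$discriminator_steps_per_ae_step)
        f <- dres$f; fst <- dres$state
        gg <- generator_grad(f, Zg_d)
        dZ_adv <- gg$dZ[, seq_len(ae$latent_dim), drop = FALSE]
        dZ_heads <- lambda * dZ_adv  # gradients w.r.t. canonical latents
      } else {
        dres <- list(loss = NA_real_)
        gg <- list(loss = NA_real_)
        dZ_heads <- matrix(0, nrow(Zg), ncol(Zg))
      }
      clf_loss <- NA_real_
      if (!is.null(state$clf)) {
        cg <- classifier_grads(state$clf, Zg, priors$labels[[i]][rows])
        dZ_heads <- dZ_heads + cfg$classifier_weight * cg$dZ
        cu <- adam_step(state$clf$layers, state$clf_opt, cg$grads,
                        cfg$learning_rate)
        state$clf$layers <- cu$layers
        state$clf_opt <- cu$state
        clf_loss <- cg$loss
      }
      anchor_val <- NA_real_
      if (!is.null(anchor_map)) {
        hit <- which(!is.na(anchor_map[rows]))
        if (length(hit)) {
          zt <- anchor_target_fn(anchor_map[rows[hit]])
          dvec <- Zg[hit, , drop = FALSE] - zt
          nrm <- sqrt(rowSums(dvec^2))
          anchor_val <- sum(nrm)
          nrm[nrm < 1e-12] <- 1
          dZ_anchor <- matrix(0, nrow(Zg), ncol(Zg))
          dZ_anchor[hit, ] <- dvec / nrm / length(hit)
          dZ_heads <- dZ_heads + cfg$anchor_weight * dZ_anchor
        } else anchor_val <- 0
      }
      dZ <- pass$dZ_recon + grad_to_core(ae, dZ_heads)
      bk <- encoder_backward(ae, pass, dZ)
      upd <- ae_opt_apply(ae, opt, bk$enc_grads, pass$dec_grads, bk$lv_grads,
                          lr)
      ae <- upd$ae; opt <- upd$opt
      acc <- acc + c(pass$loss, pass$kl,
                     ifelse(is.na(gg$loss), 0, gg$loss),
                     ifelse(is.na(dres$loss), 0, dres$loss),
                     ifelse(is.na(clf_loss), 0, clf_loss),
                     ifelse(is.na(anchor_val), 0, anchor_val))
    }
    state$aes[[i]] <- ae
    state$opts[[i]] <- opt
    state$discs[[i]] <- f
    state$disc_opts[[i]] <- fst
    acc <- acc / nb
    log_row(phase, i, epoch, recon = acc[["recon"]], kl = acc[["kl"]],
            adv_gen = acc[["adv"]], disc = acc[["disc"]],
            classifier = acc[["clf_loss"]], anchor = acc[["anchor"]])
    state
  }

  # bring a discriminator close to its optimum on the initial latent clouds
  # before the generator sees its gradients
  warmup_disc <- function(i, ZT_all, Zg_all, tag) {
    f <- state$discs[[i]]
    fst <- state$disc_opts[[i]]
    for (w in seq_len(cfg$disc_warmup)) {
      sel <- with_seed(derive_seed(cfg$seed, paste0("dw_", tag, "_", w)), {
        list(t = sample.int(nrow(ZT_all), min(128, nrow(ZT_all))),
             g = sample.int(nrow(Zg_all), min(128, nrow(Zg_all))),
             nt = matrix(stats::rnorm(min(128, nrow(ZT_all)) * ncol(ZT_all),
                                      sd = cfg$disc_input_noise),
                         ncol = ncol(ZT_all)),
             ng = matrix(stats::rnorm(min(128, nrow(Zg_all)) * ncol(Zg_all),
                                      sd = cfg$disc_input_noise),
                         ncol = ncol(Zg_all)))
      })
      res <- discriminator_step(f, fst, ZT_all[sel$t, , drop = FALSE] + sel$nt,
                                Zg_all[sel$g, , drop = FALSE] + sel$ng,
                                cfg$disc_learning_rate)
      f <- res$f; fst <- res$state
    }
    state$discs[[i]] <- f
    state$disc_opts[[i]] <- fst
    state
  }

  anchor_maps <- function(i, ref) {
    # anchors are (row in domain 1, row in domain 2); build map from rows of
    # domain i to rows of the target domain `ref`
    if (is.null(priors$anchors) || nrow(priors$anchors) == 0) return(NULL)
    if (!all(c(i, ref) %in% c(1L, 2L))) return(NULL)
    A <- priors$anchors
    n <- nrow(X[[i]])
    map <- rep(NA_integer_, n)
    map[A[, ifelse(i == 1L, 1L, 2L)]] <- A[, ifelse(ref == 1L, 1L, 2L)]
    map
  }

  if (cfg$mode == "reference_domain") {
    r <- cfg$reference_modality
    if (r < 1 || r > K) abort("reference_modality out of range")
    ref_ae <- pretrain_autoencoder(X[[r]], state$aes[[r]], cfg,
                                   epochs = cfg$pretrain_epochs + cfg$epochs)
    tr <- attr(ref_ae, "loss_trace")
    for (e in seq_along(tr)) log_row("reference", r, e, recon = tr[e], kl = 0,
                                     adv_gen = NA, disc = NA, classifier = NA,
                                     anchor = NA)
    ref_ae <- init_latent_frame(ref_ae, ae_encode(ref_ae, X[[r]]),
                                cfg$latent_init, cfg$seed)
    state$aes[[r]] <- ref_ae
    ZR <- ae_encode(ref_ae, X[[r]])
    if (!is.null(state$clf)) {
      # seed the classifier on the (frozen) reference latents
      for (e in seq_len(50)) {
        cg <- classifier_grads(state$clf, ZR, priors$labels[[r]])
        cu <- adam_step(state$clf$layers, state$clf_opt, cg$grads, 5e-3)
        state$clf$layers <- cu$layers
        state$clf_opt <- cu$state
      }
    }
    target_fn <- function(rows) ZR[rows, , drop = FALSE]
    if (cond_dim > 0) {
      attr(target_fn, "cond") <- function(rows) priors$conditions[[r]][rows]
    }
    for (i in setdiff(seq_len(K), r)) {
      # reconstruction warmup, then whiten this domain's latent scale before
      # the adversarial phases (a fresh optimizer follows the
      # reparameterization)
      warm <- pretrain_autoencoder(X[[i]], state$aes[[i]], cfg)
      tr <- attr(warm, "loss_trace")
      for (e in seq_along(tr)) log_row("warmup", i, e, recon = tr[e], kl = 0,
                                       adv_gen = NA, disc = NA, classifier = NA,
                                       anchor = NA)
      state$aes[[i]] <- init_latent_frame(warm, ae_encode(warm, X[[i]]),
                                          cfg$latent_init, cfg$seed)
      state$opts[[i]] <- ae_opt_new(state$aes[[i]])
      amap <- anchor_maps(i, r)
      atf <- function(rows) ZR[rows, , drop = FALSE]
      if (!is.null(amap)) {
        # supervised anchored refinement at full learning rate (no
        # adversarial term, hence stable) before the adversarial phases
        for (e in seq_len(cfg$pretrain_epochs)) {
          state <- adversarial_epoch(state, i, e, "anchored", 0,
                                     target_fn, nrow(ZR), amap, atf,
                                     lr = cfg$learning_rate, use_disc = FALSE)
        }
      }
      if (cond_dim == 0) {
        state <- warmup_disc(i, ZR, ae_encode(state$aes[[i]], X[[i]]),
                             paste0("ref", i))
      }
      for (e in seq_len(cfg$pretrain_epochs)) {
        state <- adversarial_epoch(state, i, e, "pretrain", cfg$lambda_pretrain,
                                   target_fn, nrow(ZR), amap, atf)
      }
      for (e in seq_len(cfg$epochs)) {
        state <- adversarial_epoch(state, i, e, "full", cfg$lambda_adv,
                                   target_fn, nrow(ZR), amap, atf)
      }
    }
  } else {
    if (K != 2) abort("alternating mode supports exactly 2 domains")
    for (i in 1:2) {
      warm <- pretrain_autoencoder(X[[i]], state$aes[[i]], cfg,
                                   epochs = cfg$pretrain_epochs)
      tr <- attr(warm, "loss_trace")
      for (e in seq_along(tr)) log_row("pretrain", i, e, recon = tr[e], kl = 0,
                                       adv_gen = NA, disc = NA, classifier = NA,
                                       anchor = NA)
      state$aes[[i]] <- init_latent_frame(warm, ae_encode(warm, X[[i]]),
                                          cfg$latent_init, cfg$seed)
      state$opts[[i]] <- ae_opt_new(state$aes[[i]])
    }
    if (!is.null(priors$anchors) && nrow(priors$anchors) > 0) {
      for (i in 1:2) {
        j <- 3L - i
        amap <- anchor_maps(i, j)
        atf <- local({
          jj <- j
          function(rows) ae_encode(state$aes[[jj]], X[[jj]][rows, , drop = FALSE])
        })
        ZJ <- ae_encode(state$aes[[j]], X[[j]])
        tfn <- local({Zs <- ZJ; function(rows) Zs[rows, , drop = FALSE]})
        for (e in seq_len(cfg$pretrain_epochs)) {
          state <- adversarial_epoch(state, i, e, "anchored", 0, tfn,
                                     nrow(ZJ), amap, atf,
                                     lr = cfg$learning_rate, use_disc = FALSE)
        }
      }
    }
    if (cond_dim == 0) {
      for (i in 1:2) {
        state <- warmup_disc(i, ae_encode(state$aes[[3L - i]], X[[3L - i]]),
                             ae_encode(state$aes[[i]], X[[i]]),
                             paste0("alt", i))
      }
    }
    for (e in seq_len(cfg$epochs)) {
      for (i in 1:2) {
        j <- 3L - i
        if (cfg$alternating_per_batch) {
          target_fn <- local({
            jj <- j
            function(rows) ae_encode(state$aes[[jj]], X[[jj]][rows, , drop = FALSE])
          })
        } else {
          ZJ <- ae_encode(state$aes[[j]], X[[j]])
          target_fn <- local({
            Zs <- ZJ
            function(rows) Zs[rows, , drop = FALSE]
          })
        }
        if (cond_dim > 0) {
          attr(target_fn, "cond") <- local({
            jj <- j
            function(rows) priors$conditions[[jj]][rows]
          })
        }
        amap <- anchor_maps(i, j)
        atf <- local({
          jj <- j
          function(rows) ae_encode(state$aes[[jj]], X[[jj]][rows, , drop = FALSE])
        })
        state <- adversarial_epoch(state, i, e, "alternating", cfg$lambda_adv,
                                   target_fn, nrow(X[[j]]), amap, atf)
      }
    }
  }

  structure(
    list(latent_dim = cfg$latent_dim, autoencoders = state$aes,
         discriminators = state$discs, classifier = state$clf,
         norms = norms, kinds = kinds, cfg = cfg,
         log = do.call(rbind, log_env$rows), seed = cfg$seed),
    class = "crossmodal_model"
  )
}

#' Encode data from one modality into the shared latent space
#'
#' @param model a fitted `crossmodal_model`.
#' @param data data matrix or volume list in the modality's original space.
#' @param i modality index.
#' @return latent matrix.
#' @export
encode_modality <- function(model, data, i) {
  if (i < 1 || i > length(model$autoencoders)) abort("modality id out of range")
  Xn <- norm_apply(as_domain_matrix(data), model$norms[[i]])
  ae_encode(model$autoencoders[[i]], Xn)
}

#' Decode latent vectors into one modality's data space
#'
#' @param model a fitted `crossmodal_model`.
#' @param Z latent matrix.
#' @param j modality index.
#' @return data matrix in modality `j`'s original (de-normalized) space.
#' @export
decode_modality <- function(model, Z, j) {
  if (j < 1 || j > length(model$autoencoders)) abort("modality id out of range")
  norm_invert(ae_decode(model$autoencoders[[j]], Z), model$norms[[j]])
}

#' Translate samples from modality i to modality j
#'
#' Composes the source encoder with the target decoder:
#' `x -> D_j(E_i(x))`. With `i == j` this is the autoencoder
#' reconstruction.
#'
#' @param x batch from modality `i` (matrix or volume list).
#' @param model a fitted `crossmodal_model`.
#' @param i source modality index.
#' @param j target modality index.
#' @return a `translation_result`: `source`, `target`, `translated` (matrix
#'   in modality j's space; `vol_shape` attribute for volume targets) and
#'   `provenance`.
#' @export
translate <- function(x, model, i, j) {
  Z <- encode_modality(model, x, i)
  out <- decode_modality(model, Z, j)
  if (model$kinds[j] == "volume") {
    attr(out, "vol_shape") <- model$autoencoders[[j]]$input_shape
  }
  structure(
    list(source = i, target = j, translated = out, latent = Z,
         provenance = list(seed = model$seed,
                           checkpoint_id = attr(model, "checkpoint_id"))),
    class = "translation_result"
  )
}

#' Save a fitted model checkpoint
#'
#' The checkpoint is a self-contained container with the architecture
#' descriptors, all parameters, normalization metadata and the training log;
#' loading it reproduces identical encodings.
#'
#' @param model a `crossmodal_model`.
#' @param path file path.
#' @return the path, invisibly (with the checkpoint id as an attribute).
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "xmodal_checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(structure(path, checkpoint_id = unname(tools::md5sum(path))))
}

#' Load a model checkpoint
#'
#' @param path file path written by [save_checkpoint()].
#' @return the `crossmodal_model`, with a `checkpoint_id` attribute.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) abort("cannot read checkpoint '%s': %s",
                                            path, conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "xmodal_checkpoint")) {
    abort("'%s' is not an xmodal checkpoint", path)
  }
  model <- obj$model
  attr(model, "checkpoint_id") <- unname(tools::md5sum(path))
  model
}
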