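# Latent-space discriminator. Trained to tell apart latent samples from two
# sources, its optimized objective
#   E_P log f + E_Q log(1 - f)
# estimates the Jensen-Shannon divergence between the two latent
# distributions up to the constant -2 log 2; driving it toward that constant
# is what aligns the modalities in the shared latent space.

DISC_EPS <- 1e-7  # outputs clamped to [eps, 1 - eps] to keep logs finite

#' Create a latent-space discriminator
#'
#' @param input_dim dimensionality of the scored vectors (latent dim, plus
#'   condition columns for the conditional variant).
#' @param hidden hidden layer sizes.
#' @param seed initialisation seed.
#' @return a `discriminator` object scoring vectors in (0, 1).
#' @export
new_discriminator <- function(input_dim, hidden = c(32, 32), seed = 1L) {
  sizes <- c(input_dim, hidden, 1)
  layers <- vector("list", length(sizes) - 1)
  for (i in seq_along(layers)) {
    act <- if (i < length(layers)) "tanh" else "sigmoid"
    layers[[i]] <- dense_layer(sizes[i], sizes[i + 1], act,
                               derive_seed(seed, paste0("disc", i)))
  }
  structure(list(layers = layers, input_dim = as.integer(input_dim)),
            class = "discriminator")
}

#' Discriminator scores
#'
#' @param f a `discriminator`.
#' @param X matrix of vectors to score.
#' @return numeric vector of scores strictly inside (0, 1).
#' @export
discriminator_predict <- function(f, X) {
  s <- as.numeric(mlp_forward(f$layers, as.matrix(X)))
  pmin(pmax(s, DISC_EPS), 1 - DISC_EPS)
}

#' Discriminative loss for a given discriminator
#'
#' Returns `mean log f(z_p) + mean log(1 - f(z_q))`. The adversarial
#' divergence estimate is this quantity after maximization over `f`
#' (see [adversarial_divergence()]); at equal distributions the maximized
#' value is `-2 log 2`, and it approaches 0 for well-separated distributions.
#'
#' @param latents_p,latents_q nonempty latent batches.
#' @param f a `discriminator` (or any function returning scores in (0, 1)).
#' @return scalar in `(-Inf, 0)`.
#' @export
discriminative_loss <- function(latents_p, latents_q, f) {
  latents_p <- as.matrix(latents_p)
  latents_q <- as.matrix(latents_q)
  if (nrow(latents_p) == 0 || nrow(latents_q) == 0) abort("empty batch")
  sp <- if (is.function(f)) f(latents_p) else discriminator_predict(f, latents_p)
  sq <- if (is.function(f)) f(latents_q) else discriminator_predict(f, latents_q)
  sp <- pmin(pmax(sp, DISC_EPS), 1 - DISC_EPS)
  sq <- pmin(pmax(sq, DISC_EPS), 1 - DISC_EPS)
  mean(log(sp)) + mean(log(1 - sq))
}

#' Conditional discriminative loss
#'
#' As [discriminative_loss()] but the discriminator scores the joint of the
#' latent vector and a condition value (a shared marker or cluster), so that
#' the joint distributions over (latent, condition) are matched rather than
#' the latent marginals alone. Conditions may be discrete or continuous.
#'
#' @param latents_p,latents_q latent batches.
#' @param cond_p,cond_q condition values (vector, or matrix of columns).
#' @param f a `discriminator` over `latent_dim + ncol(cond)` inputs.
#' @return scalar.
#' @export
conditional_discriminative_loss <- function(latents_p, cond_p,
                                            latents_q, cond_q, f) {
  discriminative_loss(cbind(as.matrix(latents_p), cond_p),
                      cbind(as.matrix(latents_q), cond_q), f)
}

# One or more full-batch Adam updates of the discriminator on fixed batches.
# Zp are "real" (target) latents, Zq "generated". Returns list(f, state, loss).
discriminator_step <- function(f, state, Zp, Zq, lr, steps = 1L) {
  np <- nrow(Zp); nq <- nrow(Zq)
  X <- rbind(Zp, Zq)
  for (s in seq_len(steps)) {
    fw <- mlp_forward(f$layers, X, cache = TRUE)
    sc <- pmin(pmax(as.numeric(fw$out), DISC_EPS), 1 - DISC_EPS)
    # minimize negative of Eq. 7 objective
    dout <- numeric(np + nq)
    dout[seq_len(np)] <- -1 / (np * sc[seq_len(np)])
    dout[np + seq_len(nq)] <- 1 / (nq * (1 - sc[np + seq_len(nq)]))
    bk <- mlp_backward(f$layers, fw$caches, matrix(dout, ncol = 1))
    upd <- adam_step(f$layers, state, bk$grads, lr)
    f$layers <- upd$layers
    state <- upd$state
  }
  loss <- mean(log(pmin(pmax(discriminator_predict(f, Zp), DISC_EPS), 1))) +
    mean(log(1 - discriminator_predict(f, Zq)))
  list(f = f, state = state, loss = loss)
}

# gradient of the non-saturating generator loss  -mean log f(Z)  w.r.t. Z
generator_grad <- function(f, Z) {
  fw <- mlp_forward(f$layers, Z, cache = TRUE)
  sc <- pmin(pmax(as.numeric(fw$out), DISC_EPS), 1 - DISC_EPS)
  dout <- matrix(-1 / (nrow(Z) * sc), ncol = 1)
  list(dZ = mlp_backward(f$layers, fw$caches, dout)$dX,
       loss = -mean(log(sc)))
}

#' Inner-maximized adversarial divergence estimate
#'
#' Trains a fresh flexible discriminator to maximize the discriminative
#' objective on the two fixed batches and returns the achieved value: close
#' to `-2 log 2` when the batches come from the same distribution, and
#' approaching 0 for well-separated ones.
#'
#' @param latents_p,latents_q latent batches.
#' @param seed initialisation seed.
#' @param epochs number of full-batch ascent steps.
#' @param hidden discriminator hidden sizes.
#' @param lr Adam learning rate.
#' @return scalar estimate of the (shifted) Jensen-Shannon divergence.
#' @export
adversarial_divergence <- function(latents_p, latents_q, seed = 1L,
                                   epochs = 400L, hidden = c(32, 32),
                                   lr = 5e-3) {
  latents_p <- as.matrix(latents_p)
  latents_q <- as.matrix(latents_q)
  f <- new_discriminator(ncol(latents_p), hidden, seed)
  st <- adam_new(f$layers)
  best <- -Inf
  for (e in seq_len(epochs)) {
    res <- discriminator_step(f, st, latents_p, latents_q, lr)
    f <- res$f; st <- res$state
    val <- discriminative_loss(latents_p, latents_q, f)
    if (val > best) best <- val
  }
  best
}
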