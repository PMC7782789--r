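# Loss functions of the cross-modal objective: Euclidean reconstruction,
# adversarial (Jensen-Shannon-type) latent alignment, and the optional
# prior-knowledge terms (latent classifier cross-entropy, anchor distance).

#' Reconstruction loss (batch-mean Euclidean distance)
#'
#' @param x,x_hat matrices (samples in rows) or vectors of equal shape.
#' @param squared use squared Euclidean distance instead (off by default;
#'   the objective is stated with the plain Euclidean metric).
#' @return nonnegative scalar: mean over samples of the (squared) Euclidean
#'   distance between flattened sample and reconstruction.
#' @export
reconstruction_loss <- function(x, x_hat, squared = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(x_hat))) x_hat <- matrix(x_hat, nrow = 1)
  if (!all(dim(x) == dim(x_hat))) abort("x and x_hat shapes differ")
  d2 <- rowSums((x - x_hat)^2)
  if (squared) mean(d2) else mean(sqrt(d2))
}

# gradient of reconstruction_loss w.r.t. x_hat
reconstruction_grad <- function(x, x_hat, squared = FALSE) {
  n <- nrow(x)
  r <- x_hat - x
  if (squared) return(2 * r / n)
  nrm <- sqrt(rowSums(r^2))
  nrm[nrm < 1e-12] <- 1  # zero residual rows contribute zero gradient anyway
  r / (n * nrm)
}

#' Latent classifier for label-guided alignment
#'
#' A small softmax network `p(Y | Z)` trained jointly with the encoders so
#' that cells with the same class label cluster together in the latent space
#' regardless of modality.
#'
#' @param latent_dim latent dimensionality.
#' @param m number of classes.
#' @param hidden hidden layer sizes.
#' @param seed initialisation seed.
#' @return a `latent_classifier` object.
#' @export
new_latent_classifier <- function(latent_dim, m, hidden = 16, seed = 1L) {
  sizes <- c(latent_dim, hidden, m)
  layers <- vector("list", length(sizes) - 1)
  for (i in seq_along(layers)) {
    act <- if (i < length(layers)) "tanh" else "linear"
    layers[[i]] <- dense_layer(sizes[i], sizes[i + 1], act,
                               derive_seed(seed, paste0("clf", i)))
  }
  structure(list(layers = layers, m = as.integer(m)),
            class = "latent_classifier")
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

#' Class probabilities of a latent classifier
#'
#' @param clf a `latent_classifier`, or a function mapping a latent matrix to
#'   a probability matrix.
#' @param latents latent matrix.
#' @return `n x m` probability matrix (rows sum to 1).
#' @export
classifier_probs <- function(clf, latents) {
  if (is.function(clf)) return(clf(latents))
  softmax_rows(mlp_forward(clf$layers, latents))
}

#' Classifier alignment loss (cross-entropy realization)
#'
#' Mean negative log-probability of the true label under `p(Y | Z)`. The
#' printed form of this objective (a minimized sum of indicator-weighted
#' class probabilities) is degenerate if taken literally; the standard
#' negative log-likelihood realization is used.
#'
#' @param latents latent matrix.
#' @param labels integer labels in `1..m`.
#' @param clf see [classifier_probs()].
#' @return nonnegative scalar.
#' @export
classifier_alignment_loss <- function(latents, labels, clf) {
  p <- classifier_probs(clf, latents)
  m <- ncol(p)
  if (any(labels < 1 | labels > m)) abort("labels out of range 1..%d", m)
  picked <- p[cbind(seq_len(nrow(p)), labels)]
  -mean(log(pmax(picked, 1e-12)))
}

# CE gradients: updates for clf parameters and gradient w.r.t. latents
classifier_grads <- function(clf, latents, labels) {
  fw <- mlp_forward(clf$layers, latents, cache = TRUE)
  p <- softmax_rows(fw$out)
  n <- nrow(p)
  onehot <- matrix(0, n, ncol(p))
  onehot[cbind(seq_len(n), labels)] <- 1
  dlogits <- (p - onehot) / n
  bk <- mlp_backward(clf$layers, fw$caches, dlogits)
  picked <- p[cbind(seq_len(n), labels)]
  list(loss = -mean(log(pmax(picked, 1e-12))), grads = bk$grads, dZ = bk$dX)
}

#' Anchor loss between corresponding latent embeddings
#'
#' Sum over anchor pairs of the Euclidean distance between the two cells'
#' latent embeddings.
#'
#' @param latents_i,latents_j latent matrices of the two modalities.
#' @param anchors 2-column integer matrix of (row in i, row in j) pairs.
#' @return nonnegative scalar; 0 (with a message) for an empty anchor set.
#' @export
anchor_loss <- function(latents_i, latents_j, anchors) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) == 0) {
    message("anchor set is empty; anchor loss is 0")
    return(0)
  }
  if (any(anchors[, 1] > nrow(latents_i)) || any(anchors[, 2] > nrow(latents_j)) ||
      any(anchors < 1)) {
    abort("anchor indices out of range")
  }
  d <- latents_i[anchors[, 1], , drop = FALSE] -
       latents_j[anchors[, 2], , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}
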