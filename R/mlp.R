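# Minimal dense-network engine: layers, forward/backward, Adam.
#
# Networks are lists of layers. A layer is either
#   list(type = "dense", W, b, act)  -- trainable affine + elementwise activation
#   list(type = "fixed", M, back)    -- fixed linear map x %*% M (e.g. pooling,
#                                       upsampling); `back` is t(M-like) for backprop
# All data matrices are samples-in-rows.

ACTIVATIONS <- c("linear", "tanh", "relu", "sigmoid", "softplus")

act_apply <- function(act, z) {
  switch(act,
    linear   = z,
    tanh     = tanh(z),
    relu     = pmax(z, 0),
    sigmoid  = 1 / (1 + exp(-z)),
    softplus = log1p(exp(-abs(z))) + pmax(z, 0),
    abort("unknown activation '%s'", act)
  )
}

# derivative expressed with pre-activation z and post-activation a
act_deriv <- function(act, z, a) {
  switch(act,
    linear   = 1,
    tanh     = 1 - a * a,
    relu     = (z > 0) * 1,
    sigmoid  = a * (1 - a),
    softplus = 1 / (1 + exp(-z)),
    abort("unknown activation '%s'", act)
  )
}

# Glorot-uniform initialised dense layer; seeded so initialisation is a pure
# function of (dims, act, seed).
dense_layer <- function(n_in, n_out, act = "tanh", seed = 1L) {
  stopifnot(act %in% ACTIVATIONS)
  lim <- sqrt(6 / (n_in + n_out))
  W <- with_seed(seed, matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out))
  list(type = "dense", W = W, b = numeric(n_out), act = act)
}

fixed_layer <- function(M) {
  list(type = "fixed", M = M, back = Matrix::t(M))
}

mlp_forward <- function(layers, X, cache = FALSE) {
  caches <- if (cache) vector("list", length(layers)) else NULL
  A <- X
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    if (L$type == "dense") {
      Z <- A %*% L$W
      Z <- sweep(Z, 2, L$b, "+")
      out <- act_apply(L$act, Z)
      if (cache) caches[[i]] <- list(X = A, Z = Z, A = out)
      A <- out
    } else {
      out <- as.matrix(A %*% L$M)
      if (cache) caches[[i]] <- list(X = A)
      A <- out
    }
  }
  if (cache) list(out = A, caches = caches) else A
}

# dOut: gradient of the loss w.r.t. the network output (same shape).
# Returns list(grads = per-layer list (NULL for fixed layers), dX).
mlp_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dA <- dOut
  for (i in rev(seq_along(layers))) {
    L <- layers[[i]]
    cc <- caches[[i]]
    if (L$type == "dense") {
      dZ <- dA * act_deriv(L$act, cc$Z, cc$A)
      grads[[i]] <- list(dW = crossprod(cc$X, dZ), db = colSums(dZ))
      dA <- dZ %*% t(L$W)
    } else {
      dA <- as.matrix(dA %*% L$back)
    }
  }
  list(grads = grads, dX = dA)
}

adam_new <- function(layers) {
  lapply(layers, function(L) {
    if (L$type != "dense") return(NULL)
    list(mW = L$W * 0, vW = L$W * 0, mb = L$b * 0, vb = L$b * 0, t = 0L)
  })
}

# One Adam update; returns list(layers, state).
adam_step <- function(layers, state, grads, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type != "dense" || is.null(grads[[i]])) next
    s <- state[[i]]
    g <- grads[[i]]
    s$t <- s$t + 1L
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    c1 <- 1 - beta1^s$t
    c2 <- 1 - beta2^s$t
    layers[[i]]$W <- layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# scale all gradient entries, or sum two gradient lists (for composite losses)
grads_scale <- function(grads, s) {
  lapply(grads, function(g) if (is.null(g)) NULL else list(dW = g$dW * s, db = g$db * s))
}

grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  mapply(function(ga, gb) {
    if (is.null(ga)) return(gb)
    if (is.null(gb)) return(ga)
    list(dW = ga$dW + gb$dW, db = ga$db + gb$db)
  }, a, b, SIMPLIFY = FALSE)
}

# Sparse average-pooling matrix for a 3D volume flattened in R's column-major
# order: maps prod(shape) voxels to prod(ceiling(shape/factor)) block means.
pooling_matrix <- function(shape, factor) {
  stopifnot(length(shape) == 3, factor >= 1)
  nb <- ceiling(shape / factor)
  idx <- arrayInd(seq_len(prod(shape)), .dim = shape)
  block <- ceiling(idx / factor)
  bcol <- block[, 1] + (block[, 2] - 1) * nb[1] + (block[, 3] - 1) * nb[1] * nb[2]
  counts <- tabulate(bcol, nbins = prod(nb))
  Matrix::sparseMatrix(
    i = seq_len(prod(shape)), j = bcol, x = 1 / counts[bcol],
    dims = c(prod(shape), prod(nb))
  )
}

# Replication (nearest-neighbour upsampling) matrix: blocks back to voxels.
upsample_matrix <- function(shape, factor) {
  P <- pooling_matrix(shape, factor)
  U <- Matrix::t(P)
  U@x <- rep(1, length(U@x))
  U
}
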