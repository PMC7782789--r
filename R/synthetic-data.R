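# Coupled multimodal benchmark generator.
#
# Both modalities are deterministic maps of one shared latent cell state plus
# modality-specific noise: a 50-d "expression-like" vector modality
# (affine map + tanh) and a 3D nuclear-volume modality whose chromatin
# density follows a monotone radial profile (central- or peripheral-enriched
# depending on the cell's subpopulation), so that alignment, translation and
# the radial-feature pipeline can all be tested against known ground truth.

#' Latent cell-state configuration
#'
#' Describes the Gaussian-mixture latent distribution shared by all
#' modalities: `n_clusters` subpopulations with given means, mixing weights
#' and within-cluster spread.
#'
#' @param dim latent dimensionality (>= 1).
#' @param n_clusters number of mixture components.
#' @param cluster_means `n_clusters x dim` matrix of component means.
#' @param cluster_weights mixing probabilities (sum to 1).
#' @param within_cluster_sd nonnegative scalar, length-`dim` vector, or
#'   `n_clusters x dim` matrix of per-coordinate standard deviations (a
#'   matrix gives each subpopulation its own diagonal covariance, which is
#'   what makes the true cross-modal correspondence identifiable from the
#'   marginals).
#' @return a `latent_config` object.
#' @export
latent_config <- function(dim, n_clusters, cluster_means, cluster_weights,
                          within_cluster_sd) {
  if (dim < 1) abort("latent dim must be >= 1")
  cluster_means <- as.matrix(cluster_means)
  if (!all(dim(cluster_means) == c(n_clusters, dim))) {
    abort("cluster_means must be %d x %d (got %d x %d)",
          n_clusters, dim, nrow(cluster_means), ncol(cluster_means))
  }
  if (length(cluster_weights) != n_clusters) abort("need one weight per cluster")
  check_prob_vector(cluster_weights, "cluster_weights")
  if (is.matrix(within_cluster_sd)) {
    if (!all(dim(within_cluster_sd) == c(n_clusters, dim))) {
      abort("within_cluster_sd matrix must be %d x %d", n_clusters, dim)
    }
  } else if (!length(within_cluster_sd) %in% c(1L, dim)) {
    abort("within_cluster_sd must be scalar, length %d, or a matrix", dim)
  }
  if (any(within_cluster_sd < 0)) abort("within_cluster_sd must be >= 0")
  sd_mat <- if (is.matrix(within_cluster_sd)) within_cluster_sd else
    matrix(rep_len(as.numeric(within_cluster_sd), dim), n_clusters, dim,
           byrow = TRUE)
  structure(
    list(dim = as.integer(dim), n_clusters = as.integer(n_clusters),
         cluster_means = cluster_means,
         cluster_weights = as.numeric(cluster_weights),
         within_cluster_sd = within_cluster_sd, sd_matrix = sd_mat),
    class = "latent_config"
  )
}

#' Default latent configuration of the bundled benchmark
#'
#' Two subpopulations (mirroring the two naive T-cell subpopulations) of
#' unequal size in an 8-d latent space. The defaults are chosen so the true
#' cross-modal correspondence is identifiable from the marginal
#' distributions alone: unequal cluster weights pin the cluster
#' correspondence, the cluster-mean displacement has a nonzero component in
#' every shared informative coordinate (pinning axis signs), and the two
#' clusters have distinct diagonal covariances with distinct variance ratios
#' (pinning the within-cluster axes). Coordinates 1-4 carry the shared
#' signal; the last four are low-variance modality-specific nuisance
#' dimensions.
#'
#' @return a `latent_config`.
#' @export
default_latent_config <- function() {
  d <- 8L
  mu <- rbind(c(-2.2, -0.8, -0.6, -0.5, rep(0, d - 4)),
              c( 2.2,  0.8,  0.6,  0.5, rep(0, d - 4)))
  sds <- rbind(c(0.45, 1.1, 0.7, 0.95, 0.55, 0.40, 0.50, 0.38),
               c(0.75, 0.7, 1.0, 0.55, 0.40, 0.55, 0.35, 0.50))
  latent_config(
    dim = d, n_clusters = 2L, cluster_means = mu,
    cluster_weights = c(0.6, 0.4),
    within_cluster_sd = sds
  )
}

#' Sample latent cell states from a mixture configuration
#'
#' @param config a [latent_config()].
#' @param n number of cells (>= 0).
#' @param seed integer seed; identical inputs give bit-identical output.
#' @return list with `latent` (`n x dim` matrix) and `labels`
#'   (integer component per cell).
#' @export
sample_latent <- function(config, n, seed) {
  stopifnot(inherits(config, "latent_config"))
  if (n < 0) abort("n must be >= 0")
  d <- config$dim
  if (n == 0) {
    return(list(latent = matrix(numeric(0), 0, d), labels = integer(0)))
  }
  with_seed(derive_seed(seed, "sample_latent"), {
    labels <- sample.int(config$n_clusters, n, replace = TRUE,
                         prob = config$cluster_weights)
    noise <- matrix(stats::rnorm(n * d), n, d)
    noise <- noise * config$sd_matrix[labels, , drop = FALSE]
    latent <- config$cluster_means[labels, , drop = FALSE] + noise
    list(latent = latent, labels = as.integer(labels))
  })
}

#' Modality specification
#'
#' Describes one observed modality as a deterministic map of (a subset of)
#' the latent coordinates plus additive noise.
#'
#' @param kind `"vector"` or `"volume"`.
#' @param output_shape integer vector: output dimensionality (length 1 for
#'   vector data, the voxel grid shape for volumes).
#' @param map list of map parameters (see [default_vector_spec()] and
#'   [default_volume_spec()]).
#' @param noise_sd nonnegative noise standard deviation.
#' @param shared_dims latent coordinates this modality responds to.
#' @return a `modality_spec` object.
#' @export
modality_spec <- function(kind = c("vector", "volume"), output_shape, map,
                          noise_sd = 0, shared_dims) {
  kind <- match.arg(kind)
  if (kind == "vector" && length(output_shape) != 1L) {
    abort("vector modalities have 1-dimensional output_shape")
  }
  if (kind == "volume" && length(output_shape) != 3L) {
    abort("volume modalities need a 3-element output_shape")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (length(shared_dims) == 0) abort("shared_dims must be nonempty")
  structure(
    list(kind = kind, output_shape = as.integer(output_shape), map = map,
         noise_sd = noise_sd, shared_dims = as.integer(shared_dims)),
    class = "modality_spec"
  )
}

#' Default expression-like vector modality (affine + tanh, 50 features)
#'
#' @param latent_dim latent dimensionality the map consumes.
#' @param n_features output dimensionality.
#' @param noise_sd additive noise sd.
#' @param seed seed for drawing the fixed affine parameters.
#' @return a `modality_spec` with `map = list(A, b)` realizing
#'   `tanh(z %*% A + b)`.
#' @export
default_vector_spec <- function(latent_dim = 8L, n_features = 50L,
                                noise_sd = 0.05, seed = 20201204L) {
  A <- with_seed(derive_seed(seed, "vector_map"),
                 matrix(stats::rnorm(latent_dim * n_features, sd = 0.35),
                        latent_dim, n_features))
  b <- with_seed(derive_seed(seed, "vector_bias"),
                 stats::rnorm(n_features, sd = 0.1))
  modality_spec("vector", n_features,
                map = list(A = A, b = b, nonlinearity = "tanh"),
                noise_sd = noise_sd, shared_dims = seq_len(latent_dim))
}

#' Default 3D nuclear-volume modality (32^3 voxels, 0.5 um spacing)
#'
#' Each nucleus is a (mildly ellipsoidal) nuclear mask whose chromatin
#' intensity follows `exp(s * m * rhat^p)` in the normalized radius `rhat`:
#' `s < 0` gives a centrally enriched profile (cluster 1), `s > 0` a
#' peripherally enriched one (cluster 2). The profile direction is set by
#' the latent position along the cluster-separating axis; its steepness,
#' shape and the nuclear radius are modulated by latent coordinates 2-4,
#' and the nuclear centre offset and ellipticity by coordinates 5-8, so
#' every latent coordinate leaves a recoverable imprint on the image.
#'
#' @param latent_dim latent dimensionality.
#' @param shape voxel grid shape.
#' @param spacing_um voxel spacing in micrometres (x, y, z).
#' @param radius_um baseline nuclear radius in micrometres.
#' @param noise_sd voxel noise sd (applied inside the mask, clipped at 0).
#' @return a `modality_spec`.
#' @export
default_volume_spec <- function(latent_dim = 8L, shape = c(32L, 32L, 32L),
                                spacing_um = c(0.5, 0.5, 0.5),
                                radius_um = 6, noise_sd = 0.02) {
  if (radius_um <= 0) abort("radius_um must be positive")
  if (any(spacing_um <= 0)) abort("spacing_um must be positive")
  direction <- c(4.4, 1.6, 1.2, 1.0, rep(0, latent_dim - 4))
  direction <- direction / sqrt(sum(direction^2))
  modality_spec("volume", shape,
                map = list(direction = direction, steep0 = 1.5, steep_coef = 0.6,
                           shape_coef = 0.3, radius_coef = 0.06,
                           offset_coef_um = 0.35, ellip_coef = 0.05,
                           radius_um = radius_um, spacing_um = spacing_um),
                noise_sd = noise_sd, shared_dims = seq_len(latent_dim))
}

#' Generate a vector modality from latent states
#'
#' Applies the spec's affine map and elementwise nonlinearity to the selected
#' latent coordinates, then adds i.i.d. Gaussian noise of sd `noise_sd`.
#'
#' @param latent `n x dim` latent matrix.
#' @param spec a vector `modality_spec`.
#' @param seed integer seed for the noise draw.
#' @return `n x output_shape` data matrix.
#' @export
generate_vector_modality <- function(latent, spec, seed) {
  stopifnot(inherits(spec, "modality_spec"))
  if (spec$kind != "vector") abort("spec must have kind 'vector'")
  latent <- as.matrix(latent)
  if (ncol(latent) < max(spec$shared_dims)) {
    abort("latent has %d columns but shared_dims needs %d",
          ncol(latent), max(spec$shared_dims))
  }
  Z <- latent[, spec$shared_dims, drop = FALSE]
  A <- spec$map$A
  if (nrow(A) != ncol(Z) || ncol(A) != spec$output_shape) {
    abort("map matrix is %d x %d but needs %d x %d",
          nrow(A), ncol(A), ncol(Z), spec$output_shape)
  }
  X <- sweep(Z %*% A, 2, spec$map$b, "+")
  nl <- spec$map$nonlinearity %||% "tanh"
  X <- act_apply(nl, X)
  if (spec$noise_sd > 0 && nrow(X) > 0) {
    X <- X + with_seed(derive_seed(seed, "vector_noise"),
                       matrix(stats::rnorm(length(X), sd = spec$noise_sd),
                              nrow(X), ncol(X)))
  }
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clamp helper for modulation coordinates (keeps renders in a sane range)
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a 3D volume modality from latent states
#'
#' Renders, per cell, a spherical nuclear mask with a strictly monotone
#' radial chromatin profile (centrally enriched for one subpopulation,
#' peripherally enriched for the other) modulated by the cell's latent
#' coordinates; voxel noise is added inside the mask and clipped at zero, and
#' all intensity outside the mask is exactly zero.
#'
#' @param latent `n x dim` latent matrix.
#' @param spec a volume `modality_spec`.
#' @param seed integer seed for the voxel noise.
#' @param directions optional numeric vector of length `n` overriding the
#'   profile direction per cell (negative = central, positive = peripheral);
#'   by default the sign of the latent projection on the cluster axis.
#' @return list of `n` elements, each `list(volume, mask, spacing_um)`.
#' @export
generate_volume_modality <- function(latent, spec, seed, directions = NULL) {
  stopifnot(inherits(spec, "modality_spec"))
  if (spec$kind != "volume") abort("spec must have kind 'volume'")
  latent <- as.matrix(latent)
  m <- spec$map
  if (m$radius_um <= 0) abort("radius_um must be positive")
  if (any(m$spacing_um <= 0)) abort("spacing_um must be positive")
  shape <- spec$output_shape
  n <- nrow(latent)
  if (is.null(directions)) {
    directions <- as.numeric(latent[, seq_along(m$direction), drop = FALSE] %*%
                               m$direction)
  }
  stopifnot(length(directions) == n)

  # physical voxel coordinates relative to the grid centre, computed once
  centre <- (shape + 1) / 2
  ax <- lapply(1:3, function(a) (seq_len(shape[a]) - centre[a]) * m$spacing_um[a])
  off_coef <- m$offset_coef_um %||% 0
  ell_coef <- m$ellip_coef %||% 0

  out <- vector("list", n)
  for (i in seq_len(n)) {
    z <- latent[i, ]
    s <- if (directions[i] < 0) -1 else 1
    steep <- act_apply("softplus", matrix(m$steep0 + m$steep_coef * z[2]))[1]
    p <- exp(m$shape_coef * clamp(z[3], -2.5, 2.5))
    R <- m$radius_um * (1 + m$radius_coef * clamp(z[4], -2.5, 2.5))
    d <- length(z)
    off <- off_coef * clamp(c(z[min(5, d)], z[min(6, d)], z[min(7, d)]),
                            -2.5, 2.5) * (d >= 7)
    ell <- exp(ell_coef * clamp(z[min(8, d)], -2.5, 2.5) * (d >= 8))
    # ellipsoidal physical distance from the (offset) nuclear centre
    x2 <- ((ax[[1]] - off[1]) * ell)^2
    y2 <- ((ax[[2]] - off[2]) / ell)^2
    z2 <- (ax[[3]] - off[3])^2
    r <- sqrt(outer(outer(x2, y2, "+"), z2, "+"))
    mask <- r <= R
    if (!any(mask)) abort("nuclear mask is empty; radius too small for grid")
    rhat <- r / R
    vol <- array(0, dim = shape)
    vol[mask] <- exp(s * steep * rhat[mask]^p)
    vol <- vol / max(vol)
    if (spec$noise_sd > 0) {
      noise <- with_seed(derive_seed(seed, paste0("volume_noise_", i)),
                         stats::rnorm(sum(mask), sd = spec$noise_sd))
      vol[mask] <- pmax(vol[mask] + noise, 0)
      vol <- vol / max(vol)  # keep intensities in [0, 1] after noise
    }
    storage.mode(mask) <- "integer"
    out[[i]] <- list(volume = vol, mask = array(mask, dim = shape),
                     spacing_um = m$spacing_um)
  }
  out
}

#' Assemble a coupled two-(or more-)modality benchmark
#'
#' All modalities are generated from the same latent draw; each modality's
#' sample order is then independently shuffled so the datasets are genuinely
#' unpaired, with the true correspondence recorded in `pairing` and an
#' anchor subset of known pairs of size `round(anchor_fraction * n)`.
#'
#' @param latent_cfg a [latent_config()].
#' @param specs list of >= 2 [modality_spec()] objects.
#' @param n number of cells per modality.
#' @param anchor_fraction fraction of cells with known correspondence, in
#'   \[0, 1\].
#' @param seed integer seed; the benchmark is a pure function of its inputs.
#' @return a `coupled_benchmark`: `latent` (original order), `datasets`
#'   (shuffled per modality), `labels` (per modality), `orders` (original
#'   index of each row per modality), `pairing` (row j of modality 2 matching
#'   row i of modality 1), `anchors` (2-column matrix of row indices), `seed`.
#' @export
make_benchmark <- function(latent_cfg, specs, n, anchor_fraction = 0, seed = 1L) {
  if (length(specs) < 2) abort("need at least 2 modality specs")
  if (anchor_fraction < 0 || anchor_fraction > 1) {
    abort("anchor_fraction must be in [0, 1]")
  }
  draw <- sample_latent(latent_cfg, n, seed)
  datasets <- vector("list", length(specs))
  labels <- vector("list", length(specs))
  orders <- vector("list", length(specs))
  for (mdl in seq_along(specs)) {
    spec <- specs[[mdl]]
    data <- if (spec$kind == "vector") {
      generate_vector_modality(draw$latent, spec, derive_seed(seed, paste0("mod", mdl)))
    } else {
      generate_volume_modality(draw$latent, spec, derive_seed(seed, paste0("mod", mdl)))
    }
    ord <- with_seed(derive_seed(seed, paste0("shuffle", mdl)), sample.int(n))
    orders[[mdl]] <- ord
    labels[[mdl]] <- draw$labels[ord]
    datasets[[mdl]] <- if (spec$kind == "vector") {
      data[ord, , drop = FALSE]
    } else {
      data[ord]
    }
  }
  # pairing between modalities 1 and 2: row i of modality 1 <-> row pairing[i] of 2
  pairing <- if (n > 0) match(orders[[1]], orders[[2]]) else integer(0)
  n_anchor <- round(anchor_fraction * n)
  anchors <- if (n_anchor > 0) {
    rows1 <- with_seed(derive_seed(seed, "anchors"),
                       sort(sample.int(n, n_anchor)))
    cbind(i = rows1, j = pairing[rows1])
  } else {
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
  }
  structure(
    list(latent = draw$latent, true_labels = draw$labels, datasets = datasets,
         labels = labels, orders = orders, pairing = pairing,
         anchors = anchors, specs = specs, latent_cfg = latent_cfg,
         n = as.integer(n), anchor_fraction = anchor_fraction,
         seed = as.integer(seed)),
    class = "coupled_benchmark"
  )
}

#' Pairing between two modalities of a benchmark
#'
#' @param bench a `coupled_benchmark`.
#' @param i,j modality indices.
#' @return integer vector p with row `r` of modality `i` matching row `p[r]`
#'   of modality `j`.
#' @export
pairing_between <- function(bench, i, j) {
  match(bench$orders[[i]], bench$orders[[j]])
}
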