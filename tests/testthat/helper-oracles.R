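# Independent brute-force oracles used to cross-check the package's
# computations. Each deliberately takes a different code path from the
# implementation it checks.

# direct 3D box erosion: AND over every offset in the box (the package uses
# separable per-axis passes)
shift3_oracle <- function(m, off) {
  d <- dim(m)
  out <- array(FALSE, d)
  xs <- seq_len(d[1]) - off[1]; ys <- seq_len(d[2]) - off[2]
  zs <- seq_len(d[3]) - off[3]
  okx <- xs >= 1 & xs <= d[1]; oky <- ys >= 1 & ys <= d[2]
  okz <- zs >= 1 & zs <= d[3]
  out[okx, oky, okz] <- m[xs[okx], ys[oky], zs[okz]]
  out
}

erode_box_oracle <- function(mask, radii) {
  out <- array(TRUE, dim(mask))
  for (dx in -radii[1]:radii[1]) {
    for (dy in -radii[2]:radii[2]) {
      for (dz in -radii[3]:radii[3]) {
        out <- out & shift3_oracle(mask, c(dx, dy, dz))
      }
    }
  }
  out
}

# iterated physical-unit erosion, counting the masks the stopping rule keeps
shell_count_oracle <- function(mask, spacing, step = 0.5, min_vol = 10) {
  radii <- pmax(1L, as.integer(round(step / spacing)))
  vox <- prod(spacing)
  count <- 1L
  current <- mask
  while (sum(current) * vox >= min_vol) {
    nxt <- erode_box_oracle(current, radii)
    if (!any(nxt)) break
    count <- count + 1L
    current <- nxt
    if (sum(current) * vox < min_vol) break
  }
  count
}

# per-voxel ring averaging driven by tapply over a shell-id labelling
ring_means_oracle <- function(intensities, shells) {
  id <- array(0L, dim(intensities))
  for (t in seq_along(shells)) id[shells[[t]]] <- t
  means <- tapply(intensities[id > 0], id[id > 0], mean)
  as.numeric(means[order(as.integer(names(means)))])
}

welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n; sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

auc_mannwhitney_oracle <- function(scores, labels) {
  lab <- as.integer(factor(labels))
  pos <- scores[lab == 2L]; neg <- scores[lab == 1L]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

coassoc_oracle <- function(labelings) {
  n <- length(labelings[[1]])
  M <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      M[a, b] <- mean(vapply(labelings,
                             function(l) l[a] == l[b], logical(1)))
    }
  }
  M
}

# naive bottom-up complete-linkage agglomeration on a distance matrix
complete_linkage_oracle <- function(D, k) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        d <- max(D[groups[[a]], groups[[b]]])
        if (d < best[1]) best <- c(d, a, b)
      }
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# digital sphere mask helper (anisotropic spacing supported)
sphere_mask <- function(radius_um, spacing, margin_vox = 2) {
  rv <- ceiling(radius_um / spacing)
  d <- 2 * (rv + margin_vox) + 1
  ax <- lapply(1:3, function(a) {
    (((seq_len(d[a])) - (d[a] + 1) / 2) * spacing[a])^2
  })
  r <- sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
  r <= radius_um
}
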