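# Radial chromatin-density profiling of segmented 3D nuclei.
#
# The nucleus mask is iteratively eroded in physical steps of 0.5 um along
# x, y and z until the remaining core falls below 10 um^3; consecutive masks
# define concentric rings whose mean intensities, max-normalized and linearly
# interpolated onto ten nuclear volume-fraction bins, summarize where in the
# nucleus the chromatin sits (centrally vs peripherally enriched).

#' Voxel volume container
#'
#' @param intensities nonnegative 3D array.
#' @param mask binary 3D array of the same shape (the segmented nucleus).
#' @param spacing_um positive voxel spacing in micrometres (x, y, z).
#' @return a `voxel_volume` object.
#' @export
voxel_volume <- function(intensities, mask, spacing_um) {
  intensities <- as.array(intensities)
  mask <- as.array(mask)
  if (!identical(dim(intensities), dim(mask))) {
    abort("intensities and mask shapes differ")
  }
  if (length(dim(intensities)) != 3) abort("expected 3D arrays")
  if (any(spacing_um <= 0) || length(spacing_um) != 3) {
    abort("spacing_um must be 3 positive values")
  }
  if (!any(mask != 0)) abort("mask is empty")
  structure(list(intensities = intensities, mask = array(mask != 0, dim(mask)),
                 spacing_um = as.numeric(spacing_um)),
            class = "voxel_volume")
}

# separable binary erosion/dilation by a box element with per-axis voxel
# radius; voxels outside the array count as background.
shift_logical <- function(m, axis, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) 1:(n - by) else (1 - by):n
  dst <- if (by >= 0) (1 + by):n else 1:(n + by)
  ix <- rep(list(quote(expr = )), 3)
  ix_src <- ix; ix_src[[axis]] <- src
  ix_dst <- ix; ix_dst[[axis]] <- dst
  out <- do.call(`[<-`, c(list(out), ix_dst,
                          list(do.call(`[`, c(list(m), ix_src, list(drop = FALSE))))))
  out
}

morph_box <- function(mask, radii_vox, op = c("erode", "dilate")) {
  op <- match.arg(op)
  m <- array(mask != 0, dim(mask))
  for (axis in 1:3) {
    r <- radii_vox[axis]
    if (r < 1) next
    acc <- m
    for (by in c(-seq_len(r), seq_len(r))) {
      s <- shift_logical(m, axis, by)
      acc <- if (op == "erode") acc & s else acc | s
    }
    m <- acc
  }
  m
}

# per-axis voxel radius realizing a physical step (minimum 1 voxel)
step_radii <- function(step_um, spacing_um) {
  pmax(1L, as.integer(round(step_um / spacing_um)))
}

#' Nested erosion shells of a nuclear mask
#'
#' Erodes the mask by `step_um` micrometres along each axis iteratively; the
#' iteration stops at the first mask whose physical volume falls below
#' `min_volume_um3` (that sub-threshold core is retained as the innermost
#' mask). Ring `t` is the set difference of masks `t` and `t + 1`.
#'
#' @param mask binary 3D array (nonempty).
#' @param spacing_um voxel spacing (x, y, z) in micrometres.
#' @param step_um erosion step in micrometres (default 0.5).
#' @param min_volume_um3 stopping volume in cubic micrometres (default 10).
#' @return list of logical masks, outermost first, strictly nested.
#' @export
erode_shells <- function(mask, spacing_um, step_um = 0.5, min_volume_um3 = 10) {
  mask <- array(mask != 0, dim(mask))
  if (!any(mask)) abort("mask is empty")
  if (step_um <= 0) abort("step_um must be positive")
  if (any(spacing_um <= 0)) abort("spacing_um must be positive")
  vox_um3 <- prod(spacing_um)
  radii <- step_radii(step_um, spacing_um)
  shells <- list(mask)
  current <- mask
  while (sum(current) * vox_um3 >= min_volume_um3) {
    nxt <- morph_box(current, radii, "erode")
    if (!any(nxt)) break
    shells[[length(shells) + 1L]] <- nxt
    current <- nxt
    if (sum(current) * vox_um3 < min_volume_um3) break
  }
  shells
}

#' Mean intensity of each concentric ring
#'
#' @param volume a [voxel_volume()].
#' @param shells nested masks from [erode_shells()] on `volume$mask`.
#' @return numeric vector, entry `t` the mean intensity over ring `t`
#'   (outermost ring first; the innermost core is its own ring).
#' @export
ring_mean_intensities <- function(volume, shells) {
  stopifnot(inherits(volume, "voxel_volume"))
  n <- length(shells)
  means <- numeric(n)
  for (t in seq_len(n)) {
    ring <- if (t < n) shells[[t]] & !shells[[t + 1]] else shells[[t]]
    cnt <- sum(ring)
    if (cnt == 0) abort("ring %d has zero voxels", t)
    means[t] <- sum(volume$intensities[ring]) / cnt
  }
  means
}

#' Max-normalized intensity fractions
#'
#' @param ring_means vector of ring mean intensities with at least one
#'   strictly positive entry.
#' @return `ring_means / max(ring_means)`; the maximum is exactly 1.
#' @export
intensity_fractions <- function(ring_means) {
  m <- max(ring_means)
  if (m <= 0) abort("all ring means are zero; cannot normalize")
  ring_means / m
}

#' Interpolate ring intensity fractions onto 10 volume-fraction bins
#'
#' Bins follow the growing concentric spheres read from the nuclear centre
#' outward: bin 1 is the central 0-10% of the nuclear volume, bin 10 the
#' peripheral 90-100%. Each ring is placed at the midpoint of the cumulative
#' (centre-out) volume fraction it occupies and the intensity fraction is
#' linearly interpolated at the ten bin midpoints 5%, 15%, ..., 95%,
#' clamping outside the ring range to the nearest ring's value.
#'
#' @param fractions intensity fractions per ring (outermost first, matching
#'   [ring_mean_intensities()]).
#' @param shell_volumes_um3 physical volume of each nested shell, strictly
#'   decreasing, same length.
#' @return numeric vector of length 10 (bins 0-10% ... 90-100%, centre to
#'   periphery).
#' @export
interp_to_volume_bins <- function(fractions, shell_volumes_um3) {
  k <- length(fractions)
  if (length(shell_volumes_um3) != k) abort("length mismatch")
  if (k >= 2 && any(diff(shell_volumes_um3) >= 0)) {
    abort("shell volumes must be strictly decreasing")
  }
  if (k == 1) return(rep(fractions, 10))
  total <- shell_volumes_um3[1]
  ring_vol <- c(shell_volumes_um3[-k] - shell_volumes_um3[-1],
                shell_volumes_um3[k])
  upper <- cumsum(ring_vol) / total        # cumulative fraction, outside-in
  lower <- c(0, upper[-k])
  mid_centre_out <- 1 - (lower + upper) / 2   # ring midpoint, centre-out
  ord <- order(mid_centre_out)
  targets <- seq(0.05, 0.95, by = 0.1)
  stats::approx(mid_centre_out[ord], fractions[ord], xout = targets,
                rule = 2)$y
}

#' Extract the radial chromatin profile of one nucleus
#'
#' Composition of [erode_shells()], [ring_mean_intensities()],
#' [intensity_fractions()] and [interp_to_volume_bins()].
#'
#' @param volume a [voxel_volume()].
#' @param step_um erosion step (default 0.5 um).
#' @param min_volume_um3 erosion stopping volume (default 10 um^3).
#' @return a `radial_profile`: `ring_means` (outermost ring first),
#'   `intensity_fractions`, `shell_volumes_um3` and `binned10` (the ten
#'   volume-fraction bins, centre to periphery).
#' @export
extract_profile <- function(volume, step_um = 0.5, min_volume_um3 = 10) {
  stopifnot(inherits(volume, "voxel_volume"))
  shells <- erode_shells(volume$mask, volume$spacing_um, step_um, min_volume_um3)
  means <- ring_mean_intensities(volume, shells)
  fr <- intensity_fractions(means)
  vols <- vapply(shells, sum, numeric(1)) * prod(volume$spacing_um)
  structure(list(ring_means = means, intensity_fractions = fr,
                 shell_volumes_um3 = vols,
                 binned10 = interp_to_volume_bins(fr, vols)),
            class = "radial_profile")
}

#' Cluster radial profiles by 1 - Spearman correlation, complete linkage
#'
#' Pairwise distances between the 10-bin profiles are `1 - rho` (Spearman);
#' profiles are agglomerated with complete linkage and the tree cut to
#' `n_clusters` groups. A constant profile has undefined rank correlation;
#' its distance to any other profile is set to 1 with a warning.
#'
#' @param profiles list of `radial_profile` objects (or a matrix with one
#'   10-bin profile per row).
#' @param n_clusters number of groups (default 2).
#' @return integer cluster labels.
#' @export
cluster_profiles <- function(profiles, n_clusters = 2) {
  B <- if (is.matrix(profiles)) profiles else
    do.call(rbind, lapply(profiles, function(p) p$binned10))
  n <- nrow(B)
  if (n < n_clusters) abort("need at least n_clusters profiles")
  const <- apply(B, 1, function(x) diff(range(x)) == 0)
  if (any(const)) warning("constant profile(s): Spearman undefined, distance set to 1")
  rho <- suppressWarnings(stats::cor(t(B), method = "spearman"))
  D <- 1 - rho
  if (any(const)) {
    D[const, ] <- 1
    D[, const] <- 1
  }
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "complete")
  stats::cutree(hc, k = n_clusters)
}

#' Protein-channel intensity ratio in the dilated nuclear object
#'
#' Dilates the nuclear mask by `dilation_um` micrometres along each axis
#' (capturing the whole cell for round cells with high karyoplasmic index)
#' and returns the ratio of total channel intensities inside the dilated
#' object.
#'
#' @param channel_a,channel_b [voxel_volume()] objects sharing shape and
#'   spacing with `nuclear_mask`.
#' @param nuclear_mask binary 3D array.
#' @param dilation_um dilation in micrometres (default 2).
#' @return `sum(channel_a) / sum(channel_b)` over the dilated mask.
#' @export
protein_ratio <- function(channel_a, channel_b, nuclear_mask, dilation_um = 2) {
  stopifnot(inherits(channel_a, "voxel_volume"), inherits(channel_b, "voxel_volume"))
  if (!identical(dim(channel_a$intensities), dim(nuclear_mask)) ||
      !identical(dim(channel_b$intensities), dim(nuclear_mask))) {
    abort("channels and mask shapes differ")
  }
  radii <- step_radii(dilation_um, channel_a$spacing_um)
  dil <- morph_box(nuclear_mask, radii, "dilate")
  denom <- sum(channel_b$intensities[dil])
  if (denom == 0) abort("zero total intensity in channel_b over the dilated mask")
  sum(channel_a$intensities[dil]) / denom
}
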