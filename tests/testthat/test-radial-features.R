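test_that("erosion shells nest strictly and honour the stopping volume", {
  sp <- c(0.5, 0.5, 0.5)
  # a 1-um sphere is already below 10 um^3: no erosion at all
  tiny <- sphere_mask(1, sp)
  expect_length(erode_shells(tiny, sp), 1)

  big <- sphere_mask(5, sp)
  shells <- erode_shells(big, sp)
  expect_gt(length(shells), 2)
  for (t in seq_len(length(shells) - 1)) {
    expect_true(all(shells[[t]][shells[[t + 1]]]))       # nested
    expect_lt(sum(shells[[t + 1]]), sum(shells[[t]]))    # strictly smaller
  }
  # innermost core is the first mask below the stopping volume
  vols <- vapply(shells, sum, numeric(1)) * prod(sp)
  expect_true(all(vols[-length(vols)] >= 10))
  expect_lt(vols[length(vols)], 10)

  expect_error(erode_shells(array(FALSE, c(3, 3, 3)), sp), "empty")
  expect_error(erode_shells(big, sp, step_um = 0), "step_um")
})

test_that("shell counts match a physical-unit brute-force erosion oracle", {
  sp <- c(0.25, 0.25, 0.25)
  mask <- sphere_mask(3, sp)
  expect_equal(length(erode_shells(mask, sp)),
               shell_count_oracle(mask, sp))
  # anisotropic voxels (thin z-slices like confocal stacks)
  spa <- c(0.25, 0.25, 0.5)
  mask2 <- sphere_mask(2.5, spa)
  expect_equal(length(erode_shells(mask2, spa)),
               shell_count_oracle(mask2, spa))
})

test_that("ring means average the intensity over each concentric ring", {
  sp <- c(0.5, 0.5, 0.5)
  mask <- sphere_mask(4, sp)
  shells <- erode_shells(mask, sp)

  const <- voxel_volume(array(3.5, dim(mask)) * (mask * 1), mask, sp)
  expect_equal(ring_mean_intensities(const, shells),
               rep(3.5, length(shells)))

  # intensity = distance from centroid: means strictly increase outward,
  # i.e. decrease along the outermost-first ordering
  d <- dim(mask)
  ax <- lapply(1:3, function(a) ((seq_len(d[a]) - (d[a] + 1) / 2) * sp[a])^2)
  r <- sqrt(outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+"))
  vol <- voxel_volume(r * mask, mask, sp)
  means <- ring_mean_intensities(vol, shells)
  expect_true(all(diff(means) < 0))
  expect_equal(means, ring_means_oracle(vol$intensities, shells),
               tolerance = 1e-10)

  # a pathological shell list with an empty ring errors
  expect_error(ring_mean_intensities(vol, list(mask, mask)), "zero voxels")
})

test_that("intensity fractions are max-normalized and invertible", {
  expect_equal(intensity_fractions(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(intensity_fractions(rep(7, 5)), rep(1, 5))
  set.seed(3)
  x <- runif(12, 0.1, 9)
  expect_equal(intensity_fractions(x) * max(x), x, tolerance = 1e-12)
  expect_error(intensity_fractions(c(0, 0)), "zero")
})

test_that("volume-fraction binning interpolates centre-out", {
  vols <- c(100, 70, 40, 15)
  expect_equal(interp_to_volume_bins(rep(0.8, 4), vols), rep(0.8, 10))

  # fractions linear in centre-out cumulative volume fraction reproduce the
  # line at the bin midpoints (within the clamped range)
  k <- 6
  sv <- seq(120, 20, length.out = k)
  upper <- cumsum(c(sv[-k] - sv[-1], sv[k])) / sv[1]
  mids <- 1 - (c(0, upper[-k]) + upper) / 2
  fr <- 0.2 + 0.6 * mids
  got <- interp_to_volume_bins(fr, sv)
  targets <- seq(0.05, 0.95, by = 0.1)
  inside <- targets >= min(mids) & targets <= max(mids)
  expect_equal(got[inside], 0.2 + 0.6 * targets[inside], tolerance = 1e-12)

  # two rings: piecewise-linear with clamping, hand-computed
  sv2 <- c(100, 40)           # ring mids (centre-out): 1-0.3=0.7, 1-0.8=0.2
  fr2 <- c(0.4, 1)            # outermost ring first
  m_in <- 0.2; m_out <- 0.7
  expected <- vapply(targets, function(t) {
    if (t <= m_in) 1
    else if (t >= m_out) 0.4
    else 1 + (t - m_in) / (m_out - m_in) * (0.4 - 1)
  }, numeric(1))
  expect_equal(interp_to_volume_bins(fr2, sv2), expected, tolerance = 1e-12)

  expect_error(interp_to_volume_bins(c(1, 1), c(50, 60)), "decreasing")
})

test_that("extract_profile composes the pipeline deterministically", {
  sp <- c(0.5, 0.5, 0.5)
  mask <- sphere_mask(4, sp)
  uni <- voxel_volume(array(1, dim(mask)) * (mask * 1), mask, sp)
  p <- extract_profile(uni)
  expect_equal(p$binned10, rep(1, 10))
  expect_length(p$binned10, 10)
  expect_equal(max(p$intensity_fractions), 1)

  # synthetic central nucleus: binned10 decreases from the central bin 1
  # to the peripheral bin 10
  lc <- default_latent_config()
  spec0 <- default_volume_spec(); spec0$noise_sd <- 0
  v <- generate_volume_modality(lc$cluster_means[1, , drop = FALSE], spec0, 1)[[1]]
  pc <- extract_profile(voxel_volume(v$volume, v$mask, v$spacing_um))
  # nonincreasing centre-out with a strict overall fall; clamping at the
  # outermost rings can duplicate the boundary bins
  expect_true(all(diff(pc$binned10) <= 0))
  expect_lt(sum(diff(pc$binned10)), 0)

  expect_identical(extract_profile(uni), p)
})

test_that("shell volumes decrease and rings partition the mask", {
  sp <- c(0.5, 0.5, 0.5)
  mask <- sphere_mask(4, sp)
  shells <- erode_shells(mask, sp)
  vols <- vapply(shells, sum, numeric(1))
  expect_true(all(diff(vols) < 0))
  n <- length(shells)
  ring_counts <- vapply(seq_len(n), function(t) {
    if (t < n) sum(shells[[t]] & !shells[[t + 1]]) else sum(shells[[t]])
  }, numeric(1))
  expect_equal(sum(ring_counts), sum(mask))

  # scale invariance of the profile
  r <- array(runif(length(mask), 0.2, 1), dim(mask)) * (mask * 1)
  v1 <- extract_profile(voxel_volume(r, mask, sp))
  v2 <- extract_profile(voxel_volume(5.7 * r, mask, sp))
  expect_equal(v1$binned10, v2$binned10, tolerance = 1e-12)
})

test_that("profile clustering matches a naive complete-linkage oracle", {
  # two rank-distinct groups split perfectly
  up <- seq(0.1, 1, length.out = 10)
  down <- rev(up)
  profs <- rbind(up, up, up, down, down)
  lab <- cluster_profiles(profs, 2)
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:5])), 1)
  expect_true(lab[1] != lab[4])

  # 5 jittered profiles against the brute-force agglomerator
  set.seed(11)
  P <- rbind(up + rnorm(10, sd = 0.03), up + rnorm(10, sd = 0.03),
             down + rnorm(10, sd = 0.03), down + rnorm(10, sd = 0.03),
             up * up + rnorm(10, sd = 0.03))
  D <- 1 - cor(t(P), method = "spearman")
  diag(D) <- 0
  for (k in 2:3) {
    got <- cluster_profiles(P, k)
    want <- complete_linkage_oracle(D, k)
    # compare partitions up to label permutation
    expect_equal(outer(got, got, "=="), outer(want, want, "=="))
  }

  # constant profile: warned about, maximally distant
  expect_warning(cl <- cluster_profiles(rbind(up, down, rep(0.5, 10)), 2),
                 "constant")
  expect_length(cl, 3)
  expect_error(cluster_profiles(rbind(up), 2), "at least")
})

test_that("protein ratios integrate channels over the dilated nucleus", {
  sp <- c(0.5, 0.5, 0.5)
  mask <- sphere_mask(2.5, sp)
  d <- dim(mask)
  set.seed(4)
  base <- array(runif(prod(d)), d)
  cha <- voxel_volume(2 * base, mask, sp)
  chb <- voxel_volume(base, mask, sp)
  expect_equal(protein_ratio(cha, chb, mask), 2, tolerance = 1e-12)

  # dilation strictly grows an interior mask
  dil <- xmodal:::morph_box(mask, xmodal:::step_radii(2, sp), "dilate")
  expect_gt(sum(dil), sum(mask))
  expect_true(all(dil[mask]))

  # random channels against direct summation over the dilated object
  chc <- voxel_volume(array(runif(prod(d)), d), mask, sp)
  got <- protein_ratio(cha, chc, mask)
  want <- sum(cha$intensities[dil]) / sum(chc$intensities[dil])
  expect_equal(got, want, tolerance = 1e-10)

  zero <- voxel_volume(array(0, d), mask, sp)
  expect_error(protein_ratio(cha, zero, mask), "zero")
})

test_that("radial clustering separates central from peripheral nuclei exactly", {
  skip_if_not_installed("mclust")
  lc <- default_latent_config()
  spec0 <- default_volume_spec(); spec0$noise_sd <- 0
  draw <- sample_latent(lc, 40, 77)
  # force balanced classes via the direction override
  dirs <- rep(c(-1, 1), each = 20)
  vols <- generate_volume_modality(draw$latent, spec0, 1, directions = dirs)
  profs <- lapply(vols, function(v)
    extract_profile(voxel_volume(v$volume, v$mask, v$spacing_um)))
  lab <- cluster_profiles(profs, 2)
  truth <- rep(1:2, each = 20)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1.0)
})
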