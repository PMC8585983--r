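test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- small_spec(seed = 5L, shape = c(64L, 64L, 24L))
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$data, b$data)
  expect_identical(attr(a, "features"), attr(b, "features"))
  spec2 <- small_spec(seed = 6L, shape = c(64L, 64L, 24L))
  expect_false(identical(generate_phantom(spec2)$data, a$data))
})

test_that("zero speckle density gives pure background and nothing trackable", {
  spec <- flat_spec(shape = c(128L, 128L, 1L))
  spec$speckle_density <- 0
  ph <- generate_phantom(spec)
  expect_lt(max(ph$data), 6 * spec$noise_sd)
  # independent per-frame sensor noise carries no persistent texture, so no
  # candidate survives the multi-window consensus downstream
  ser <- generate_series(spec, iops = c(5, 10), strain_law = c(0.05, -0.02))
  cfg <- tracker_config(mode = "2d", dedup_radius = 12)
  expect_error(track_series(ser, cfg), "no trajectory survived|no trackable")
})

test_that("bright voxels are confined to the vein-wall shell", {
  spec <- small_spec(seed = 2L)
  ph <- generate_phantom(spec)
  d <- dim(ph$data)
  bright <- which(ph$data > 0.25 * max(ph$data), arr.ind = TRUE)
  # straight tube along X through the volume centre: radial distance in (y, z)
  cy <- (d[2] - 1) / 2 * ph$spacing[2]
  cz <- (d[3] - 1) / 2 * ph$spacing[3]
  rad <- sqrt(((bright[, 2] - 1) * ph$spacing[2] - cy)^2 +
              ((bright[, 3] - 1) * ph$spacing[3] - cz)^2)
  # within the wall band, allowing the anisotropic blur to smear outwards
  tol <- spec$wall_thickness / 2 + 2 * max(spec$blur_sigma)
  expect_gt(mean(abs(rad - spec$vein_radius) <= tol), 0.99)
})

test_that("phantom errors when the vein exits the volume", {
  expect_error(
    phantom_spec(shape = c(64L, 64L, 24L), spacing = c(4, 4, 13),
                 vein_centerline = rbind(c(0, 20, 150), c(252, 20, 150))),
    "exits the volume")
})

test_that("identity and integer-translation warps are exact", {
  spec <- small_spec(shape = c(48L, 48L, 16L))
  ph <- generate_phantom(spec)
  w_id <- deform_volume(ph, deformation_affine(diag(3)))
  expect_equal(w_id$data, ph$data, tolerance = 0)
  shift_vox <- c(3L, 2L, 0L)
  mdl <- deformation_affine(diag(3), shift = shift_vox * ph$spacing)
  w <- deform_volume(ph, mdl)
  d <- dim(ph$data)
  expect_equal(w$data[(1 + 3):d[1], (1 + 2):d[2], ],
               ph$data[1:(d[1] - 3), 1:(d[2] - 2), ], tolerance = 0)
})

test_that("a 9.53% uniaxial stretch moves feature centroids to 1.0953 x", {
  spec <- small_spec(seed = 9L, shape = c(96L, 96L, 40L), density = 1)
  ph <- generate_phantom(spec)
  lam <- 1.0953
  w <- deform_volume(ph, deformation_affine(diag(c(lam, 1, 1))))
  feats <- attr(ph, "features")
  sp <- ph$spacing
  d <- dim(ph$data)
  nn <- as.matrix(dist(feats))
  diag(nn) <- Inf
  isolated <- apply(nn, 1, min) > 80  # exclude overlapping blob pairs
  checked <- 0L
  for (f in which(isolated)) {
    target <- feats[f, ] * c(lam, 1, 1)
    cv <- round(target / sp)
    if (any(cv < 6) || any(cv > d - 7)) next
    ii <- (cv[1] - 4):(cv[1] + 4); jj <- (cv[2] - 4):(cv[2] + 4)
    kk <- max(cv[3] - 5, 0):min(cv[3] + 5, d[3] - 1)
    blk <- w$data[ii + 1, jj + 1, kk + 1]
    if (max(blk) < 0.2) next
    blk <- pmax(blk - 0.05, 0)  # suppress background noise in the centroid
    cx <- sum(blk * rep(ii, times = length(jj) * length(kk))) / sum(blk) * sp[1]
    expect_lt(abs(cx - target[1]), sp[1])
    checked <- checked + 1L
  }
  expect_gte(checked, 4L)
})

test_that("analytic strain oracle matches closed forms", {
  pts <- matrix(runif(15, 0, 400), 5, 3)
  id <- deformation_affine(diag(3))
  for (s in ground_truth_strain(id, pts, "log"))
    expect_equal(s, matrix(0, 3, 3), tolerance = 1e-15)
  st <- deformation_affine(diag(c(1.0953, 1, 1)))
  for (s in ground_truth_strain(st, pts, "log")) {
    expect_equal(s[1, 1], log(1.0953), tolerance = 1e-12)  # = 0.0910280
    expect_equal(sum(abs(s)) - abs(s[1, 1]), 0, tolerance = 1e-12)
  }
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  for (s in ground_truth_strain(deformation_affine(R), pts, "log"))
    expect_equal(s, matrix(0, 3, 3), tolerance = 1e-12)
  # small-strain measure picks up the symmetric displacement gradient
  for (s in ground_truth_strain(st, pts, "small"))
    expect_equal(s[1, 1], 0.0953, tolerance = 1e-12)
})

test_that("warping by composed models agrees with sequential warps", {
  spec <- small_spec(seed = 4L, shape = c(64L, 64L, 24L))
  spec$noise_sd <- 0  # smooth texture
  ph <- generate_phantom(spec)
  A <- deformation_affine(diag(c(1.03, 1, 1)))
  B <- deformation_affine(diag(c(1, 1.02, 1)), shift = c(5, 0, 0))
  seq_w <- deform_volume(deform_volume(ph, A), B)
  comp_w <- deform_volume(ph, deformation_compose(A, B))
  rng <- diff(range(ph$data))
  expect_lt(mean(abs(seq_w$data - comp_w$data)), 0.02 * rng)
})

test_that("generate_series stores the exact strain law and IOPs", {
  spec <- small_spec(shape = c(48L, 48L, 16L))
  # single frame: reference only, zero ground truth
  s1 <- generate_series(spec, iops = 5, strain_law = c(0.05, -0.02))
  expect_length(s1$frames, 1L)
  expect_equal(attr(s1, "ground_truth")$strain, 0)
  # a = 0: every frame equals the reference (up to per-frame sensor noise,
  # removed here to make the identity exact)
  spec0 <- spec; spec0$noise_sd <- 0
  s0 <- generate_series(spec0, iops = c(5, 10, 15), strain_law = c(0, -0.02))
  expect_equal(s0$frames[[2]]$data, s0$frames[[1]]$data, tolerance = 1e-12)
  # law evaluated exactly in the stored ground truth
  iops <- c(5, 10, 15, 20)
  s <- generate_series(spec, iops = iops, strain_law = c(0.05, -0.02))
  expect_equal(attr(s, "ground_truth")$strain,
               0.05 * log(iops) - 0.05 * log(5), tolerance = 1e-12)
  expect_equal(s$iops, iops)
  expect_error(generate_series(spec, c(5, 10), c(-2, 0), measure = "small"),
               "non-positive stretch")
})

test_that("non-invertible deformations are rejected", {
  spec <- small_spec(shape = c(48L, 48L, 16L))
  ph <- generate_phantom(spec)
  expect_error(deformation_affine(diag(c(-1, 1, 1))), "positive determinant")
  expect_error(deformation_sinusoidal(amplitude = 200, wavelength = 100,
                                      direction = c(0, 1, 0), normal = c(0, 1, 0)),
               "fold")
})

test_that("radial and sinusoidal models invert and report exact gradients", {
  pts <- matrix(runif(30, 50, 300), 10, 3)
  rad <- deformation_radial(axis_point = c(0, 180, 150), axis_dir = c(1, 0, 0),
                            rate = 0.08)
  expect_equal(rad$inverse(rad$evaluate(pts)), pts, tolerance = 1e-10)
  sin_m <- deformation_sinusoidal(amplitude = 6, wavelength = 300,
                                  direction = c(1, 0, 0), normal = c(0, 1, 0))
  expect_equal(sin_m$inverse(sin_m$evaluate(pts)), pts, tolerance = 1e-8)
  # finite-difference check of one gradient
  h <- 1e-5
  p <- pts[1, , drop = FALSE]
  G <- sin_m$gradient(p)[[1]]
  for (a in 1:3) {
    dp <- p; dp[a] <- dp[a] + h
    expect_equal(as.numeric((sin_m$evaluate(dp) - sin_m$evaluate(p)) / h),
                 as.numeric(G[, a]), tolerance = 1e-4)
  }
})
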