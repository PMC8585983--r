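test_that("zncc matches hand-computed Pearson values", {
  a <- array(c(1, 2, 3, 4), c(2, 2, 1))
  b <- array(c(1, 2, 4, 3), c(2, 2, 1))
  expect_equal(as.numeric(zncc(a, b)), 0.8, tolerance = 1e-12)
  x <- array(runif(27), c(3, 3, 3))
  expect_equal(as.numeric(zncc(x, x)), 1, tolerance = 1e-12)
  neg <- 2 * mean(x) - x  # reflection about the mean
  expect_equal(as.numeric(zncc(x, neg)), -1, tolerance = 1e-12)
  k <- array(1, c(3, 3, 3))
  z <- zncc(k, k)
  expect_equal(as.numeric(z), 0)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("candidate detection applies the neighbour-contrast rule", {
  cfg <- tracker_config(lateral_windows = c(5L, 7L, 9L),
                        axial_windows = c(3L, 3L, 5L),
                        search_lateral = 7L, search_axial = 3L)
  base <- array(1, c(24, 24, 12))
  vol_const <- image_volume(base, c(4, 4, 13))
  expect_equal(nrow(detect_candidates(vol_const, cfg)), 0L)

  hot <- base; hot[13, 12, 6] <- 2.0   # contrast 1.0 >= 0.55
  cand <- detect_candidates(image_volume(hot, c(4, 4, 13)), cfg)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand[1, ], c(12L, 11L, 5L))  # 0-based
  expect_equal(attr(cand, "contrast"), 1.0)

  warm <- base; warm[13, 12, 6] <- 1.5  # contrast 0.5 < 0.55
  expect_equal(nrow(detect_candidates(image_volume(warm, c(4, 4, 13)), cfg)), 0L)

  # candidates too close to the border for the largest window are excluded
  edge <- base; edge[2, 12, 6] <- 2.0
  expect_equal(nrow(detect_candidates(image_volume(edge, c(4, 4, 13)), cfg)), 0L)
})

test_that("search_best_match finds exact matches and handles degeneracy", {
  set.seed(8)
  ref <- image_volume(array(runif(40 * 40 * 16), c(40, 40, 16)), c(4, 4, 13))
  loc <- c(20L, 19L, 8L)
  r <- search_best_match(ref, ref, loc, window = c(9, 9, 5), search = c(11, 11, 5))
  expect_equal(r$loc, loc)
  expect_equal(r$corr, 1, tolerance = 1e-10)

  shifted <- ref
  shifted$data <- array(0, dim(ref$data))
  shifted$data[4:40, 3:40, ] <- ref$data[1:37, 1:38, ]
  r2 <- search_best_match(ref, shifted, loc, c(9, 9, 5), c(11, 11, 5))
  expect_equal(r2$displacement, c(3, 2, 0))
  expect_equal(r2$corr, 1, tolerance = 1e-10)

  flat <- ref; flat$data[] <- 1
  r3 <- search_best_match(flat, ref, loc, c(9, 9, 5), c(11, 11, 5))
  expect_equal(r3$status, "degenerate")
})

test_that("correlation ties break towards the smallest displacement", {
  # periodic texture: perfect matches at displacements 0 and +-period
  motif <- matrix(runif(25), 5, 5)
  img <- matrix(0, 45, 45)
  for (i in 0:8) for (j in 0:8) img[i * 5 + 1:5, j * 5 + 1:5] <- motif
  vol <- image_volume(array(img, c(45, 45, 1)), c(4, 4, 1))
  r <- search_best_match(vol, vol, c(22L, 22L, 0L), c(9, 9, 1), c(21, 21, 1))
  expect_equal(r$displacement, c(0, 0, 0))
  expect_equal(r$corr, 1, tolerance = 1e-10)
})

test_that("track_step accepts consistent windows and rejects split consensus", {
  set.seed(10)
  cfg <- tracker_config(lateral_windows = c(9L, 13L, 17L),
                        axial_windows = c(5L, 5L, 7L),
                        search_lateral = 13L, search_axial = 5L)
  ref <- image_volume(array(runif(48 * 48 * 16), c(48, 48, 16)), c(4, 4, 13))
  loc <- c(24L, 24L, 8L)
  r <- track_step(ref, ref, loc, cfg)
  expect_true(r$accepted)
  expect_equal(r$loc, loc)

  shifted <- ref
  shifted$data <- array(0, dim(ref$data))
  shifted$data[4:48, 3:48, ] <- ref$data[1:45, 1:46, ]
  r2 <- track_step(ref, shifted, loc, cfg)
  expect_true(r2$accepted)
  expect_equal(r2$loc, loc + c(3, 2, 0))

  # scene torn around the point: the small window's content moves +4 voxels
  # while the larger windows' context stays put -> window sizes disagree
  torn <- ref
  blk <- ref$data[(25 - 4):(25 + 4), (25 - 4):(25 + 4), (9 - 2):(9 + 2)]
  torn$data[(25 - 4):(25 + 4) + 4, (25 - 4):(25 + 4), (9 - 2):(9 + 2)] <- blk
  torn$data[(25 - 4):(25 - 1), (25 - 4):(25 + 4), (9 - 2):(9 + 2)] <- 0
  r3 <- track_step(ref, torn, loc, cfg)
  expect_false(r3$accepted)
  expect_equal(r3$reason, "consensus")
})

test_that("self-tracking returns zero displacement for every accepted point", {
  spec <- small_spec(seed = 12L, shape = c(72L, 72L, 28L))
  ph <- generate_phantom(spec)
  ser <- frame_series(list(ph, ph, ph), iops = rep(NA_real_, 3))
  ts <- track_series(ser, small_tracker())
  acc <- Filter(function(t) t$status == "accepted", ts$trajectories)
  expect_equal(length(acc), length(ts$trajectories))  # all survive
  for (t in acc) {
    expect_equal(t$loc[2, ], t$loc[1, ])
    expect_equal(t$loc[3, ], t$loc[1, ])
  }
})

test_that("integer translation of all frames shifts trajectories exactly", {
  spec <- small_spec(seed = 13L)
  ph <- generate_phantom(spec)
  shift <- c(4L, -3L, 1L)
  shifted <- deform_volume(ph, deformation_affine(diag(3),
                                                  shift = shift * ph$spacing))
  ser <- frame_series(list(ph, shifted), iops = rep(NA_real_, 2))
  cfg <- small_tracker()
  ts <- track_series(ser, cfg)
  acc <- Filter(function(t) t$status == "accepted", ts$trajectories)
  # equivariance holds where windows and search stay clear of the
  # zero-filled band the translation drags in at the volume border
  d <- dim(ph$data)
  margin <- c(21, 21, 9) + abs(shift)
  inside <- Filter(function(t)
    all(t$loc[1, ] >= margin) && all(t$loc[1, ] <= d - 1 - margin), acc)
  expect_gte(length(inside), 10L)
  for (t in inside) expect_equal(t$loc[2, ], t$loc[1, ] + shift)
})

test_that("a blank frame rejects every trajectory at that frame", {
  spec <- small_spec(seed = 14L, shape = c(64L, 64L, 24L))
  ph <- generate_phantom(spec)
  blank <- ph; blank$data[] <- 0
  ser <- frame_series(list(ph, blank), iops = rep(NA_real_, 2))
  expect_error(track_series(ser, small_tracker()), "no trajectory survived")
})

test_that("raising the agreement tolerance never loses accepted points", {
  spec <- small_spec(seed = 15L, shape = c(72L, 72L, 28L))
  spec$noise_sd <- 0.05
  ph <- generate_phantom(spec)
  warped <- deform_volume(ph, deformation_affine(diag(c(1.025, 1, 1))))
  ser <- frame_series(list(ph, warped), iops = rep(NA_real_, 2))
  n_acc <- sapply(c(0, 1, 2, 4), function(tol) {
    ts <- track_series(ser, small_tracker(agreement_tol = tol))
    length(Filter(function(t) t$status == "accepted", ts$trajectories))
  })
  expect_true(all(diff(n_acc) >= 0))
})

test_that("tracked endpoints match a smooth deformation to <= 1 voxel RMS", {
  # per-step feature displacements of the order 15-20 um, as in the
  # acquisitions the tracker is designed for
  spec <- small_spec(seed = 16L)
  ph <- generate_phantom(spec)
  lam_tot <- exp(0.0953)
  frames <- list(ph)
  for (i in 1:4)
    frames[[i + 1]] <- deform_volume(ph, deformation_affine(
      diag(c(lam_tot^(i / 4), 1, 1))))
  ser <- frame_series(frames, iops = rep(NA_real_, 5))
  ts <- track_series(ser, small_tracker())
  acc <- Filter(function(t) t$status == "accepted", ts$trajectories)
  expect_gt(length(acc) / length(ts$trajectories), 0.9)
  err <- t(vapply(acc, function(t) {
    x0 <- t$loc[1, ] * ph$spacing
    xt <- t$loc[5, ] * ph$spacing
    (xt - c(lam_tot * x0[1], x0[2], x0[3])) / ph$spacing
  }, numeric(3)))
  rms <- sqrt(colMeans(err^2))
  expect_lt(rms[1], 1)
  expect_lt(rms[2], 1)
})
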