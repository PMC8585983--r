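test_that("element deformation gradients match closed forms", {
  expect_equal(element_F(unit_tet, unit_tet), diag(3), tolerance = 1e-14)
  stretched <- unit_tet %*% diag(c(1.0953, 1, 1))
  expect_equal(element_F(unit_tet, stretched), diag(c(1.0953, 1, 1)),
               tolerance = 1e-14)
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))  # 90 degrees about Z
  rotated <- unit_tet %*% t(R)
  Fm <- element_F(unit_tet, rotated)
  expect_equal(Fm, R, tolerance = 1e-14)
  expect_equal(det(Fm), 1, tolerance = 1e-14)
  flat <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 0, 1))
  expect_error(element_F(flat, flat), "degenerate")
})

test_that("strain measures behave as expected under stretch and rotation", {
  expect_equal(strain_from_F(diag(3), "log"), matrix(0, 3, 3))
  expect_equal(strain_from_F(diag(3), "small"), matrix(0, 3, 3))
  eps <- strain_from_F(diag(c(1.0953, 1, 1)), "log")
  expect_equal(eps[1, 1], log(1.0953), tolerance = 1e-12)  # = 0.0910280
  expect_equal(eps[2, 2], 0); expect_equal(eps[3, 3], 0)
  th <- 0.5
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  # the true (log) measure is rotation-invariant; the linearised measure
  # picks up spurious strain under finite rotation
  expect_equal(strain_from_F(R, "log"), matrix(0, 3, 3), tolerance = 1e-12)
  expect_gt(max(abs(strain_from_F(R, "small"))), 0.1)
  expect_error(strain_from_F(diag(c(-1, 1, 1))), "det F > 0")
})

test_that("affine nodal motions give the exact uniform strain field", {
  set.seed(41)
  pts <- matrix(runif(3 * 25, 0, 400), 25, 3)
  A <- diag(3) + matrix(rnorm(9, 0, 0.03), 3, 3)  # random affine, det > 0
  stopifnot(det(A) > 0)
  disp <- array(0, c(2, 25, 3))
  disp[2, , ] <- pts %*% t(A) - pts
  mesh <- strain_mesh_from_points(pts, disp, mode = "3d")
  field <- field_strain(mesh, 2, measure = "log")
  truth <- veinstrain:::pack_tensor(strain_from_F(A, "log"), "3d")
  for (e in seq_len(nrow(field$eps)))
    expect_equal(unname(field$eps[e, ]), truth, tolerance = 1e-12)
  # the weighted average of a uniform field equals the uniform value
  expect_equal(as.numeric(weighted_average_strain(field, mesh)), truth,
               tolerance = 1e-12)
  # rigid translation produces the zero field
  disp_t <- array(0, c(2, 25, 3))
  disp_t[2, , ] <- matrix(c(7, -3, 11), 25, 3, byrow = TRUE)
  mesh_t <- strain_mesh_from_points(pts, disp_t, mode = "3d")
  expect_equal(max(abs(field_strain(mesh_t, 2)$eps)), 0, tolerance = 1e-12)
  # reference frame is identically zero
  expect_equal(max(abs(field_strain(mesh, 1)$eps)), 0)
})

test_that("log-strain fields are objective under superposed rotation", {
  set.seed(42)
  pts <- matrix(runif(3 * 20, 0, 300), 20, 3)
  A <- diag(3) + matrix(rnorm(9, 0, 0.04), 3, 3)
  stopifnot(det(A) > 0)
  th <- 0.4
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  disp <- array(0, c(2, 20, 3)); disp[2, , ] <- pts %*% t(A) - pts
  disp_r <- array(0, c(2, 20, 3)); disp_r[2, , ] <- pts %*% t(R %*% A) - pts
  m1 <- strain_mesh_from_points(pts, disp, mode = "3d")
  m2 <- strain_mesh_from_points(pts, disp_r, mode = "3d")
  f1 <- field_strain(m1, 2, "log"); f2 <- field_strain(m2, 2, "log")
  expect_lt(max(abs(f1$eps - f2$eps)), 1e-10)
})

test_that("nodal strains average the tensors of incident elements", {
  # two tets sharing a face
  pts <- rbind(unit_tet * 100, c(100, 100, 100))
  mesh <- strain_mesh_from_points(pts, array(0, c(2, 5, 3)), mode = "3d")
  expect_equal(nrow(mesh$elements), 2L)
  field <- field_strain(mesh, 2)
  field$eps[1, "XX"] <- 0.1
  field$eps[2, "XX"] <- 0.3
  ns <- nodal_strains(mesh, field)
  shared <- intersect(mesh$elements[1, ], mesh$elements[2, ])
  only1 <- setdiff(mesh$elements[1, ], mesh$elements[2, ])
  expect_equal(unname(ns[shared, "XX"]), rep(0.2, length(shared)))
  expect_equal(unname(ns[only1, "XX"]), rep(0.1, length(only1)))
  # a uniform field yields the uniform value at every node
  field$eps[, "XX"] <- 0.25
  expect_equal(unname(nodal_strains(mesh, field)[, "XX"]), rep(0.25, 5))
})

test_that("tensor rotation follows R eps R' with invariant trace", {
  eps <- matrix(c(0.05, 0.01, 0.00,
                  0.01, -0.02, 0.03,
                  0.00, 0.03, 0.08), 3, 3, byrow = TRUE)
  expect_equal(rotate_strain(eps, diag(3)), eps)
  R90 <- rotation_about_x(pi / 2)
  out <- rotate_strain(eps, R90)
  # 90 degrees about X exchanges YY and ZZ and negates the YZ-coupled terms
  expect_equal(out[2, 2], eps[3, 3], tolerance = 1e-12)
  expect_equal(out[3, 3], eps[2, 2], tolerance = 1e-12)
  expect_equal(out[2, 3], -eps[2, 3], tolerance = 1e-12)
  expect_equal(out[1, 2], -eps[1, 3], tolerance = 1e-12)
  set.seed(43)
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    R <- rotation_about_x(th[1]) %*%
      rbind(c(cos(th[2]), -sin(th[2]), 0), c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    expect_equal(sum(diag(rotate_strain(eps, R))), sum(diag(eps)),
                 tolerance = 1e-12)
  }
  expect_error(rotate_strain(eps, matrix(2 * diag(3), 3)), "orthonormal")
})

test_that("weighted averages respect the reference measures", {
  pts <- rbind(unit_tet * 100, c(100, 100, 100))
  mesh <- strain_mesh_from_points(pts, array(0, c(2, 5, 3)), mode = "3d")
  field <- field_strain(mesh, 2)
  # single element: the average is its tensor
  mesh1 <- strain_mesh_from_points(unit_tet * 100, array(0, c(2, 4, 3)), "3d")
  f1 <- field_strain(mesh1, 2)
  f1$eps[1, "XX"] <- 0.42
  expect_equal(unname(weighted_average_strain(f1, mesh1)["XX"]), 0.42)
  # volumes in ratio 1:3 with strains 0.1 and 0.2 -> 0.175
  field$eps[, "XX"] <- c(0.1, 0.2)
  mesh$ref_measure <- c(1, 3)
  avg <- weighted_average_strain(field, mesh)
  expect_equal(unname(avg["XX"]), 0.175, tolerance = 1e-14)
  # the average always lies within the element range, per component
  set.seed(44)
  field$eps[] <- rnorm(length(field$eps), 0, 0.05)
  mesh$ref_measure <- runif(2, 0.1, 5)
  avg2 <- weighted_average_strain(field, mesh)
  for (cc in colnames(field$eps)) {
    expect_gte(avg2[cc], min(field$eps[, cc]))
    expect_lte(avg2[cc], max(field$eps[, cc]))
  }
})

test_that("inter-structure strain recovers the separation stretch", {
  # nodes on two parallel vein walls bounding a strip of sclera
  set.seed(45)
  n_side <- 12
  x <- runif(2 * n_side, 0, 600)
  y <- c(rep(0, n_side), rep(350, n_side)) + runif(2 * n_side, -4, 4)
  z <- runif(2 * n_side, 0, 40)
  pts <- cbind(x, y, z)
  labels <- rep(c("vein1", "vein2"), each = n_side)
  # both structures translated rigidly together: zero field
  disp0 <- array(0, c(2, 2 * n_side, 3))
  disp0[2, , 2] <- 25
  m0 <- strain_mesh_from_points(pts, disp0, mode = "3d", node_label = labels)
  f0 <- inter_vein_strain(m0, frames = 2)
  expect_lt(max(abs(f0[[1]]$eps)), 1e-12)
  # separation grows 10%: eps_YY = ln(1.1) under the log measure
  disp1 <- array(0, c(2, 2 * n_side, 3))
  disp1[2, , 2] <- 0.1 * pts[, 2]
  m1 <- strain_mesh_from_points(pts, disp1, mode = "3d", node_label = labels)
  f1 <- inter_vein_strain(m1, frames = 2)
  expect_equal(unname(weighted_average_strain(f1[[1]], m1)["YY"]), log(1.1),
               tolerance = 1e-10)
  # reference frame zero; single-structure meshes are refused
  expect_lt(max(abs(inter_vein_strain(m1, frames = 1)[[1]]$eps)), 1e-15)
  m_bad <- strain_mesh_from_points(pts, disp1, mode = "3d",
                                   node_label = rep("vein1", 2 * n_side))
  expect_error(inter_vein_strain(m_bad), "two structures")
})
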