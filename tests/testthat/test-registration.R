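test_that("rigid transforms validate, compose and invert", {
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "improper")
  a <- rigid_transform(rotation_about(c(1, 2, 3), 40), c(1, -2, 3))
  b <- rigid_transform(rotation_about(c(0, 1, 0), -25), c(-4, 0, 2))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_transform(compose_transform(a, b), p),
               apply_transform(a, apply_transform(b, p)), tolerance = 1e-12)
  expect_lt(max(abs(apply_transform(invert_transform(a),
                                    apply_transform(a, p)) - p)), 1e-9)
})

test_that("landmark alignment recovers exact rigid displacements", {
  fid <- rbind(c(0, 0, -12), c(10, 0, 8), c(-5, 8.7, 8), c(-5, -8.7, 8))
  lm0 <- landmark_align(fid, fid)
  expect_lt(lm0$rms_mm, 1e-12)
  expect_lt(max(abs(lm0$transform$rotation - diag(3))), 1e-9)

  tr <- rigid_transform(rotation_about(c(0, 0, 1), 30), c(5, -3, 2))
  lm <- landmark_align(fid, apply_transform(tr, fid))
  expect_lt(lm$rms_mm, 1e-9)
  # recovered transform is the inverse of the applied one
  rt <- compose_transform(lm$transform, tr)
  expect_lt(max(abs(rt$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(rt$translation)), 1e-9)

  # reflected fiducials: det +1 enforced, residual strictly positive
  lmr <- landmark_align(fid, fid %*% diag(c(-1, 1, 1)))
  expect_equal(det(lmr$transform$rotation), 1, tolerance = 1e-9)
  expect_gt(lmr$rms_mm, 0.1)

  expect_error(landmark_align(fid[1:2, ], fid[1:2, ]), "at least 3")
  expect_error(landmark_align(fid, fid[1:3, ]), "differ")
  coll <- cbind(1:4, 2 * (1:4), 3 * (1:4))
  expect_error(landmark_align(coll, coll), "collinear")
})

test_that("ICP refines a perturbed cloud back onto the mesh", {
  mesh <- small_shell_mesh()
  set.seed(21)
  pts <- mesh$vertices[sample(nrow(mesh$vertices), 120), ]
  tr <- rigid_transform(rotation_about(c(1, 1, 0), 20), c(6, -4, 3))
  moved <- apply_transform(tr, pts)
  icp <- icp_refine(moved, mesh, init = rigid_transform(), conv_tol = 1e-5)
  expect_lt(icp$rms_mm, 0.5)
  expect_true(all(diff(icp$rms_trace) <= 1e-12))
  # already-optimal init stays put
  icp2 <- icp_refine(pts, mesh, init = rigid_transform())
  expect_lt(icp2$rms_mm, 1e-6)
  expect_lt(max(abs(icp2$transform$rotation - diag(3))), 1e-4)
})

test_that("point-to-node mapping honours the radius and matches brute force", {
  mesh <- small_shell_mesh()
  # a point exactly on a node
  p0 <- mesh$vertices[7, , drop = FALSE]
  m0 <- map_points_to_nodes(p0, mesh)
  expect_equal(m0$node_id, 7L)
  expect_equal(m0$assign_dist_mm, 0)
  # a point far from every node is unassigned
  far <- matrix(c(0, 0, 0), 1)           # cavity centre, ~12 mm from surface
  mf <- map_points_to_nodes(far, mesh)
  expect_true(is.na(mf$node_id))

  set.seed(22)
  q <- mesh$vertices[sample(nrow(mesh$vertices), 400), ] +
    matrix(rnorm(1200, 0, 0.7), ncol = 3)
  got <- map_points_to_nodes(q, mesh, radius = 1.0)
  want <- nn_brute_oracle(q, mesh$vertices)
  expect_equal(ifelse(want$dist <= 1.0, want$index, NA_integer_), got$node_id)
})
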