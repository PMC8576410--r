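test_that("slab phantom builds the requested wall with correct truth", {
  ph <- small_slab()$ph
  lab <- tissue_labels()
  d <- dim(ph$label$data)
  # wall fills the full lateral extent, blood below, background above
  expect_true(all(ph$label$data %in% lab))
  counts <- table(factor(ph$label$data, levels = lab))
  expect_gt(counts[["2"]], 0)
  expect_gt(counts[["1"]], 0)
  expect_true(all(ph$truth$endo_truth$true_thickness == 10))
  # each lateral column holds the same number of wall voxels
  wall <- array(ph$label$data %in% wall_labels(), d)
  col_counts <- apply(wall, c(1, 2), sum)
  expect_true(all(col_counts == col_counts[1, 1]))
  # voxelised extent within half a voxel of the requested thickness
  expect_lt(abs(col_counts[1, 1] * 1.2 - 10), 0.61)
})

test_that("shell phantom has constant true thickness at every endo node", {
  ph <- small_shell()$ph
  expect_true(all(abs(ph$truth$endo_truth$true_thickness - 6) < 1e-9))
  r <- sqrt(rowSums(as.matrix(ph$truth$endo_truth[, c("x", "y", "z")])^2))
  expect_true(all(r >= 12 - 1e-9 & r < 13.3))   # endo voxels hug the surface
})

test_that("scar patch occupies the inner fraction of the wall (voxel audit)", {
  ph <- phantom_volume(phantom_spec(
    "slab", slab_thickness = 10, slab_extent = c(36, 36), seed = 3L,
    scar_patches = list(scar_patch(c(0, 0), 10, transmural_fraction = 0.5,
                                   ht_rim_width = 0))))
  lab <- tissue_labels()
  d <- dim(ph$label$data)
  wall <- array(ph$label$data %in% wall_labels(), d)
  scar <- ph$label$data == lab[["scar"]]
  # audit columns under the patch centre: scar depth fraction ~ 0.5
  ctr <- round(d[1:2] / 2)
  fr <- c()
  for (di in -2:2) for (dj in -2:2) {
    i <- ctr[1] + di; j <- ctr[2] + dj
    nw <- sum(wall[i, j, ]); ns <- sum(scar[i, j, ])
    expect_gt(nw, 0)
    fr <- c(fr, ns / nw)
    # scar voxels are the innermost ones (contiguous from the endo side)
    ks <- which(scar[i, j, ]); kw <- which(wall[i, j, ])
    expect_identical(ks, kw[seq_along(ks)])
  }
  # within one voxel-depth of the requested fraction
  expect_true(all(abs(fr - 0.5) <= 1.2 / 10 + 1e-9))
})

test_that("HT rim wraps the scar and truth fractions are consistent", {
  ph <- phantom_volume(phantom_spec(
    "shell", r_endo = 12, r_epi = 18, seed = 5L,
    scar_patches = list(scar_patch(c(1, 0, 0), 35, 0.5, ht_rim_width = 2))))
  lab <- tissue_labels()
  ht_idx <- which(ph$label$data == lab[["ht"]], arr.ind = TRUE)
  sc_idx <- which(ph$label$data == lab[["scar"]], arr.ind = TRUE)
  expect_gt(nrow(ht_idx), 0)
  ht_pos <- voxel_to_world(ph$label, ht_idx)
  sc_pos <- voxel_to_world(ph$label, sc_idx)
  nn <- nn_brute_oracle(ht_pos[seq_len(min(200, nrow(ht_pos))), , drop = FALSE],
                        sc_pos)
  expect_true(all(nn$dist <= 2 + 1e-9))
  et <- ph$truth$endo_truth
  core <- et$true_scar_frac > 0
  expect_true(any(core))
  expect_true(all(et$true_scar_frac[core] == 0.5))
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec("slab", slab_thickness = 6, slab_extent = c(14, 14),
                       seed = 99L)
  a <- phantom_volume(spec); b <- phantom_volume(spec)
  expect_identical(a$label$data, b$label$data)
  expect_identical(a$intensity$data, b$intensity$data)
  expect_identical(a$truth$endo_truth, b$truth$endo_truth)
})

test_that("invalid patches are rejected with a diagnostic", {
  expect_error(phantom_spec("slab", slab_extent = c(20, 20),
                            scar_patches = list(scar_patch(c(0, 0), 15))),
               "exceeds")
  expect_error(scar_patch(c(0, 0), 5, transmural_fraction = 1.2))
  expect_error(scar_patch(c(0, 0), 5, ht_rim_width = -1))
})

test_that("EAM export lies on the surface and restores under the inverse transform", {
  sh <- small_shell()
  mesh <- small_shell_mesh()
  ph2 <- phantom_volume(phantom_spec(
    "shell", r_endo = 12, r_epi = 18, seed = 11L,
    scar_patches = list(scar_patch(c(1, 0, 0), 35, 0.5, 2))))
  # identity transform, zero noise: exported positions are mesh vertices
  eam0 <- phantom_eam_points(ph2$truth, mesh, rigid_transform(),
                             n_diastolic = 20, n_normal = 20, noise_sd = 0,
                             seed = 4L)
  nn <- nearest_dist(as.matrix(eam0[, c("x", "y", "z")]), mesh$vertices)
  expect_lt(max(nn$dist), 1e-5)
  expect_setequal(eam0$category, c("diastolic", "normal", "fiducial"))
  expect_equal(sum(eam0$category == "fiducial"), 4L)

  # known rotation + translation: inverse restores within noise
  tr <- rigid_transform(rotation_about(c(0, 0, 1), 15), c(5, -3, 2))
  eam1 <- phantom_eam_points(ph2$truth, mesh, tr, n_diastolic = 20,
                             n_normal = 20, noise_sd = 0.1, seed = 4L)
  back <- apply_transform(invert_transform(tr),
                          as.matrix(eam1[, c("x", "y", "z")]))
  ref <- as.matrix(eam0[, c("x", "y", "z")])
  expect_lt(max(sqrt(rowSums((back - ref)^2))), 0.1 * 4.5)

  # determinism
  eam2 <- phantom_eam_points(ph2$truth, mesh, tr, n_diastolic = 20,
                             n_normal = 20, noise_sd = 0.1, seed = 4L)
  expect_identical(eam1, eam2)
})

test_that("activation phantom constructs the promised wavefronts", {
  am <- phantom_activation_map(width = 30, depth = 40, seed = 8L)
  p <- am$points
  d <- as.matrix(stats::dist(cbind(p$x, p$y, p$z)))
  dtm <- abs(outer(p$time_ms, p$time_ms, `-`))
  adj <- d <= 5 & upper.tri(d)
  same_side <- outer(p$y <= 20, p$y <= 20, `==`)
  # no block within a single wavefront
  expect_lt(max(dtm[adj & same_side]), 15)
  # ~offset across the line for immediately adjacent cross pairs
  near_line <- outer(abs(p$y - 20) < 3, abs(p$y - 20) < 3, `&`)
  cross <- adj & !same_side & near_line
  expect_gt(min(dtm[cross]), 30)
  expect_equal(am$truth$block_length_mm, 30)
  # uniform wavefront: monotone in y, no gap above threshold anywhere
  am0 <- phantom_activation_map(width = 30, depth = 40, block = FALSE, seed = 8L)
  expect_equal(am0$truth$n_regions, 0L)
  d0 <- as.matrix(stats::dist(cbind(am0$points$x, am0$points$y, am0$points$z)))
  dt0 <- abs(outer(am0$points$time_ms, am0$points$time_ms, `-`))
  expect_lt(max(dt0[d0 <= 5 & upper.tri(d0)]), 15)
})
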