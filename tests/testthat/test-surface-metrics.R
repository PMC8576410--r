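test_that("RBF gradient reproduces constant and linear fields", {
  mesh <- plane_mesh(25, 15)
  gf0 <- rbf_gradient(mesh, rep(7, nrow(mesh$vertices)))
  expect_lt(max(gf0$grad_mag), 1e-6)
  thk <- 3 + 0.4 * mesh$vertices[, 1]
  gf1 <- rbf_gradient(mesh, thk)
  expect_true(all(abs(gf1$grad_mag - 0.4) < 0.004))
  expect_lt(max(abs(gf1$thickness_fit - thk)), 1e-6)
})

test_that("a thickness step localises the gradient maximum (graph FD oracle)", {
  mesh <- plane_mesh(41, 15)
  x <- mesh$vertices[, 1]
  # 10 mm plateau stepping down to 4 mm across x in [18, 22]
  thk <- ifelse(x < 18, 10, ifelse(x > 22, 4, 10 - 6 * (x - 18) / 4))
  gf <- rbf_gradient(mesh, thk, smoothing = 1e-3)
  fd <- graph_fd_oracle(mesh, thk)
  in_step <- x >= 17 & x <= 23
  # both methods put their largest gradients inside the step band
  expect_true(x[which.max(gf$grad_mag)] >= 17 &&
              x[which.max(gf$grad_mag)] <= 23)
  expect_true(x[which.max(fd)] >= 17 && x[which.max(fd)] <= 23)
  expect_gt(median(gf$grad_mag[in_step]), 5 * median(gf$grad_mag[!in_step]))
  # magnitude in the band agrees with the finite-difference slope (1.5)
  expect_lt(abs(max(gf$grad_mag) - max(fd)) / max(fd), 0.25)
})

test_that("steep region extraction is monotone in the threshold", {
  mesh <- plane_mesh(41, 15)
  x <- mesh$vertices[, 1]
  thk <- ifelse(x < 18, 10, ifelse(x > 22, 4, 10 - 6 * (x - 18) / 4))
  gf <- rbf_gradient(mesh, thk, smoothing = 1e-3)
  expect_equal(nrow(steep_regions(gf, steep_threshold = 100)), 0L)
  sizes <- vapply(c(1.2, 0.8, 0.5, 0.2),
                  function(th) nrow(steep_regions(gf, th)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  st <- steep_regions(gf, steep_threshold = 1.0)
  expect_gt(nrow(st), 0)
  expect_equal(length(unique(st$component)), 1L)   # one band at the step
  expect_true(all(x[st$vertex] >= 16 & x[st$vertex] <= 24))
})

test_that("distance_to_set equals the brute-force oracle", {
  set.seed(41)
  q <- matrix(runif(300 * 3, 0, 50), ncol = 3)
  tg <- matrix(runif(120 * 3, 0, 50), ncol = 3)
  got <- distance_to_set(q, tg)
  want <- nn_brute_oracle(q, tg)
  expect_equal(got$dist_mm, want$dist, tolerance = 1e-9)
  expect_equal(got$target_index, want$index)
  # a query inside the target set has distance zero
  got2 <- distance_to_set(tg[5, , drop = FALSE], tg)
  expect_equal(got2$dist_mm, 0)
  expect_equal(got2$target_index, 5L)
})

test_that("distances are monotone in the target and 1-Lipschitz in the query", {
  set.seed(42)
  q <- matrix(runif(150 * 3, 0, 30), ncol = 3)
  tg <- matrix(runif(40 * 3, 0, 30), ncol = 3)
  d1 <- distance_to_set(q, tg)$dist_mm
  d2 <- distance_to_set(q, rbind(tg, c(15, 15, 15)))$dist_mm
  expect_true(all(d2 <= d1 + 1e-12))
  for (rep in 1:50) {
    ij <- sample(nrow(q), 2)
    gap <- sqrt(sum((q[ij[1], ] - q[ij[2], ])^2))
    expect_lte(abs(d1[ij[1]] - d1[ij[2]]), gap + 1e-12)
  }
  expect_warning(d0 <- distance_to_set(q, matrix(numeric(0), 0, 3)), "empty")
  expect_true(all(is.infinite(d0$dist_mm)))
})

test_that("map_to_mesh transfers nearest-node metrics", {
  sh <- small_shell()
  em <- endocardial_map(sh$ph$label, sh$fld)
  mesh <- small_shell_mesh()
  vm <- map_to_mesh(em, mesh)
  expect_equal(nrow(vm), nrow(mesh$vertices))
  expect_lt(max(vm$node_dist_mm), 1.2 * sqrt(3))
  expect_true(all(is.finite(vm$thickness_mm)))
})
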