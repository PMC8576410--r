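# Independent brute-force oracles used to cross-check the package's
# vectorised implementations. Deliberately written in the plainest
# possible style (loops, full enumeration).

# Exact two-tailed Mann-Whitney p by full enumeration of the C(n, nA)
# group assignments of the pooled ranks.
mw_enumeration_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  cmb <- utils::combn(na + nb, na)
  us <- numeric(ncol(cmb))
  for (q in seq_len(ncol(cmb)))
    us[q] <- sum(r[cmb[, q]]) - na * (na + 1) / 2
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  list(u = u_obs, p = min(p, 1))
}

# All-pairs nearest-neighbour search, one query at a time.
nn_brute_oracle <- function(query, target) {
  dist <- numeric(nrow(query)); index <- integer(nrow(query))
  for (i in seq_len(nrow(query))) {
    best <- Inf; bi <- NA_integer_
    for (j in seq_len(nrow(target))) {
      d <- sqrt(sum((query[i, ] - target[j, ])^2))
      if (d < best) { best <- d; bi <- j }
    }
    dist[i] <- best; index[i] <- bi
  }
  list(dist = dist, index = index)
}

# Per-vertex finite-difference gradient bound on the mesh edge graph:
# the largest |delta thickness| / edge length over incident edges.
graph_fd_oracle <- function(mesh, thickness) {
  ed <- vtsubstrate:::mesh_edges(mesh)
  len <- sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                       mesh$vertices[ed[, 2], , drop = FALSE])^2))
  slope <- abs(thickness[ed[, 1]] - thickness[ed[, 2]]) / len
  out <- numeric(nrow(mesh$vertices))
  for (q in seq_len(nrow(ed))) {
    out[ed[q, 1]] <- max(out[ed[q, 1]], slope[q])
    out[ed[q, 2]] <- max(out[ed[q, 2]], slope[q])
  }
  out
}

# Small shared fixtures, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_shell <- function() fixture("small_shell", function() {
  ph <- phantom_volume(phantom_spec("shell", r_endo = 12, r_epi = 18,
                                    seed = 11L))
  fld <- solve_laplace(ph$label)
  list(ph = ph, fld = fld)
})

small_shell_mesh <- function() fixture("small_shell_mesh", function() {
  extract_surface_mesh(small_shell()$ph$label, "endo")
})

small_slab <- function() fixture("small_slab", function() {
  ph <- phantom_volume(phantom_spec("slab", slab_thickness = 10,
                                    slab_extent = c(24, 24), seed = 12L))
  fld <- solve_laplace(ph$label)
  list(ph = ph, fld = fld)
})

# A flat rectangular grid mesh in the z = 0 plane (nx x ny vertices,
# spacing s), for analytic surface-field tests.
plane_mesh <- function(nx = 25, ny = 15, s = 1) {
  g <- expand.grid(x = (seq_len(nx) - 1) * s, y = (seq_len(ny) - 1) * s)
  vid <- function(i, j) (j - 1L) * nx + i
  f <- list(); k <- 0L
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    k <- k + 1L; f[[k]] <- c(vid(i, j), vid(i + 1, j), vid(i, j + 1))
    k <- k + 1L; f[[k]] <- c(vid(i + 1, j), vid(i + 1, j + 1), vid(i, j + 1))
  }
  surface_mesh(cbind(g$x, g$y, 0), do.call(rbind, f))
}

random_rigid <- function(max_deg = 30, max_trans = 10) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  rigid_transform(rotation_about(ax, stats::runif(1, -max_deg, max_deg)),
                  stats::runif(3, -max_trans, max_trans))
}
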