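#' Tag endocardial and epicardial surface voxels
#'
#' The endocardial surface is the set of wall voxels face-adjacent
#' (6-connectivity) to the blood pool; the epicardial surface the set of
#' wall voxels face-adjacent to background. A voxel adjacent to both
#' (wall thinner than two voxels) is assigned to the endocardium, with a
#' warning, so that every endocardial seed is preserved.
#'
#' @param labels A label [vox_volume()].
#' @param base_exclude Optional logical array marking wall voxels whose
#'   background-facing sides must stay untagged (zero-flux), e.g. the cut
#'   base of a truncated ellipsoid.
#' @return List of logical arrays `endo`, `epi` (disjoint).
#' @export
tag_surfaces <- function(labels, base_exclude = NULL) {
  stopifnot(inherits(labels, "vox_volume"))
  lab <- tissue_labels()
  wall <- array(labels$data %in% wall_labels(), dim(labels$data))
  blood <- labels$data == lab[["blood"]]
  bg <- labels$data == lab[["background"]]
  if (!any(wall) || !any(blood))
    stop("label volume must contain both myocardium and blood pool")
  endo <- touches(wall, blood)
  epi <- touches(wall, bg)
  if (!is.null(base_exclude)) epi <- epi & !base_exclude
  both <- endo & epi
  if (any(both)) {
    warning("wall thinner than 2 voxels at ", sum(both),
            " voxel(s); assigning them to the endocardium")
    epi <- epi & !both
  }
  list(endo = endo, epi = epi)
}

# Sub-voxel crossing fraction of the 0.5-level of a smoothed indicator
# between voxel centre c (inside, phi < 0.5) and neighbour nb (outside).
crossing_theta <- function(phi_c, phi_nb, lo = 0.1, hi = 1) {
  th <- (0.5 - phi_c) / (phi_nb - phi_c)
  th[!is.finite(th)] <- 0.5
  pmin(pmax(th, lo), hi)
}

#' Solve the Laplace equation across the myocardial wall
#'
#' Solves `laplacian(u) = 0` on the wall voxels with Dirichlet conditions
#' u = 0 at the endocardial and u = 1 at the epicardial surface and
#' zero-flux (mirror) conditions on untagged wall faces, using a 7-point
#' finite-difference stencil and a direct sparse solve. By default the
#' Dirichlet boundary is placed at sub-voxel accuracy: the surface is
#' taken as the 0.5-level of a Gaussian-smoothed phase indicator and
#' imposed through a Shortley-Weller (cut-cell) stencil, which removes
#' the half-voxel bias of imposing the condition at voxel centres.
#'
#' @param labels A label [vox_volume()].
#' @param tol Maximum acceptable residual of the solved linear system
#'   (scaled by the diagonal); the direct solve is verified against it.
#' @param subvoxel Use sub-voxel (Shortley-Weller) boundary placement;
#'   `FALSE` places the boundary at the voxel face (fixed theta = 0.5).
#' @param sigma Smoothing sd of the surface indicator, in voxels.
#' @param tags Optional result of [tag_surfaces()] (recomputed if NULL).
#' @return A `laplace_field` object: the potential `u` (3D array, NA
#'   outside the wall), surface masks, gradient arrays, smoothed surface
#'   indicators, and the achieved residuals.
#' @export
#' @examples
#' ph <- phantom_volume(phantom_spec("slab", slab_thickness = 6,
#'                                   slab_extent = c(12, 12)))
#' fld <- solve_laplace(ph$label)
#' range(fld$u, na.rm = TRUE)
solve_laplace <- function(labels, tol = 1e-6, subvoxel = TRUE, sigma = 0.8,
                          tags = NULL) {
  stopifnot(inherits(labels, "vox_volume"))
  lab <- tissue_labels()
  L <- labels$data
  d <- dim(L)
  h <- labels$spacing
  wall <- array(L %in% wall_labels(), d)
  blood <- L == lab[["blood"]]
  bg <- L == lab[["background"]]
  if (is.null(tags)) tags <- tag_surfaces(labels)
  endo <- tags$endo; epi <- tags$epi
  if (!any(endo) || !any(epi))
    stop("both endocardial and epicardial surfaces must be tagged")

  phi_endo <- smooth3d(array(as.numeric(blood), d), sigma)
  phi_epi <- smooth3d(array(as.numeric(bg), d), sigma)

  ids <- array(NA_integer_, d)
  widx <- which(wall)
  N <- length(widx)
  ids[widx] <- seq_len(N)
  wijk <- which(wall, arr.ind = TRUE)

  # Per-direction neighbour classification. side kind: 0 wall, 1 Dirichlet
  # (with value), 2 Neumann.
  side_info <- function(off, axis) {
    nijk <- sweep(wijk, 2L, off, `+`)
    inb <- nijk[, 1] >= 1 & nijk[, 1] <= d[1] &
           nijk[, 2] >= 1 & nijk[, 2] <= d[2] &
           nijk[, 3] >= 1 & nijk[, 3] <= d[3]
    kind <- rep(2L, N); nb <- rep(NA_integer_, N)
    val <- rep(NA_real_, N); theta <- rep(1, N)
    ok <- which(inb)
    nlin <- nijk[ok, 1] + d[1] * (nijk[ok, 2] - 1) + d[1] * d[2] * (nijk[ok, 3] - 1)
    nb_wall <- !is.na(ids[nlin])
    kind[ok[nb_wall]] <- 0L
    nb[ok[nb_wall]] <- ids[nlin[nb_wall]]
    is_bl <- blood[nlin]
    is_bg <- bg[nlin]
    c_endo <- endo[widx[ok]]
    c_epi <- epi[widx[ok]]
    dir0 <- is_bl & c_endo
    dir1 <- is_bg & c_epi
    kind[ok[dir0]] <- 1L; val[ok[dir0]] <- 0
    kind[ok[dir1]] <- 1L; val[ok[dir1]] <- 1
    if (subvoxel) {
      th0 <- crossing_theta(phi_endo[widx[ok[dir0]]], phi_endo[nlin[dir0]])
      th1 <- crossing_theta(phi_epi[widx[ok[dir1]]], phi_epi[nlin[dir1]])
      theta[ok[dir0]] <- th0
      theta[ok[dir1]] <- th1
    } else {
      theta[ok[dir0]] <- 0.5
      theta[ok[dir1]] <- 0.5
    }
    list(kind = kind, nb = nb, val = val, theta = theta)
  }

  # symmetric cut-cell stencil (ghost value by linear extrapolation
  # through the boundary condition): each face contributes 1/h^2 coupling
  # for a wall neighbour, -1/(theta h^2) diagonal + val/(theta h^2) rhs
  # for a Dirichlet face, and nothing for a mirror (zero-flux) face. The
  # system is symmetric positive definite, solved by sparse Cholesky.
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  diag_acc <- numeric(N); rhs <- numeric(N)
  offs <- face_offsets()
  has_dir <- rep(FALSE, N)
  for (axis in 1:3) {
    ha2 <- h[axis]^2
    for (s in list(side_info(offs[2 * axis, ], axis),
                   side_info(offs[2 * axis - 1, ], axis))) {
      w <- which(s$kind == 0L)
      ti <- c(ti, w); tj <- c(tj, s$nb[w]); tx <- c(tx, rep(1 / ha2, length(w)))
      diag_acc[w] <- diag_acc[w] - 1 / ha2
      dsel <- which(s$kind == 1L)
      diag_acc[dsel] <- diag_acc[dsel] - 1 / (s$theta[dsel] * ha2)
      rhs[dsel] <- rhs[dsel] - s$val[dsel] / (s$theta[dsel] * ha2)
      has_dir[dsel] <- TRUE
    }
  }
  ne <- length(ti)
  ti_all <- c(ti, seq_len(N)); tj_all <- c(tj, seq_len(N))
  tx_all <- c(tx, diag_acc)
  A <- Matrix::sparseMatrix(i = ti_all, j = tj_all, x = -tx_all,
                            dims = c(N, N))
  b <- -rhs

  # a connected component with no Dirichlet face would be singular:
  # detect it on the voxel adjacency graph and leave it undefined
  g <- igraph::make_graph(rbind(ti, tj), n = N, directed = FALSE)
  comp <- igraph::components(g)$membership
  has_dirichlet <- tapply(has_dir, comp, any)
  bad <- as.integer(names(has_dirichlet)[!has_dirichlet])
  keep <- !(comp %in% bad)
  if (any(!keep)) {
    warning(sum(!keep), " wall voxel(s) in components without boundary ",
            "conditions; their potential is undefined")
  }
  u <- rep(NA_real_, N)
  ksel <- which(keep)
  Ak <- Matrix::forceSymmetric(A[ksel, ksel, drop = FALSE])
  u[ksel] <- as.numeric(Matrix::solve(Ak, b[ksel]))
  res <- as.numeric(Ak %*% u[ksel] - b[ksel])
  residual <- max(abs(res)) / max(abs(diag_acc))
  if (!is.finite(residual) || residual > tol)
    stop("Laplace solve did not reach the requested residual (",
         signif(residual, 3), " > ", tol, ")")

  uarr <- array(NA_real_, d)
  uarr[widx] <- u

  # extended field for gradients: fill the one-voxel halo by linear
  # extrapolation through the boundary condition (ghost values)
  uext <- uarr
  halo_num <- array(0, d); halo_den <- array(0, d)
  for (axis in 1:3) {
    for (sgn in c(1L, -1L)) {
      off <- c(0L, 0L, 0L); off[axis] <- sgn
      s <- side_info(off, axis)
      sel <- which(s$kind %in% c(1L, 2L))
      if (!length(sel)) next
      nijk <- sweep(wijk[sel, , drop = FALSE], 2L, off, `+`)
      inb <- nijk[, 1] >= 1 & nijk[, 1] <= d[1] &
             nijk[, 2] >= 1 & nijk[, 2] <= d[2] &
             nijk[, 3] >= 1 & nijk[, 3] <= d[3]
      sel <- sel[inb]; nijk <- nijk[inb, , drop = FALSE]
      if (!length(sel)) next
      uc <- u[sel]
      th <- s$theta[sel]
      gv <- ifelse(s$kind[sel] == 2L, uc,
            ifelse(s$val[sel] == 0, uc * (th - 1) / th, uc + (1 - uc) / th))
      nlin <- nijk[, 1] + d[1] * (nijk[, 2] - 1) + d[1] * d[2] * (nijk[, 3] - 1)
      ok <- is.finite(gv)
      for (q in which(ok)) {          # accumulate (few duplicates share a halo voxel)
        halo_num[nlin[q]] <- halo_num[nlin[q]] + gv[q]
        halo_den[nlin[q]] <- halo_den[nlin[q]] + 1
      }
    }
  }
  fill <- halo_den > 0 & !wall
  uext[fill] <- halo_num[fill] / halo_den[fill]

  grad <- list()
  for (axis in 1:3) {
    gp <- array(NA_real_, d)
    off <- c(0L, 0L, 0L); off[axis] <- 1L
    up <- sweep(wijk, 2L, off, `+`); um <- sweep(wijk, 2L, -off, `+`)
    clampm <- function(m) { for (a in 1:3) m[, a] <- pmin(pmax(m[, a], 1L), d[a]); m }
    vp <- uext[clampm(up)]; vm <- uext[clampm(um)]
    vp[is.na(vp)] <- u[is.na(vp)]     # fallback: one-sided towards centre
    vm[is.na(vm)] <- u[is.na(vm)]
    gp[widx] <- (vp - vm) / (2 * h[axis])
    grad[[axis]] <- gp
  }

  structure(list(u = uarr, u_ext = uext, grad = grad,
                 endo = endo, epi = epi, wall = wall,
                 phi_endo = phi_endo, phi_epi = phi_epi,
                 spacing = h, origin = labels$origin,
                 labels = labels,
                 residual = residual, n_unknowns = N,
                 n_undefined = sum(!keep)),
            class = "laplace_field")
}

#' @export
print.laplace_field <- function(x, ...) {
  cat("<laplace_field> ", x$n_unknowns, " wall voxels, residual ",
      signif(x$residual, 3), "\n", sep = "")
  invisible(x)
}

# Interpolated normalised gradient direction at world positions.
field_direction <- function(field, xyz) {
  p <- world_to_cont(field, xyz)
  g <- cbind(trilinear(field$grad[[1]], p),
             trilinear(field$grad[[2]], p),
             trilinear(field$grad[[3]], p))
  nrm <- sqrt(rowSums(g^2))
  list(dir = g / pmax(nrm, 1e-12), norm = nrm)
}

# Batch streamline tracer. Seeds are world positions on/near the
# endocardium; integrates the normalised potential gradient with RK4 at a
# fixed step, forward to the epicardial surface and backward to the
# endocardial surface (each surface = 0.5-level of its smoothed
# indicator), and samples the tissue label at every step point.
trace_batch <- function(field, seeds, step = 0.5 * min(field$spacing),
                        keep_paths = FALSE, grad_floor = 1e-8) {
  n <- nrow(seeds)
  d <- dim(field$u)
  lab <- tissue_labels()
  max_steps <- ceiling(3 * max(d * field$spacing) / step)
  counts <- matrix(0L, n, 3L,
                   dimnames = list(NULL, c("normal", "ht", "scar")))
  count_at <- function(idx, xyz) {
    lv <- sample_nearest(field$labels, xyz, outside = NA)
    counts[cbind(idx, 1L)] <<- counts[cbind(idx, 1L)] +
      as.integer(!is.na(lv) & lv == lab[["myocardium"]])
    counts[cbind(idx, 2L)] <<- counts[cbind(idx, 2L)] +
      as.integer(!is.na(lv) & lv == lab[["ht"]])
    counts[cbind(idx, 3L)] <<- counts[cbind(idx, 3L)] +
      as.integer(!is.na(lv) & lv == lab[["scar"]])
  }
  count_at(seq_len(n), seeds)
  arc <- matrix(0, n, 2L)            # backward, forward
  undefined <- rep(FALSE, n)
  paths <- if (keep_paths) list(bwd = vector("list", n),
                                fwd = vector("list", n)) else NULL

  interp_phi <- function(arr, xyz) trilinear(arr, world_to_cont(field, xyz))

  for (pass in 1:2) {
    sgn <- if (pass == 1) -1 else 1            # backward to endo, then forward
    phi <- if (pass == 1) field$phi_endo else field$phi_epi
    pos <- seeds
    active <- !undefined
    steps <- 0L
    while (any(active) && steps < max_steps) {
      steps <- steps + 1L
      ia <- which(active)
      p0 <- pos[ia, , drop = FALSE]
      f1 <- field_direction(field, p0)
      stag <- f1$norm < grad_floor | !is.finite(f1$norm)
      if (any(stag)) {
        undefined[ia[stag]] <- TRUE
        active[ia[stag]] <- FALSE
        ia <- ia[!stag]; p0 <- p0[!stag, , drop = FALSE]
        f1$dir <- f1$dir[!stag, , drop = FALSE]
        if (!length(ia)) break
      }
      k1 <- f1$dir
      k2 <- field_direction(field, p0 + sgn * step / 2 * k1)$dir
      k3 <- field_direction(field, p0 + sgn * step / 2 * k2)$dir
      k4 <- field_direction(field, p0 + sgn * step * k3)$dir
      k2[!is.finite(k2)] <- k1[!is.finite(k2)]
      k3[!is.finite(k3)] <- k1[!is.finite(k3)]
      k4[!is.finite(k4)] <- k1[!is.finite(k4)]
      mv <- sgn * step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      p1 <- p0 + mv
      ph <- interp_phi(phi, p1)
      crossed <- !is.na(ph) & ph >= 0.5
      # bisect the exit point on the surface level
      if (any(crossed)) {
        ic <- which(crossed)
        a <- p0[ic, , drop = FALSE]; bpt <- p1[ic, , drop = FALSE]
        for (it in 1:25) {
          mid <- (a + bpt) / 2
          pm <- interp_phi(phi, mid)
          hit <- !is.na(pm) & pm >= 0.5
          bpt[hit, ] <- mid[hit, ]
          a[!hit, ] <- mid[!hit, ]
        }
        exitp <- (a + bpt) / 2
        arc[ia[ic], pass] <- arc[ia[ic], pass] +
          sqrt(rowSums((exitp - p0[ic, , drop = FALSE])^2))
        # sample the midpoint of the clipped final segment
        count_at(ia[ic], (p0[ic, , drop = FALSE] + exitp) / 2)
        if (keep_paths) for (q in seq_along(ic))
          paths[[pass]][[ia[ic[q]]]] <-
            rbind(paths[[pass]][[ia[ic[q]]]], exitp[q, ])
        active[ia[ic]] <- FALSE
      }
      nc <- which(!crossed)
      if (length(nc)) {
        arc[ia[nc], pass] <- arc[ia[nc], pass] + step
        pos[ia[nc], ] <- p1[nc, , drop = FALSE]
        # sample at segment midpoint and endpoint (quarter-voxel spacing)
        count_at(ia[nc], (p0[nc, , drop = FALSE] + p1[nc, , drop = FALSE]) / 2)
        count_at(ia[nc], p1[nc, , drop = FALSE])
        if (keep_paths) for (q in seq_along(nc))
          paths[[pass]][[ia[nc[q]]]] <-
            rbind(paths[[pass]][[ia[nc[q]]]], p1[nc[q], ])
      }
    }
    if (any(active)) undefined[active] <- TRUE   # never exited
  }
  list(thickness = ifelse(undefined, NA_real_, arc[, 1] + arc[, 2]),
       arc_backward = arc[, 1], arc_forward = arc[, 2],
       counts = counts, undefined = undefined, paths = paths,
       step = step)
}

#' Trace a single transmural streamline
#'
#' Integrates the normalised gradient of the Laplace potential from an
#' endocardial seed to the epicardial surface (and back to the
#' endocardial surface, so the path spans the full wall), with
#' fourth-order Runge-Kutta at a fixed step of half a voxel. Tissue
#' labels are sampled at every path point (equal arc-length sampling), so
#' label proportions along the path approximate proportions of path
#' length.
#'
#' @param field A `laplace_field` from [solve_laplace()].
#' @param seed World position (length-3, mm) of an endocardial node.
#' @param step Integration step, mm (default half the voxel edge).
#' @return A `streamline_path`: matrix of path `points`, per-point
#'   `labels`, `arc_length` in mm, and `defined` flag.
#' @export
trace_streamline <- function(field, seed, step = 0.5 * min(field$spacing)) {
  stopifnot(inherits(field, "laplace_field"), length(seed) == 3L)
  tb <- trace_batch(field, matrix(seed, 1L), step = step, keep_paths = TRUE)
  bwd <- tb$paths$bwd[[1]]
  fwd <- tb$paths$fwd[[1]]
  pts <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed, 1L), fwd)
  labv <- sample_nearest(field$labels, pts, outside = NA)
  structure(list(points = pts, labels = labv,
                 arc_length = tb$thickness[1],
                 defined = !tb$undefined[1]),
            class = "streamline_path")
}

#' Transmurality of scar and heterogeneous tissue along a streamline
#'
#' The transmurality of each tissue type is the percentage of points
#' along the endo-to-epi path carrying that label.
#'
#' @param path A `streamline_path` from [trace_streamline()].
#' @return Named numeric: `scar_pct`, `ht_pct` (each in `[0, 100]`).
#' @export
compute_transmurality <- function(path) {
  stopifnot(inherits(path, "streamline_path"))
  lab <- tissue_labels()
  lv <- path$labels[!is.na(path$labels) & path$labels %in% wall_labels()]
  if (length(lv) < 2L)
    return(c(scar_pct = NA_real_, ht_pct = NA_real_))
  c(scar_pct = 100 * mean(lv == lab[["scar"]]),
    ht_pct = 100 * mean(lv == lab[["ht"]]))
}

#' Build the per-node endocardial map of thickness and transmurality
#'
#' Traces one streamline per endocardial voxel and tabulates wall
#' thickness (total streamline arc length) and scar/HT transmurality
#' (label proportions along the path). Nodes whose streamline stagnates
#' or fails to exit are flagged undefined rather than given a fabricated
#' thickness. A node is classified transmural when its combined scar+HT
#' transmurality reaches `transmural_cutoff` (non-transmural below 95%).
#'
#' @param labels A label [vox_volume()].
#' @param field A `laplace_field` from [solve_laplace()] on those labels.
#' @param step Streamline integration step, mm.
#' @param transmural_cutoff Percentage cutoff for the transmural class.
#' @return An `endocardial_map` tibble: `node_id`, voxel indices, world
#'   position, `thickness_mm`, `scar_pct`, `ht_pct`, `transmural`,
#'   `defined`.
#' @export
endocardial_map <- function(labels, field, step = 0.5 * min(field$spacing),
                            transmural_cutoff = 95) {
  stopifnot(inherits(field, "laplace_field"))
  eidx <- which(field$endo, arr.ind = TRUE)
  seeds <- voxel_to_world(labels, eidx)
  tb <- trace_batch(field, seeds, step = step)
  tot <- pmax(rowSums(tb$counts), 1L)
  scar_pct <- 100 * tb$counts[, "scar"] / tot
  ht_pct <- 100 * tb$counts[, "ht"] / tot
  out <- tibble::tibble(
    node_id = seq_len(nrow(eidx)),
    i = eidx[, 1], j = eidx[, 2], k = eidx[, 3],
    x = seeds[, 1], y = seeds[, 2], z = seeds[, 3],
    thickness_mm = tb$thickness,
    scar_pct = ifelse(tb$undefined, NA_real_, scar_pct),
    ht_pct = ifelse(tb$undefined, NA_real_, ht_pct),
    transmural = ifelse(tb$undefined, NA,
                        scar_pct + ht_pct >= transmural_cutoff),
    defined = !tb$undefined)
  frac_undef <- mean(tb$undefined)
  if (frac_undef > 0.05)
    warning(sum(tb$undefined), " of ", nrow(out),
            " endocardial nodes have undefined streamlines")
  class(out) <- c("endocardial_map", class(out))
  attr(out, "transmural_cutoff") <- transmural_cutoff
  out
}
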