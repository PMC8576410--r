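#' Rigid transform (rotation + translation)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric, mm.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("improper rotation (det = -1) not allowed")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Rotation about an axis by an angle
#' @param axis Length-3 axis (need not be unit).
#' @param angle_deg Angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

#' Apply a rigid transform to points
#' @param transform A [rigid_transform()].
#' @param xyz Matrix (n x 3) of points, mm.
#' @return Transformed matrix (n x 3).
#' @export
apply_transform <- function(transform, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(xyz %*% t(transform$rotation), 2L, transform$translation, `+`)
}

#' Compose two rigid transforms (`a` applied after `b`)
#' @param a,b [rigid_transform()] objects.
#' @return The composite transform `x -> a(b(x))`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% transform$translation))
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat("<rigid_transform> rotation ", signif(ang, 4), " deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

# Least-squares rigid fit (Kabsch) mapping `moving` onto `fixed`;
# det = +1 enforced (no reflection, no scaling).
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  H <- crossprod(sweep(moving, 2L, cm), sweep(fixed, 2L, cf))
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  rigid_transform(R, cf - as.numeric(R %*% cm))
}

#' Landmark-based rigid alignment
#'
#' Least-squares rigid transform (Kabsch/Procrustes, no scaling, no
#' reflection) mapping paired moving fiducials (e.g. mapping-system
#' apex and ostial landmarks) onto their fixed CMR counterparts.
#'
#' @param fixed,moving Paired fiducial matrices (n x 3, n >= 3,
#'   non-collinear), same row order.
#' @return List: `transform` ([rigid_transform()]), `rms_mm` (fiducial
#'   root-mean-square residual).
#' @export
landmark_align <- function(fixed, moving) {
  fixed <- matrix(as.numeric(fixed), ncol = 3L)
  moving <- matrix(as.numeric(moving), ncol = 3L)
  if (nrow(fixed) != nrow(moving)) stop("fiducial counts differ")
  if (nrow(fixed) < 3L) stop("need at least 3 paired fiducials")
  cf <- sweep(fixed, 2L, colMeans(fixed))
  if (svd(cf)$d[2] < 1e-9 * max(svd(cf)$d[1], 1))
    stop("fiducials are collinear")
  tr <- kabsch(moving, fixed)
  res <- apply_transform(tr, moving) - fixed
  list(transform = tr, rms_mm = sqrt(mean(rowSums(res^2))))
}

# Exact closest points on a set of triangles (Ericson's method),
# vectorised: p, a, b, c are n x 3.
closest_point_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- p - b
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- p - c
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  out <- matrix(NA_real_, nrow(p), 3L)
  done <- rep(FALSE, nrow(p))
  setres <- function(sel, val) {
    sel <- sel & !done
    out[sel, ] <<- val[sel, , drop = FALSE]
    done[sel] <<- TRUE
  }
  setres(d1 <= 0 & d2 <= 0, a)
  setres(d3 >= 0 & d4 <= d3, b)
  setres(d6 >= 0 & d5 <= d6, c)
  vc <- d1 * d4 - d3 * d2
  vv <- d1 / (d1 - d3)
  setres(vc <= 0 & d1 >= 0 & d3 <= 0, a + vv * ab)
  vb <- d5 * d2 - d1 * d6
  ww <- d2 / (d2 - d6)
  setres(vb <= 0 & d2 >= 0 & d6 <= 0, a + ww * ac)
  va <- d3 * d6 - d5 * d4
  w2 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  setres(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, b + w2 * (c - b))
  denom <- va + vb + vc
  v3 <- vb / denom; w3 <- vc / denom
  setres(!done, a + v3 * ab + w3 * ac)
  out
}

# Closest surface point on a mesh for each query point: nearest vertex
# first, then the exact foot point among triangles incident to it.
closest_surface_point <- function(points, mesh, vfi = vertex_face_index(mesh)) {
  nn <- nearest_dist(points, mesh$vertices)
  n <- nrow(points)
  best <- mesh$vertices[nn$index, , drop = FALSE]
  bestd <- nn$dist
  fl <- vfi[as.character(nn$index)]
  nf <- lengths(fl)
  maxf <- max(nf, 1L)
  for (r in seq_len(maxf)) {
    sel <- which(nf >= r)
    if (!length(sel)) break
    fid <- vapply(fl[sel], `[[`, integer(1), r)
    tri <- mesh$faces[fid, , drop = FALSE]
    cp <- closest_point_on_triangle(points[sel, , drop = FALSE],
                                    mesh$vertices[tri[, 1], , drop = FALSE],
                                    mesh$vertices[tri[, 2], , drop = FALSE],
                                    mesh$vertices[tri[, 3], , drop = FALSE])
    dd <- sqrt(rowSums((cp - points[sel, , drop = FALSE])^2))
    upd <- dd < bestd[sel]
    best[sel[upd], ] <- cp[upd, , drop = FALSE]
    bestd[sel[upd]] <- dd[upd]
  }
  list(point = best, dist = bestd)
}

#' Iterative closest point refinement against a surface mesh
#'
#' Refines an initial rigid alignment (normally the landmark result) by
#' alternating point-to-surface correspondence (exact closest point on
#' the triangles incident to the nearest vertex) and a rigid Kabsch
#' update, with the worst `trim` fraction of correspondences discarded
#' each iteration for robustness. Iterates until the trimmed RMS change
#' falls below `conv_tol` or `max_iter` is reached; the best transform
#' seen is returned, so the reported RMS sequence is non-increasing.
#'
#' @param moving Point matrix (n x 3), original (unregistered) frame.
#' @param mesh Target [surface_mesh()].
#' @param init Initial [rigid_transform()].
#' @param max_iter Iteration cap.
#' @param conv_tol RMS-change convergence tolerance, mm.
#' @param trim Fraction of worst correspondences trimmed per iteration.
#' @return List: `transform`, `rms_mm` (final trimmed RMS), `rms_trace`
#'   (per-iteration), `iterations`, `converged`.
#' @export
icp_refine <- function(moving, mesh, init = rigid_transform(),
                       max_iter = 100L, conv_tol = 1e-4, trim = 0.1) {
  stopifnot(inherits(mesh, "surface_mesh"))
  moving <- matrix(as.numeric(moving), ncol = 3L)
  if (!nrow(mesh$faces)) stop("degenerate target mesh")
  vfi <- vertex_face_index(mesh)
  tr <- init
  best_tr <- tr; best_rms <- Inf
  trace_ <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- apply_transform(tr, moving)
    cs <- closest_surface_point(cur, mesh, vfi)
    keep <- seq_len(nrow(cur))
    if (trim > 0 && nrow(cur) >= 10L) {
      k <- max(3L, floor((1 - trim) * nrow(cur)))
      keep <- order(cs$dist)[seq_len(k)]
    }
    rms <- sqrt(mean(cs$dist[keep]^2))
    if (it > 1L && rms > trace_[it - 1L] + 1e-12) break  # reject ascent, keep best
    trace_ <- c(trace_, rms)
    if (rms < best_rms) { best_rms <- rms; best_tr <- tr }
    if (it > 1L && abs(trace_[it - 1L] - rms) < conv_tol) {
      converged <- TRUE
      break
    }
    upd <- kabsch(cur[keep, , drop = FALSE], cs$point[keep, , drop = FALSE])
    tr <- compose_transform(upd, tr)
  }
  list(transform = best_tr, rms_mm = best_rms,
       rms_trace = trace_, iterations = length(trace_),
       converged = converged)
}

#' Map registered points to mesh nodes within a radius
#'
#' Each registered mapping point is assigned to its nearest mesh node if
#' that node lies within `radius` (default 1 mm, the node-mapping radius
#' used when transferring electroanatomic points onto the CMR-derived
#' mesh); otherwise it is left unassigned. Nearest-neighbour ties
#' resolve to the lowest node id.
#'
#' @param points Tibble/data frame with `x, y, z` (and optionally
#'   `time_ms`, `category`, `label`) in the unregistered frame, or a
#'   plain n x 3 matrix.
#' @param mesh Target [surface_mesh()].
#' @param transform [rigid_transform()] taking points into the mesh
#'   frame (from [landmark_align()] / [icp_refine()]).
#' @param radius Assignment radius, mm.
#' @return Tibble of mapped points: original and transformed positions,
#'   carried-over columns, `node_id` (NA when unassigned) and
#'   `assign_dist_mm`.
#' @export
map_points_to_nodes <- function(points, mesh, transform = rigid_transform(),
                                radius = 1.0) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (is.matrix(points)) points <- tibble::tibble(x = points[, 1],
                                                  y = points[, 2],
                                                  z = points[, 3])
  pos <- as.matrix(points[, c("x", "y", "z")])
  newpos <- apply_transform(transform, pos)
  nn <- nearest_dist(newpos, mesh$vertices)
  assigned <- nn$dist <= radius
  out <- tibble::as_tibble(points)
  out$x_orig <- pos[, 1]; out$y_orig <- pos[, 2]; out$z_orig <- pos[, 3]
  out$x <- newpos[, 1]; out$y <- newpos[, 2]; out$z <- newpos[, 3]
  out$node_id <- ifelse(assigned, nn$index, NA_integer_)
  out$assign_dist_mm <- ifelse(assigned, nn$dist, NA_real_)
  class(out) <- c("mapped_points", class(out))
  out
}
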