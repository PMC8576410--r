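# Chunked vectorised nearest-neighbour search: for each query row the
# distance to, and index of, the nearest target row (Euclidean, world mm).
# Ties resolve to the lowest target index (which.min).
nearest_dist <- function(query, target, chunk = 512L) {
  query <- matrix(as.numeric(query), ncol = 3L)
  target <- matrix(as.numeric(target), ncol = 3L)
  n <- nrow(query)
  if (!nrow(target)) return(list(dist = rep(Inf, n), index = rep(NA_integer_, n)))
  t2 <- rowSums(target^2)
  dist <- numeric(n); index <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), t2, `+`) - 2 * q %*% t(target)
    ix <- max.col(-d2, ties.method = "first")
    dist[s:e] <- sqrt(pmax(d2[cbind(seq_len(e - s + 1L), ix)], 0))
    index[s:e] <- ix
  }
  list(dist = dist, index = index)
}

#' Distance from query points to a target point set
#'
#' Euclidean distance in world millimetres from each query point to its
#' nearest element of the target set (e.g. from endocardial nodes to the
#' nearest node labelled heterogeneous tissue anywhere in the wall, or to
#' the nearest steep-gradient vertex). With an empty target all
#' distances are undefined (`Inf`) and a warning is raised.
#'
#' @param query Numeric matrix (n x 3) or data frame with `x, y, z`.
#' @param target Same forms; the target set.
#' @return Tibble: `dist_mm`, `target_index` per query point.
#' @export
distance_to_set <- function(query, target) {
  as_xyz <- function(p) {
    if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y", "z")])
    matrix(as.numeric(p), ncol = 3L)
  }
  q <- as_xyz(query); tg <- as_xyz(target)
  if (!nrow(tg)) warning("empty target set; all distances undefined")
  nn <- nearest_dist(q, tg)
  tibble::tibble(dist_mm = nn$dist, target_index = nn$index)
}

#' World positions of voxels carrying a given label
#'
#' @param labels A label [vox_volume()].
#' @param label Integer label code (see [tissue_labels()]).
#' @return Matrix (n x 3) of voxel-centre world positions.
#' @export
label_positions <- function(labels, label = tissue_labels()[["ht"]]) {
  idx <- which(labels$data == label, arr.ind = TRUE)
  voxel_to_world(labels, idx)
}

#' Fit a radial basis function to a surface field and take its gradient
#'
#' Interpolates a per-vertex scalar (wall thickness) with a polyharmonic
#' cubic radial basis function `phi(r) = r^3` plus a linear polynomial in
#' ambient 3D coordinates, evaluates the analytic gradient of the
#' interpolant at every vertex, and projects it onto the local tangent
#' plane (per-vertex normal). The tangential magnitude, in mm of
#' thickness per mm of surface distance, is the thickness-gradient field.
#'
#' Constants and linear ramps are reproduced exactly by the polynomial
#' part regardless of smoothing. For large meshes the RBF centres are a
#' deterministic subsample (`max_centers`) and the system is solved in a
#' regularised least-squares sense.
#'
#' @param mesh A [surface_mesh()].
#' @param thickness Per-vertex numeric (NA allowed; such vertices are
#'   excluded from the fit but still evaluated).
#' @param smoothing Ridge added to the kernel block, as a fraction of the
#'   mean absolute kernel entry (default 1e-2, enough to suppress the
#'   half-voxel ripple of measured thickness without flattening genuine
#'   border-zone gradients).
#' @param max_centers Maximum number of RBF centres.
#' @return A `gradient_field`: tibble with `vertex`, `grad_mag`
#'   (mm/mm), the tangential gradient components, and the fitted
#'   thickness; the mesh is attached as an attribute.
#' @export
rbf_gradient <- function(mesh, thickness, smoothing = 1e-2,
                         max_centers = 2000L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  ok <- which(is.finite(thickness))
  if (length(ok) < 10L) stop("need at least 10 vertices with defined thickness")
  ctr_idx <- ok
  if (length(ctr_idx) > max_centers)
    ctr_idx <- ok[round(seq(1L, length(ok), length.out = max_centers))]
  C <- v[ctr_idx, , drop = FALSE]
  nC <- nrow(C)

  pdist <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(pmax(d2, 0))
  }
  K <- pdist(C, C)^3
  # keep only independent polynomial columns (coplanar or collinear
  # centres make the full linear polynomial rank deficient)
  P_full <- cbind(1, C)
  qrP <- qr(P_full)
  keepP <- sort(qrP$pivot[seq_len(qrP$rank)])
  P <- P_full[, keepP, drop = FALSE]
  npol <- ncol(P)
  lam <- smoothing * mean(abs(K))
  Afit <- rbind(cbind(K + diag(lam, nC), P),
                cbind(t(P), matrix(0, npol, npol)))
  yfit <- c(thickness[ctr_idx], rep(0, npol))
  coef <- tryCatch(solve(Afit, yfit), error = function(e) {
    warning("ill-conditioned RBF system; increasing smoothing")
    solve(Afit + diag(1e-8 * mean(abs(Afit)), nrow(Afit)), yfit)
  })
  w <- coef[seq_len(nC)]
  pol <- numeric(4)
  pol[keepP] <- coef[nC + seq_len(npol)]

  # analytic gradient: d/dx sum w_i r_i^3 = sum w_i * 3 r_i * (x - c_i)
  grad <- matrix(rep(pol[2:4], each = nrow(v)), ncol = 3L)
  val <- as.numeric(cbind(1, v) %*% pol)
  chunk <- 1024L
  for (s in seq(1L, nrow(v), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(v))
    D <- pdist(v[s:e, , drop = FALSE], C)
    val[s:e] <- val[s:e] + as.numeric(D^3 %*% w)
    for (ax in 1:3) {
      diffs <- outer(v[s:e, ax], C[, ax], `-`)
      grad[s:e, ax] <- grad[s:e, ax] + as.numeric((3 * D * diffs) %*% w)
    }
  }
  nrml <- vertex_normals(mesh)
  gn <- rowSums(grad * nrml)
  gt <- grad - gn * nrml
  out <- tibble::tibble(vertex = seq_len(nrow(v)),
                        grad_x = gt[, 1], grad_y = gt[, 2], grad_z = gt[, 3],
                        grad_mag = sqrt(rowSums(gt^2)),
                        thickness_fit = val)
  class(out) <- c("gradient_field", class(out))
  attr(out, "mesh") <- mesh
  out
}

#' Identify steep-gradient regions on the surface
#'
#' Vertices whose tangential thickness-gradient magnitude meets the
#' threshold, grouped into connected components over the mesh edge graph.
#' The threshold for a "steep" gradient is a package choice (default 0.5
#' mm/mm); a data-driven quantile alternative is available via
#' `quantile_threshold`.
#'
#' @param field A `gradient_field` from [rbf_gradient()].
#' @param steep_threshold Gradient magnitude threshold, mm/mm.
#' @param quantile_threshold If non-NULL, use this quantile of the
#'   observed magnitudes (e.g. 0.9) instead of `steep_threshold`.
#' @return Tibble of steep vertices: `vertex`, `grad_mag`, `component`.
#' @export
steep_regions <- function(field, steep_threshold = 0.5,
                          quantile_threshold = NULL) {
  stopifnot(inherits(field, "gradient_field"))
  thr <- if (!is.null(quantile_threshold))
    stats::quantile(field$grad_mag, quantile_threshold, na.rm = TRUE)
  else steep_threshold
  steep <- which(field$grad_mag >= thr)
  mesh <- attr(field, "mesh")
  comp <- integer(0)
  if (length(steep)) {
    ed <- mesh_edges(mesh)
    keep <- ed[, 1] %in% steep & ed[, 2] %in% steep
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ed[keep, 1]),
                 to = as.character(ed[keep, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(steep)))
    comp <- igraph::components(g)$membership[as.character(steep)]
  }
  out <- tibble::tibble(vertex = steep,
                        grad_mag = field$grad_mag[steep],
                        component = as.integer(comp))
  attr(out, "threshold") <- thr
  out
}

#' Transfer an endocardial node map onto mesh vertices
#'
#' Assigns each mesh vertex the metrics of its nearest endocardial node
#' (nearest voxel-centre node of an [endocardial_map()]).
#'
#' @param map An `endocardial_map` tibble.
#' @param mesh A [surface_mesh()].
#' @return Tibble with one row per vertex: `vertex`, position, and the
#'   node metrics (`thickness_mm`, `scar_pct`, `ht_pct`, `transmural`,
#'   `node_id`, `node_dist_mm`).
#' @export
map_to_mesh <- function(map, mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nn <- nearest_dist(mesh$vertices, as.matrix(map[, c("x", "y", "z")]))
  tibble::tibble(vertex = seq_len(nrow(mesh$vertices)),
                 x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                 z = mesh$vertices[, 3],
                 node_id = map$node_id[nn$index],
                 node_dist_mm = nn$dist,
                 thickness_mm = map$thickness_mm[nn$index],
                 scar_pct = map$scar_pct[nn$index],
                 ht_pct = map$ht_pct[nn$index],
                 transmural = map$transmural[nn$index])
}
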