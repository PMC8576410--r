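#' Surface mesh container
#'
#' @param vertices Numeric matrix (V x 3), world mm.
#' @param faces Integer matrix (F x 3), 1-based vertex indices.
#' @param attributes Optional named list of per-vertex numeric vectors.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, faces, attributes = list()) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- matrix(as.integer(faces), ncol = 3L)
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices reference missing vertices")
  structure(list(vertices = vertices, faces = faces, attributes = attributes),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

# linear interpolation of the iso crossing on an edge
.edge_point <- function(pa, pb, va, vb, iso) {
  t <- (iso - va) / (vb - va)
  t[!is.finite(t)] <- 0.5
  t <- pmin(pmax(t, 0), 1)
  pa + (pb - pa) * t
}

# Marching tetrahedra over a scalar field: triangulates the `iso`
# level set. Returns a triangle soup (n x 9: three xyz triples).
marching_tetrahedra <- function(arr, iso, spacing, origin) {
  d <- dim(arr)
  # cube corner offsets, standard ordering with main diagonal c0-c6
  corner <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  tets <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  cubes <- which(array(TRUE, d - 1L), arr.ind = TRUE)
  # restrict to cubes with a sign change over their 8 corners
  vmin <- array(Inf, d - 1L); vmax <- array(-Inf, d - 1L)
  for (r in 1:8) {
    sl <- arr[corner[r, 1] + seq_len(d[1] - 1L),
              corner[r, 2] + seq_len(d[2] - 1L),
              corner[r, 3] + seq_len(d[3] - 1L)]
    vmin <- pmin(vmin, sl); vmax <- pmax(vmax, sl)
  }
  act <- which(vmin < iso & vmax >= iso)
  if (!length(act)) return(matrix(numeric(0), 0, 9))
  cubes <- cubes[act, , drop = FALSE]
  n <- nrow(cubes)
  V <- matrix(0, n, 8); P <- array(0, c(n, 8, 3))
  for (r in 1:8) {
    ijk <- sweep(cubes, 2L, corner[r, ], `+`)
    V[, r] <- arr[ijk]
    P[, r, ] <- sweep(sweep(ijk - 1, 2L, spacing, `*`), 2L, origin, `+`)
  }
  soup <- vector("list", 64L); ns <- 0L
  emit <- function(p1, p2, p3) {
    ns <<- ns + 1L
    soup[[ns]] <<- cbind(p1, p2, p3)
  }
  for (t in 1:6) {
    idx <- tets[t, ]
    v <- V[, idx, drop = FALSE]
    p <- P[, idx, , drop = FALSE]
    inside <- v >= iso
    code <- inside[, 1] + 2L * inside[, 2] + 4L * inside[, 3] + 8L * inside[, 4]
    for (cd in 1:14) {
      sel <- which(code == cd)
      if (!length(sel)) next
      bits <- as.logical(bitwAnd(cd, c(1L, 2L, 4L, 8L)))
      ins <- which(bits); outs <- which(!bits)
      ep <- function(a, b)
        .edge_point(p[sel, a, , drop = TRUE], p[sel, b, , drop = TRUE],
                    v[sel, a], v[sel, b], iso)
      if (length(sel) == 1L) {
        ep <- function(a, b)
          matrix(.edge_point(p[sel, a, ], p[sel, b, ], v[sel, a], v[sel, b],
                             iso), 1L)
      }
      if (length(ins) == 1L) {
        A <- ins; O <- outs
        emit(ep(A, O[1]), ep(A, O[2]), ep(A, O[3]))
      } else if (length(ins) == 3L) {
        A <- outs; O <- ins
        emit(ep(A, O[1]), ep(A, O[2]), ep(A, O[3]))
      } else {
        A <- ins[1]; B <- ins[2]; C <- outs[1]; D <- outs[2]
        emit(ep(A, C), ep(B, C), ep(A, D))
        emit(ep(B, C), ep(B, D), ep(A, D))
      }
    }
  }
  do.call(rbind, soup[seq_len(ns)])
}

#' Extract an endocardial or epicardial surface mesh
#'
#' Triangulates the requested surface as the 0.5 level set of a
#' Gaussian-smoothed binary phase indicator (blood pool for the
#' endocardium; blood + wall for the epicardium), via marching
#' tetrahedra in world millimetres. Smoothing removes the voxel
#' staircase so that vertex positions and surface area track the
#' underlying smooth anatomy.
#'
#' @param labels A label [vox_volume()].
#' @param which `"endo"` or `"epi"`.
#' @param sigma Indicator smoothing sd, voxels.
#' @return A [surface_mesh()].
#' @export
#' @examples
#' ph <- phantom_volume(phantom_spec("shell", r_endo = 10, r_epi = 16))
#' m <- extract_surface_mesh(ph$label, "endo")
#' mean(sqrt(rowSums(m$vertices^2)))   # ~ 10 mm
extract_surface_mesh <- function(labels, which = c("endo", "epi"),
                                 sigma = 0.8) {
  which <- match.arg(which)
  stopifnot(inherits(labels, "vox_volume"))
  lab <- tissue_labels()
  inside <- if (which == "endo") labels$data == lab[["blood"]] else
    labels$data %in% c(lab[["blood"]], wall_labels())
  if (!any(inside)) stop("no voxels for the ", which, " surface")
  phi <- smooth3d(array(as.numeric(inside), dim(labels$data)), sigma)
  soup <- marching_tetrahedra(phi, 0.5, labels$spacing, labels$origin)
  if (!nrow(soup)) stop("empty ", which, " isosurface")
  pts <- rbind(soup[, 1:3], soup[, 4:6], soup[, 7:9])
  key <- paste(round(pts[, 1], 5), round(pts[, 2], 5), round(pts[, 3], 5))
  uid <- match(key, unique(key))
  verts <- pts[!duplicated(key), , drop = FALSE]
  nt <- nrow(soup)
  faces <- cbind(uid[seq_len(nt)], uid[nt + seq_len(nt)], uid[2L * nt + seq_len(nt)])
  deg <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
         faces[, 1] == faces[, 3]
  surface_mesh(verts, faces[!deg, , drop = FALSE])
}

#' Anatomical fiducial vertices of a ventricular mesh
#'
#' Picks the apex (vertex farthest below the base, i.e. lowest z) and
#' three basal landmarks (emulating aortic/ostial fiducials) at spread
#' azimuths on the basal rim. The same geometric rule applied in the
#' imaging frame and in the mapping frame yields paired fiducials for
#' landmark registration.
#'
#' @param mesh A [surface_mesh()].
#' @return List: `positions` (4 x 3 matrix), `labels`
#'   (`apex`, `ostium_1..3`), `index` (vertex ids).
#' @export
mesh_fiducials <- function(mesh) {
  vz <- mesh$vertices[, 3]
  apex <- which.min(vz)
  basal <- which(vz >= stats::quantile(vz, 0.95))
  az <- atan2(mesh$vertices[basal, 2], mesh$vertices[basal, 1])
  pick_az <- function(a) basal[which.min(abs(atan2(sin(az - a), cos(az - a))))]
  ost <- vapply(c(0, 2 * pi / 3, -2 * pi / 3), pick_az, integer(1))
  idx <- c(apex, ost)
  list(positions = mesh$vertices[idx, , drop = FALSE],
       labels = c("apex", paste0("ostium_", 1:3)),
       index = idx)
}

#' Triangle areas of a mesh
#' @param mesh A [surface_mesh()].
#' @return Numeric vector of face areas, mm^2.
#' @export
mesh_face_areas <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Total surface area of a mesh
#' @param mesh A [surface_mesh()].
#' @return Total area, mm^2.
#' @export
mesh_area <- function(mesh) sum(mesh_face_areas(mesh))

# Area-weighted per-vertex normals (unit; orientation not made globally
# consistent -- downstream uses only the normal line).
vertex_normals <- function(mesh) {
  a <- mesh$vertices[mesh$faces[, 1], , drop = FALSE]
  b <- mesh$vertices[mesh$faces[, 2], , drop = FALSE]
  cc <- mesh$vertices[mesh$faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  fn <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  out <- matrix(0, nrow(mesh$vertices), 3L)
  for (c_ in 1:3) {
    for (ax in 1:3) {
      acc <- tapply(fn[, ax], mesh$faces[, c_], sum)
      out[as.integer(names(acc)), ax] <- out[as.integer(names(acc)), ax] + acc
    }
  }
  nrm <- sqrt(rowSums(out^2))
  out / pmax(nrm, 1e-12)
}

# Undirected unique edge list of a mesh.
mesh_edges <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# vertex -> incident face ids
vertex_face_index <- function(mesh) {
  f <- rep(seq_len(nrow(mesh$faces)), 3L)
  v <- as.vector(mesh$faces)
  split(f, v)
}

#' Write a mesh as legacy ASCII VTK polydata or ASCII PLY
#'
#' @param mesh A [surface_mesh()].
#' @param path Output path; format chosen by extension (`.vtk`, `.ply`)
#'   unless given.
#' @param format `"vtk"` or `"ply"`.
#' @param attributes Named list of per-vertex numeric vectors written as
#'   point data (VTK) or vertex properties (PLY); defaults to the mesh's
#'   own attributes.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, attributes = mesh$attributes) {
  if (is.null(format))
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "vtk"
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w"); on.exit(close(con))
  if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "vtsubstrate surface",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    writeLines(apply(format(v, digits = 8, trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
    if (length(attributes)) {
      writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
      for (nm in names(attributes)) {
        writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
        writeLines(format(attributes[[nm]], digits = 8, trim = TRUE), con)
      }
    }
  } else {
    props <- names(attributes)
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("property float %s", props),
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    vt <- cbind(v, do.call(cbind, attributes[props]))
    writeLines(apply(format(vt, digits = 8, trim = TRUE), 1, paste, collapse = " "), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}
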