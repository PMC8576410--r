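#' Tissue label vocabulary
#'
#' Integer codes used in label volumes throughout the package. Scar and
#' heterogeneous tissue (HT, the border zone of intermediate signal
#' intensity) are geometric subsets of the myocardium, so the myocardial
#' wall is always `union(myocardium, ht, scar)`.
#'
#' @return Named integer vector with elements `background`, `blood`,
#'   `myocardium`, `ht`, `scar`.
#' @export
#' @examples
#' tissue_labels()["scar"]
tissue_labels <- function() {
  c(background = 0L, blood = 1L, myocardium = 2L, ht = 3L, scar = 4L)
}

#' Labels that make up the myocardial wall
#' @return Integer vector of the wall labels (myocardium, HT, scar).
#' @export
wall_labels <- function() unname(tissue_labels()[c("myocardium", "ht", "scar")])

#' Construct a voxel volume
#'
#' Thin container for a 3D scalar or integer grid with world geometry:
#' voxel `(i, j, k)` (1-based) has world position
#' `origin + (c(i, j, k) - 1) * spacing` (mm). Axis-aligned affines only;
#' general NIfTI affines are reduced to spacing + origin on read.
#'
#' @param data 3D array.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, world position of voxel (1,1,1) in mm.
#' @return A `vox_volume` object.
#' @export
vox_volume <- function(data, spacing = c(1.2, 1.2, 1.2), origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L,
            length(spacing) == 3L, all(spacing > 0),
            length(origin) == 3L, all(is.finite(spacing)), all(is.finite(origin)))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "vox_volume")
}

#' @export
print.vox_volume <- function(x, ...) {
  cat("<vox_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
dim.vox_volume <- function(x) dim(x$data)

#' World coordinates of voxel indices
#'
#' @param vol A [vox_volume()].
#' @param ijk Integer matrix (n x 3) of 1-based voxel indices.
#' @return Numeric matrix (n x 3) of world positions in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  sweep(sweep(ijk - 1, 2L, vol$spacing, `*`), 2L, vol$origin, `+`)
}

#' Voxel indices nearest to world coordinates
#'
#' @param vol A [vox_volume()].
#' @param xyz Numeric matrix (n x 3) of world positions in mm.
#' @return Integer matrix (n x 3) of 1-based indices (not clamped).
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  round(sweep(sweep(xyz, 2L, vol$origin, `-`), 2L, vol$spacing, `/`)) + 1L
}

# Continuous (fractional, 1-based) voxel coordinates of world points.
world_to_cont <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  sweep(sweep(xyz, 2L, vol$origin, `-`), 2L, vol$spacing, `/`) + 1
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1 image via RNifti and reduces its affine to spacing and
#' origin (the affine must be axis-aligned up to sign; the absolute
#' per-axis step is used as spacing).
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param integer_labels If `TRUE`, round and store as integer (label
#'   volumes survive a write/read round trip losslessly).
#' @return A [vox_volume()].
#' @export
read_volume <- function(path, integer_labels = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume, got ", length(dim(arr)), " dimensions")
  if (integer_labels) {
    arr2 <- array(as.integer(round(arr)), dim(arr))
    arr <- arr2
  }
  pd <- RNifti::pixdim(img)[1:3]
  aff <- try(RNifti::xform(img), silent = TRUE)
  origin <- c(0, 0, 0)
  if (!inherits(aff, "try-error") && is.matrix(aff)) origin <- aff[1:3, 4]
  vox_volume(arr, spacing = abs(pd), origin = origin)
}

#' Write a volume as NIfTI
#'
#' @param vol A [vox_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- vol$spacing
  aff[1:3, 4] <- vol$origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Clamp continuous voxel coords to the valid interpolation box.
clamp_cont <- function(p, dims) {
  for (a in 1:3) p[, a] <- pmin(pmax(p[, a], 1), dims[a])
  p
}

# Vectorised trilinear interpolation of a 3D array at continuous voxel
# coordinates (1-based). NA cells get zero weight; all-NA neighbourhoods
# return NA.
trilinear <- function(arr, p) {
  d <- dim(arr)
  p <- clamp_cont(p, d)
  i0 <- pmin(floor(p[, 1]), d[1] - 1L); i0 <- pmax(i0, 1)
  j0 <- pmin(floor(p[, 2]), d[2] - 1L); j0 <- pmax(j0, 1)
  k0 <- pmin(floor(p[, 3]), d[3] - 1L); k0 <- pmax(k0, 1)
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  num <- rep(0, nrow(p)); den <- rep(0, nrow(p))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    v <- arr[cbind(i0 + dx, j0 + dy, k0 + dz)]
    ok <- !is.na(v)
    num[ok] <- num[ok] + w[ok] * v[ok]
    den[ok] <- den[ok] + w[ok]
  }
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Nearest-voxel lookup of a 3D array at world coordinates; out-of-grid
# queries return `outside`.
sample_nearest <- function(vol, xyz, outside = NA) {
  ijk <- world_to_voxel(vol, xyz)
  d <- dim(vol$data)
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] &
        ijk[, 2] >= 1 & ijk[, 2] <= d[2] &
        ijk[, 3] >= 1 & ijk[, 3] <= d[3]
  out <- rep(outside, nrow(ijk))
  if (any(ok)) out[ok] <- vol$data[ijk[ok, , drop = FALSE]]
  out
}

# Separable Gaussian smoothing of a 3D array (replicate padding),
# implemented as a sum of index-shifted copies. sigma in voxels.
smooth3d <- function(arr, sigma = 0.8, radius = max(2L, ceiling(3 * sigma))) {
  off <- (-radius):radius
  k <- exp(-off^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  for (a in 1:3) {
    out <- array(0, d)
    idx_all <- seq_len(d[a])
    for (m in seq_along(off)) {
      src <- pmin(pmax(idx_all + off[m], 1L), d[a])
      out <- out + k[m] * switch(a,
        arr[src, , , drop = FALSE],
        arr[, src, , drop = FALSE],
        arr[, , src, drop = FALSE])
    }
    arr <- out
  }
  arr
}

# 6-connected face-neighbour shifts.
face_offsets <- function() {
  rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
        c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
}

# For a logical 3D array, return a logical array marking voxels with at
# least one TRUE face-neighbour in `other`.
touches <- function(mask, other) {
  d <- dim(mask)
  out <- array(FALSE, d)
  sh <- face_offsets()
  pad_shift <- function(arr, s) {
    res <- array(FALSE, d)
    src1 <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    dst1 <- src1
    for (a in 1:3) {
      if (s[a] == 1)  { dst1[[a]] <- 2:d[a];        src1[[a]] <- 1:(d[a] - 1) }
      if (s[a] == -1) { dst1[[a]] <- 1:(d[a] - 1);  src1[[a]] <- 2:d[a] }
    }
    res[dst1[[1]], dst1[[2]], dst1[[3]]] <- arr[src1[[1]], src1[[2]], src1[[3]]]
    res
  }
  for (r in seq_len(nrow(sh))) out <- out | pad_shift(other, sh[r, ])
  out & mask
}
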