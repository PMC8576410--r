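#' Classify myocardial tissue by maximum-referenced signal intensity
#'
#' Thresholds the signal intensity of late gadolinium enhancement imaging
#' within a myocardial mask: with `M` the highest signal intensity inside
#' the mask, voxels with `SI >= scar_frac * M` become scar, voxels with
#' `ht_frac * M <= SI < scar_frac * M` become heterogeneous tissue (HT),
#' and the remainder normal myocardium. The defaults (60% / 40% of the
#' maximum) follow the thresholding strategy that best identifies
#' electrophysiologically relevant ventricular substrate. Thresholds are
#' inclusive at the lower edge of each class, and labels outside the mask
#' are left unchanged.
#'
#' @param intensity An intensity [vox_volume()].
#' @param myocardium_mask Logical 3D array (same grid) marking the wall,
#'   or a label [vox_volume()] whose [wall_labels()] voxels define it.
#' @param scar_frac,ht_frac Fractions of the in-mask maximum defining the
#'   scar and HT thresholds; require `0 < ht_frac < scar_frac <= 1`.
#' @param min_component Optional cleanup (default 0 = off): connected
#'   components (6-connectivity) of the combined scar+HT set smaller
#'   than this voxel count are reassigned to normal myocardium. Useful
#'   because max-referenced thresholds turn isolated noise excursions
#'   into spurious HT.
#' @return A label [vox_volume()] on the same grid, using
#'   [tissue_labels()] codes inside the mask; outside the mask, labels
#'   are copied from `myocardium_mask` when it is a label volume, else
#'   background.
#' @export
#' @examples
#' ph <- phantom_volume(phantom_spec("slab",
#'   intensity = list(noise_sd = 0),
#'   scar_patches = list(scar_patch(c(0, 0), 8, 0.5, 2))))
#' seg <- classify_tissue(ph$intensity, ph$label)
#' all(seg$data == ph$label$data)
classify_tissue <- function(intensity, myocardium_mask,
                            scar_frac = 0.60, ht_frac = 0.40,
                            min_component = 0L) {
  stopifnot(inherits(intensity, "vox_volume"),
            ht_frac > 0, scar_frac > ht_frac, scar_frac <= 1)
  lab <- tissue_labels()
  base <- NULL
  if (inherits(myocardium_mask, "vox_volume")) {
    base <- myocardium_mask$data
    mask <- array(base %in% wall_labels(), dim(base))
  } else {
    mask <- myocardium_mask
  }
  stopifnot(is.logical(mask) | is.array(mask))
  mask <- array(as.logical(mask), dim(intensity$data))
  if (!identical(dim(mask), dim(intensity$data)))
    stop("mask and intensity grids differ")
  if (!any(mask)) stop("myocardium mask is empty")
  si <- intensity$data[mask]
  if (!all(is.finite(si))) stop("non-finite signal intensity inside the mask")
  M <- max(si)
  if (M <= 0) stop("maximum signal intensity within the mask is not positive")
  cls <- rep(lab[["myocardium"]], length(si))
  cls[si >= ht_frac * M] <- lab[["ht"]]
  cls[si >= scar_frac * M] <- lab[["scar"]]
  out <- if (is.null(base)) array(lab[["background"]], dim(intensity$data)) else base
  out[mask] <- cls
  out <- array(as.integer(out), dim(intensity$data))
  if (min_component > 0L) {
    enh <- out == lab[["scar"]] | out == lab[["ht"]]
    if (any(enh)) {
      small <- .small_components(enh, min_component)
      out[small] <- lab[["myocardium"]]
    }
  }
  vox_volume(out, intensity$spacing, intensity$origin)
}

# logical array marking members of 6-connected components of `mask`
# smaller than `min_size` voxels
.small_components <- function(mask, min_size) {
  d <- dim(mask)
  ids <- array(NA_integer_, d)
  idx <- which(mask)
  ids[idx] <- seq_along(idx)
  ijk <- which(mask, arr.ind = TRUE)
  ei <- integer(0); ej <- integer(0)
  for (axis in 1:3) {
    off <- c(0L, 0L, 0L); off[axis] <- 1L
    nijk <- sweep(ijk, 2L, off, `+`)
    ok <- nijk[, axis] <= d[axis]
    nlin <- nijk[ok, 1] + d[1] * (nijk[ok, 2] - 1) + d[1] * d[2] * (nijk[ok, 3] - 1)
    nb <- ids[nlin]
    has <- !is.na(nb)
    ei <- c(ei, ids[idx[ok][has]]); ej <- c(ej, nb[has])
  }
  g <- igraph::make_graph(rbind(ei, ej), n = length(idx), directed = FALSE)
  cmp <- igraph::components(g)
  small <- cmp$csize[cmp$membership] < min_size
  res <- array(FALSE, d)
  res[idx[small]] <- TRUE
  res
}
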