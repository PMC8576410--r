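#' Describe a scar patch for the phantom
#'
#' A patch is placed on the wall of a phantom geometry and fills the wall
#' from the endocardial side up to `transmural_fraction` of the local wall
#' depth, surrounded by a rim of heterogeneous tissue (HT) of width
#' `ht_rim_width` that emulates the border zone of intermediate signal
#' intensity around dense scar.
#'
#' @param center Patch centre: for `slab` geometries a length-2 in-plane
#'   position (mm); for `shell`/`ellipsoid` a length-3 direction vector
#'   from the cavity centre (need not be normalised).
#' @param extent Patch half-extent: lateral radius in mm (slab) or angular
#'   half-width in degrees (shell/ellipsoid).
#' @param transmural_fraction Fraction of the wall depth occupied by scar,
#'   in `[0, 1]` (1 = transmural).
#' @param ht_rim_width Width of the HT rim around the scar, mm (>= 0).
#' @param thinning Local wall thinning under the patch, mm (healed
#'   infarcts thin the wall); ramps smoothly to zero across `taper`.
#' @param taper Width of the thinning transition band at the patch
#'   border: degrees for shell/ellipsoid patches, mm for slab patches.
#'   The transition is where the steep thickness gradients of the border
#'   zone live.
#' @return A `scar_patch` list.
#' @export
scar_patch <- function(center, extent, transmural_fraction = 0.5,
                       ht_rim_width = 2, thinning = 0,
                       taper = if (length(center) == 2L) 6 else 10) {
  stopifnot(is.numeric(center), length(center) %in% c(2L, 3L),
            is.numeric(extent), extent > 0,
            transmural_fraction >= 0, transmural_fraction <= 1,
            ht_rim_width >= 0, thinning >= 0, taper > 0)
  structure(list(center = as.numeric(center), extent = extent,
                 transmural_fraction = transmural_fraction,
                 ht_rim_width = ht_rim_width,
                 thinning = thinning, taper = taper),
            class = "scar_patch")
}

# smoothstep ramp: 1 inside the patch, 0 beyond extent + taper
.sstep <- function(t) { t <- pmin(pmax(t, 0), 1); t * t * (3 - 2 * t) }

#' Specify a synthetic left-ventricular phantom
#'
#' Defines the geometry, scar patches, intensity model and random seed of
#' a digital phantom with known ground truth. Three wall geometries are
#' supported: an axis-aligned slab, a spherical shell, and a truncated
#' ellipsoid (LV-like, cut at a base plane; the apex is the wall point
#' farthest from the base plane).
#'
#' Intensity defaults (normal 22, HT 42, scar 80 arbitrary units, noise sd
#' 3) are chosen so that thresholding at 40%/60% of the maximum wall
#' signal intensity recovers the constructed classes exactly on a
#' noiseless phantom, with at least two noise standard deviations of
#' margin to each class boundary under noise.
#'
#' @param shape One of `"slab"`, `"shell"`, `"ellipsoid"`.
#' @param spacing Isotropic voxel spacing in mm (default 1.2, the working
#'   resolution of high-resolution 3D LGE imaging).
#' @param slab_thickness,slab_extent Slab wall thickness and lateral
#'   extents (mm). The slab spans the full lateral grid so that lateral
#'   grid edges are zero-flux, with blood below and background above.
#' @param r_endo,r_epi Shell endocardial/epicardial radii (mm).
#' @param semi_axes,wall_thickness,base_fraction Ellipsoid endocardial
#'   semi-axes (mm), wall thickness added to each semi-axis (mm), and the
#'   base-plane truncation as a fraction of the long (z) semi-axis.
#' @param scar_patches List of [scar_patch()] objects.
#' @param intensity Named list: mean signal intensity per class
#'   (`normal`, `ht`, `scar`, `blood`, `background`) and `noise_sd`.
#' @param margin Padding around the geometry, in voxels.
#' @param seed Integer seed controlling all phantom randomness.
#' @return A `phantom_spec` list.
#' @export
#' @examples
#' spec <- phantom_spec("shell", r_endo = 20, r_epi = 30)
phantom_spec <- function(shape = c("shell", "slab", "ellipsoid"),
                         spacing = 1.2,
                         slab_thickness = 10, slab_extent = c(48, 48),
                         r_endo = 20, r_epi = 30,
                         semi_axes = c(22, 22, 34), wall_thickness = 8,
                         base_fraction = 0.35,
                         scar_patches = list(),
                         intensity = list(normal = 22, ht = 42, scar = 80,
                                          blood = 10, background = 0,
                                          noise_sd = 3),
                         margin = 3L, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(spacing > 0, slab_thickness > 0, all(slab_extent > 0),
            r_endo > 0, r_epi > r_endo, all(semi_axes > 0),
            wall_thickness > 0, base_fraction > -1, base_fraction < 1)
  defaults <- list(normal = 22, ht = 42, scar = 80, blood = 10,
                   background = 0, noise_sd = 3)
  intensity <- utils::modifyList(defaults, intensity)
  for (p in scar_patches) {
    if (!inherits(p, "scar_patch")) stop("scar_patches must be scar_patch objects")
    if (shape == "slab" && length(p$center) != 2L)
      stop("slab patches need a length-2 in-plane center")
    if (shape != "slab" && length(p$center) != 3L)
      stop("shell/ellipsoid patches need a length-3 direction center")
    if (shape == "slab" && any(p$extent + abs(p$center) > slab_extent / 2 + 1e-9))
      stop("patch extent exceeds the slab geometry")
    if (shape != "slab" && p$extent > 180)
      stop("patch angular extent exceeds the geometry (max 180 degrees)")
  }
  structure(list(shape = shape, spacing = spacing,
                 slab_thickness = slab_thickness, slab_extent = slab_extent,
                 r_endo = r_endo, r_epi = r_epi,
                 semi_axes = semi_axes, wall_thickness = wall_thickness,
                 base_fraction = base_fraction,
                 scar_patches = scar_patches, intensity = intensity,
                 margin = as.integer(margin), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Direction-dependent endo/epi radii of the ellipsoid (radial metric).
ellipsoid_radius <- function(dirs, axes) {
  1 / sqrt(rowSums(sweep(dirs, 2L, axes, `/`)^2))
}

#' Generate label and intensity volumes from a phantom specification
#'
#' Builds the voxelised phantom: blood pool, myocardial wall, scar patches
#' occupying the wall from the endocardial side up to the requested
#' transmural fraction, an HT rim around each scar, and an intensity
#' volume of class means plus Gaussian noise. Ground truth for every
#' downstream quantity is returned alongside.
#'
#' @param spec A [phantom_spec()].
#' @return List with elements `label` ([vox_volume()], integer codes from
#'   [tissue_labels()]), `intensity` ([vox_volume()]), and `truth`, a list
#'   holding the spec, the per-endocardial-node ground-truth tibble
#'   (`endo_truth`: position, true thickness, true scar/HT fractions) and
#'   geometry helpers.
#' @export
#' @examples
#' ph <- phantom_volume(phantom_spec("slab", slab_thickness = 10))
#' table(ph$label$data)
phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  lab <- tissue_labels()
  h <- spec$spacing
  m <- spec$margin * h

  if (spec$shape == "slab") {
    ex <- spec$slab_extent
    nx <- ceiling(ex[1] / h); ny <- ceiling(ex[2] / h)
    nb <- max(2L, spec$margin)            # blood layers below the wall
    nwall_max <- ceiling(spec$slab_thickness / h) + 1L
    nz <- nb + nwall_max + max(2L, spec$margin)
    origin <- c(0, 0, -(nb - 0.5) * h)    # wall inner face at z = 0
    d <- c(nx, ny, nz)
    ctr <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * h)
    Z <- array(rep(ctr[[3]], each = nx * ny), d)
    blood <- Z < 0
    X <- array(rep(ctr[[1]], times = ny * nz), d)
    Y <- array(rep(rep(ctr[[2]], each = nx), times = nz), d)
    lat <- function(p) sqrt((X - (ex[1] / 2 + p$center[1]))^2 +
                            (Y - (ex[2] / 2 + p$center[2]))^2)
    T_loc <- array(spec$slab_thickness, d)
    for (p in spec$scar_patches) if (p$thinning > 0)
      T_loc <- T_loc - p$thinning * .sstep((p$extent + p$taper - lat(p)) / p$taper)
    wall <- Z > 0 & Z < T_loc
    depth <- Z / T_loc
    in_patch <- function(p) lat(p) <= p$extent
    thick_true <- function(xyz) {
      tt <- rep(spec$slab_thickness, nrow(xyz))
      for (p in spec$scar_patches) if (p$thinning > 0) {
        dl <- sqrt((xyz[, 1] - (ex[1] / 2 + p$center[1]))^2 +
                   (xyz[, 2] - (ex[2] / 2 + p$center[2]))^2)
        tt <- tt - p$thinning * .sstep((p$extent + p$taper - dl) / p$taper)
      }
      tt
    }
  } else {
    r_out <- if (spec$shape == "shell") spec$r_epi else
      max(spec$semi_axes) + spec$wall_thickness
    n <- 2L * ceiling((r_out + m) / h) + 1L
    origin <- rep(-(n - 1) / 2 * h, 3)
    d <- c(n, n, n)
    ctr <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * h)
    X <- array(rep(ctr[[1]], times = n * n), d)
    Y <- array(rep(rep(ctr[[2]], each = n), times = n), d)
    Z <- array(rep(ctr[[3]], each = n * n), d)
    R <- sqrt(X^2 + Y^2 + Z^2)
    patch_angle <- function(p) {       # angle (deg) from the patch axis
      u <- p$center / sqrt(sum(p$center^2))
      cosang <- (X * u[1] + Y * u[2] + Z * u[3]) / pmax(R, 1e-9)
      acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    }
    thin_arr <- array(0, d)
    for (p in spec$scar_patches) if (p$thinning > 0)
      thin_arr <- thin_arr +
        p$thinning * .sstep((p$extent + p$taper - patch_angle(p)) / p$taper)
    if (spec$shape == "shell") {
      blood <- R < spec$r_endo
      rin <- spec$r_endo
      rout_loc <- spec$r_epi - thin_arr
      wall <- R >= rin & R < rout_loc
      depth <- (R - rin) / pmax(rout_loc - rin, 1e-9)
      r_in_dir <- function(dirs) rep(spec$r_endo, nrow(dirs))
      r_out_dir <- function(dirs) rep(spec$r_epi, nrow(dirs))
    } else {
      ax_in <- spec$semi_axes
      ax_out <- spec$semi_axes + spec$wall_thickness
      z_base <- spec$base_fraction * ax_in[3]
      below <- Z <= z_base
      rs <- R; rs[rs == 0] <- 1
      dirs_all <- cbind(as.vector(X / rs), as.vector(Y / rs), as.vector(Z / rs))
      rin <- array(ellipsoid_radius(dirs_all, ax_in), d)
      rout_loc <- array(ellipsoid_radius(dirs_all, ax_out), d) - thin_arr
      blood <- R < rin & below
      wall <- R >= rin & R < rout_loc & below
      depth <- (R - rin) / pmax(rout_loc - rin, 1e-9)
      r_in_dir <- function(dirs) ellipsoid_radius(dirs, ax_in)
      r_out_dir <- function(dirs) ellipsoid_radius(dirs, ax_out)
    }
    in_patch <- function(p) {
      u <- p$center / sqrt(sum(p$center^2))
      cosang <- (X * u[1] + Y * u[2] + Z * u[3]) / pmax(R, 1e-9)
      cosang >= cos(p$extent * pi / 180)
    }
    thick_true <- function(xyz) {
      r <- sqrt(rowSums(xyz^2))
      dirs <- xyz / pmax(r, 1e-9)
      tt <- r_out_dir(dirs) - r_in_dir(dirs)
      for (p in spec$scar_patches) if (p$thinning > 0) {
        u <- p$center / sqrt(sum(p$center^2))
        ang <- acos(pmin(pmax(as.numeric(dirs %*% u), -1), 1)) * 180 / pi
        tt <- tt - p$thinning * .sstep((p$extent + p$taper - ang) / p$taper)
      }
      tt
    }
  }

  labels <- array(lab["background"], d)
  labels[blood] <- lab["blood"]
  labels[wall] <- lab["myocardium"]

  scar <- array(FALSE, d)
  for (p in spec$scar_patches) {
    if (p$transmural_fraction > 0)
      scar <- scar | (wall & in_patch(p) & depth <= p$transmural_fraction)
  }
  ht <- array(FALSE, d)
  rimw <- vapply(spec$scar_patches, `[[`, numeric(1), "ht_rim_width")
  if (any(scar) && length(rimw) && max(rimw) > 0) {
    w <- max(rimw)
    # HT = wall voxels within the rim width of scar (Euclidean, brute force
    # over a dilated bounding box of the scar set).
    sc_idx <- which(scar, arr.ind = TRUE)
    pad <- ceiling(w / h) + 1L
    lo <- pmax(apply(sc_idx, 2, min) - pad, 1L)
    hi <- pmin(apply(sc_idx, 2, max) + pad, d)
    cand <- which(wall & !scar, arr.ind = TRUE)
    keep <- cand[, 1] >= lo[1] & cand[, 1] <= hi[1] &
            cand[, 2] >= lo[2] & cand[, 2] <= hi[2] &
            cand[, 3] >= lo[3] & cand[, 3] <= hi[3]
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand)) {
      pc <- sweep(sweep(cand - 1, 2, rep(h, 3), `*`), 2, origin, `+`)
      ps <- sweep(sweep(sc_idx - 1, 2, rep(h, 3), `*`), 2, origin, `+`)
      dmin <- nearest_dist(pc, ps)$dist
      sel <- cand[dmin <= w, , drop = FALSE]
      if (nrow(sel)) ht[sel] <- TRUE
    }
  }
  labels[ht] <- lab["ht"]
  labels[scar] <- lab["scar"]

  # intensity = class mean + Gaussian noise
  mu <- spec$intensity
  intens <- array(mu$background, d)
  intens[blood] <- mu$blood
  intens[labels == lab["myocardium"]] <- mu$normal
  intens[labels == lab["ht"]] <- mu$ht
  intens[labels == lab["scar"]] <- mu$scar
  if (mu$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    intens <- intens + array(stats::rnorm(prod(d), 0, mu$noise_sd), d)
  }

  label_vol <- vox_volume(array(as.integer(labels), d), rep(h, 3), origin)
  inten_vol <- vox_volume(intens, rep(h, 3), origin)

  if (!any(wall)) stop("phantom produced an empty wall")

  # per-endocardial-node ground truth
  endo <- touches(wall, blood)
  eidx <- which(endo, arr.ind = TRUE)
  exyz <- sweep(sweep(eidx - 1, 2, rep(h, 3), `*`), 2, origin, `+`)
  tt <- thick_true(exyz)
  tsf <- rep(0, nrow(exyz)); thf <- rep(0, nrow(exyz))
  for (p in spec$scar_patches) {
    f <- p$transmural_fraction
    if (spec$shape == "slab") {
      dlat <- sqrt((exyz[, 1] - (spec$slab_extent[1] / 2 + p$center[1]))^2 +
                   (exyz[, 2] - (spec$slab_extent[2] / 2 + p$center[2]))^2)
      core <- dlat <= p$extent
    } else {
      u <- p$center / sqrt(sum(p$center^2))
      rr <- sqrt(rowSums(exyz^2))
      core <- (exyz %*% u)[, 1] / pmax(rr, 1e-9) >= cos(p$extent * pi / 180)
    }
    tsf[core] <- pmax(tsf[core], f)
    thf[core] <- pmax(thf[core],
                      pmin(p$ht_rim_width / tt[core], pmax(1 - f, 0)))
  }
  endo_truth <- tibble::tibble(
    i = eidx[, 1], j = eidx[, 2], k = eidx[, 3],
    x = exyz[, 1], y = exyz[, 2], z = exyz[, 3],
    true_thickness = tt, true_scar_frac = tsf, true_ht_frac = thf)

  truth <- list(spec = spec, endo_truth = endo_truth,
                thickness_fun = thick_true)
  list(label = label_vol, intensity = inten_vol, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Export a synthetic electroanatomic point table
#'
#' Samples mapping points on the phantom's endocardial mesh, assigns
#' categories from ground truth (diastolic points on the scar border
#' zone / thinned wall, normal points in remote healthy wall), appends
#' fiducial rows (apex and three basal "ostial" landmarks), applies a
#' rigid displacement emulating the mapping-system frame, and adds
#' isotropic positional noise.
#'
#' @param truth Ground-truth list from [phantom_volume()].
#' @param mesh Endocardial [surface_mesh] (from [extract_surface_mesh()]).
#' @param transform A [rigid_transform()]: the true CMR-to-mapping-frame
#'   displacement.
#' @param n_diastolic,n_normal Numbers of diastolic / normal points.
#' @param noise_sd Isotropic positional noise sd, mm.
#' @param diastolic_window Length-2 ms window (from QRS end) in which the
#'   diastolic activation times are drawn.
#' @param seed Integer seed.
#' @return Tibble with columns `x, y, z` (mapping-frame mm), `time_ms`,
#'   `category` (`"normal"`, `"diastolic"`, `"fiducial"`), `label`. The
#'   true transform is attached as attribute `"transform_true"`.
#' @export
phantom_eam_points <- function(truth, mesh, transform = rigid_transform(),
                               n_diastolic = 100, n_normal = 100,
                               noise_sd = 0, diastolic_window = c(150, 400),
                               seed = 1L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (n_diastolic + n_normal < 1) stop("need at least one mapping point")
  et <- truth$endo_truth
  nn <- nearest_dist(mesh$vertices, as.matrix(et[, c("x", "y", "z")]))
  v_scar <- et$true_scar_frac[nn$index]
  v_ht <- et$true_ht_frac[nn$index]
  # distance from each vertex to the patch region (0 inside)
  in_patch <- et$true_scar_frac > 0 | et$true_ht_frac > 0
  if (any(in_patch)) {
    dpatch <- nearest_dist(mesh$vertices,
                           as.matrix(et[in_patch, c("x", "y", "z")]))$dist
  } else dpatch <- rep(Inf, nrow(mesh$vertices))
  dia_cand <- which((v_scar > 0 & v_scar < 1) | (v_scar == 0 & dpatch <= 4))
  nor_cand <- which(v_scar == 0 & v_ht == 0 & dpatch >= 12)
  if (length(dia_cand) < n_diastolic)
    stop("phantom has only ", length(dia_cand), " border-zone vertices for ",
         n_diastolic, " diastolic points")
  if (length(nor_cand) < n_normal)
    stop("phantom has only ", length(nor_cand), " remote vertices for ",
         n_normal, " normal points")

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  di <- sample(dia_cand, n_diastolic)
  no <- sample(nor_cand, n_normal)

  fid <- mesh_fiducials(mesh)
  idx <- c(di, no, fid$index)
  cat_ <- c(rep("diastolic", n_diastolic), rep("normal", n_normal),
            rep("fiducial", 4L))
  labl <- c(sprintf("pt_%03d", seq_len(n_diastolic + n_normal)), fid$labels)
  tms <- c(stats::runif(n_diastolic, diastolic_window[1], diastolic_window[2]),
           stats::runif(n_normal, 0, 90), rep(NA_real_, 4L))
  pos <- mesh$vertices[idx, , drop = FALSE]
  pos <- apply_transform(transform, pos)
  if (noise_sd > 0)
    pos <- pos + matrix(stats::rnorm(length(pos), 0, noise_sd), ncol = 3L)
  out <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        time_ms = tms, category = cat_, label = labl)
  attr(out, "transform_true") <- transform
  attr(out, "true_vertex") <- idx
  out
}

#' Construct a synthetic activation map with a known line of block
#'
#' Builds a planar strip of mapping points activated by two kinematic
#' planar wavefronts whose collision boundary is a constructed line of
#' conduction block spanning the strip: activation on either side of the
#' line differs by `block_offset_ms` (as across the central line of block
#' of a figure-of-eight re-entry). With `block = FALSE` a single uniform
#' wavefront is produced and no adjacent-point time gap exceeds the block
#' threshold.
#'
#' @param width,depth Strip extent in mm; the block line spans the full
#'   `width` at mid-`depth`, so its true length equals `width`.
#' @param point_spacing Nominal mapping-point spacing, mm.
#' @param block Logical: construct the line of block?
#' @param block_offset_ms Activation-time offset across the line, ms.
#' @param speed Wavefront speed, mm/ms.
#' @param jitter Uniform positional jitter half-width, mm.
#' @param seed Integer seed.
#' @return List with `points` (tibble `x, y, z, time_ms`) and `truth`
#'   (`block_lines`: list of polyline matrices; `block_length_mm`;
#'   `n_regions`).
#' @export
phantom_activation_map <- function(width = 30, depth = 40, point_spacing = 2,
                                   block = TRUE, block_offset_ms = 40,
                                   speed = 0.5, jitter = 0.3, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gx <- seq(0, width, by = point_spacing)
  gy <- seq(0, depth, by = point_spacing)
  g <- expand.grid(x = gx, y = gy)
  g$x <- g$x + stats::runif(nrow(g), -jitter, jitter)
  g$y <- g$y + stats::runif(nrow(g), -jitter, jitter)
  y_line <- depth / 2
  t1 <- g$y / speed                              # front entering from y = 0
  if (block) {
    # far side activated by the delayed front entering from y = depth
    tt <- ifelse(g$y <= y_line, t1, block_offset_ms + (depth - g$y) / speed)
    truth <- list(block_lines = list(rbind(c(0, y_line, 0),
                                           c(width, y_line, 0))),
                  block_length_mm = width, n_regions = 1L)
  } else {
    tt <- t1
    truth <- list(block_lines = list(), block_length_mm = 0, n_regions = 0L)
  }
  list(points = tibble::tibble(x = g$x, y = g$y, z = 0, time_ms = tt),
       truth = truth)
}
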