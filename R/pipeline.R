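#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end substrate analysis with the
#' study defaults: scar / HT thresholds at 60% / 40% of the maximal wall
#' signal intensity, the non-transmural cutoff at 95% combined scar+HT
#' transmurality, a 1 mm point-to-node mapping radius, a 15 ms
#' adjacent-point activation difference defining conduction block, and a
#' steep-thickness-gradient threshold of 0.5 mm/mm (a package choice;
#' there is no established quantitative definition of "steep").
#'
#' @param phantom A [phantom_spec()] describing the synthetic input; the
#'   default is an infarcted spherical-shell ventricle (20/30 mm radii)
#'   with one 50%-transmural antero-septal patch, a 2.5 mm HT rim and
#'   3 mm wall thinning.
#' @param scar_frac,ht_frac Segmentation thresholds (fractions of max SI).
#' @param min_component Minimum scar/HT connected-component size kept by
#'   segmentation (voxels); the pipeline default (10) removes isolated
#'   noise-driven HT voxels.
#' @param transmural_cutoff Non-transmural below this combined scar+HT
#'   transmurality, percent.
#' @param mapping_radius Point-to-node assignment radius, mm.
#' @param dt_block Conduction-block activation-time difference, ms.
#' @param neighbor_radius Activation-map adjacency radius, mm.
#' @param steep_threshold Steep-gradient threshold, mm/mm.
#' @param diastolic_window Diastolic window (QRS end to window end), ms.
#' @param eam_transform True mapping-frame displacement applied by the
#'   phantom exporter (recovered by registration).
#' @param n_diastolic,n_normal Mapping points per category.
#' @param eam_noise_sd Positional noise of mapping points, mm.
#' @param seed Master seed for all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = NULL,
                            scar_frac = 0.60, ht_frac = 0.40,
                            min_component = 10L,
                            transmural_cutoff = 95,
                            mapping_radius = 1.0,
                            dt_block = 15, neighbor_radius = 5,
                            steep_threshold = 0.5,
                            diastolic_window = c(150, 400),
                            eam_transform = rigid_transform(
                              rotation_about(c(0, 0, 1), 15), c(5, -3, 2)),
                            n_diastolic = 100, n_normal = 100,
                            eam_noise_sd = 0.2,
                            seed = 1L) {
  if (is.null(phantom))
    phantom <- phantom_spec(
      "shell", r_endo = 20, r_epi = 30,
      scar_patches = list(scar_patch(c(1, 0, 0.2), extent = 40,
                                     transmural_fraction = 0.5,
                                     ht_rim_width = 2.5, thinning = 3)),
      seed = seed)
  structure(list(phantom = phantom, scar_frac = scar_frac, ht_frac = ht_frac,
                 min_component = as.integer(min_component),
                 transmural_cutoff = transmural_cutoff,
                 mapping_radius = mapping_radius, dt_block = dt_block,
                 neighbor_radius = neighbor_radius,
                 steep_threshold = steep_threshold,
                 diastolic_window = diastolic_window,
                 eam_transform = eam_transform,
                 n_diastolic = n_diastolic, n_normal = n_normal,
                 eam_noise_sd = eam_noise_sd, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Loads a YAML file whose top-level keys are [pipeline_config()]
#' arguments. The `phantom` key is a map of [phantom_spec()] arguments;
#' its `scar_patches` entry is a list of [scar_patch()] argument maps,
#' and `eam_transform` may be given as
#' `{axis: [x,y,z], angle_deg: a, translation: [x,y,z]}`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$phantom)) {
    pa <- cfg$phantom
    if (!is.null(pa$scar_patches))
      pa$scar_patches <- lapply(pa$scar_patches, function(p) {
        p$center <- as.numeric(p$center)
        do.call(scar_patch, p)
      })
    for (nm in c("spacing", "slab_extent", "semi_axes"))
      if (!is.null(pa[[nm]])) pa[[nm]] <- as.numeric(pa[[nm]])
    cfg$phantom <- do.call(phantom_spec, pa)
  }
  if (!is.null(cfg$eam_transform)) {
    tr <- cfg$eam_transform
    cfg$eam_transform <- rigid_transform(
      rotation_about(as.numeric(tr$axis), tr$angle_deg),
      as.numeric(tr$translation))
  }
  if (!is.null(cfg$diastolic_window))
    cfg$diastolic_window <- as.numeric(cfg$diastolic_window)
  do.call(pipeline_config, cfg)
}

#' Run the full substrate-analysis pipeline
#'
#' Chains every stage on a synthetic phantom: volume generation, signal
#' intensity classification, Laplace wall thickness and transmurality,
#' endocardial mesh and thickness-gradient field, electroanatomic export,
#' landmark + ICP registration, point-to-node mapping, structural metrics
#' at mapped points, and the group statistics of the headline
#' comparisons (thickness, distance to HT, and distance to steep
#' thickness gradients at diastolic vs normal locations, plus the
#' fraction of diastolic points in non-transmural scar/HT).
#'
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress.
#' @return A `substrate_result` list: `phantom`, `segmentation`, `field`,
#'   `endo_map`, `mesh`, `gradient`, `steep`, `registration`, `points`
#'   (mapped points with per-point metrics), `comparisons` (stat tests),
#'   `summary` (tibble of headline quantities), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(...)

  say("phantom: generating volumes")
  ph <- phantom_volume(config$phantom)

  say("segmentation: thresholding signal intensity")
  seg <- classify_tissue(ph$intensity, ph$label,
                         scar_frac = config$scar_frac,
                         ht_frac = config$ht_frac,
                         min_component = config$min_component)

  say("laplace: solving wall potential")
  fld <- solve_laplace(seg)
  emap <- endocardial_map(seg, fld,
                          transmural_cutoff = config$transmural_cutoff)

  say("mesh: extracting endocardial surface")
  mesh <- extract_surface_mesh(seg, "endo")
  vmet <- map_to_mesh(emap, mesh)

  say("metrics: thickness gradient and distances")
  gf <- rbf_gradient(mesh, vmet$thickness_mm)
  steep <- steep_regions(gf, steep_threshold = config$steep_threshold)
  ht_pos <- label_positions(seg, tissue_labels()[["ht"]])

  say("registration: landmark + ICP")
  eam <- phantom_eam_points(ph$truth, mesh,
                            transform = config$eam_transform,
                            n_diastolic = config$n_diastolic,
                            n_normal = config$n_normal,
                            noise_sd = config$eam_noise_sd,
                            diastolic_window = config$diastolic_window,
                            seed = config$seed)
  fix_fid <- mesh_fiducials(mesh)
  mov_fid <- as.matrix(eam[match(fix_fid$labels, eam$label), c("x", "y", "z")])
  lm <- landmark_align(fix_fid$positions, mov_fid)
  mappts <- eam[eam$category != "fiducial", , drop = FALSE]
  icp <- icp_refine(as.matrix(mappts[, c("x", "y", "z")]), mesh,
                    init = lm$transform)
  mapped <- map_points_to_nodes(mappts, mesh, icp$transform,
                                radius = config$mapping_radius)

  say("analysis: per-point metrics and statistics")
  assigned <- !is.na(mapped$node_id)
  if (mean(assigned) < 1)
    say(sum(!assigned), " point(s) beyond the mapping radius left unassigned")
  mapped$thickness_mm <- NA_real_
  mapped$scar_pct <- NA_real_
  mapped$ht_pct <- NA_real_
  node_pos <- mesh$vertices[ifelse(assigned, mapped$node_id, 1L), , drop = FALSE]
  mapped$thickness_mm[assigned] <- vmet$thickness_mm[mapped$node_id[assigned]]
  mapped$scar_pct[assigned] <- vmet$scar_pct[mapped$node_id[assigned]]
  mapped$ht_pct[assigned] <- vmet$ht_pct[mapped$node_id[assigned]]
  dht <- distance_to_set(node_pos, ht_pos)$dist_mm
  mapped$dist_ht_mm <- ifelse(assigned, dht, NA_real_)
  steep_pos <- mesh$vertices[steep$vertex, , drop = FALSE]
  dst <- distance_to_set(node_pos, steep_pos)$dist_mm
  mapped$dist_steep_mm <- ifelse(assigned, dst, NA_real_)
  mapped$phase <- factor(NA_character_, c("early", "mid", "late"))
  dia <- which(mapped$category == "diastolic")
  mapped$phase[dia] <- classify_diastolic_phase(
    pmin(pmax(mapped$time_ms[dia], config$diastolic_window[1]),
         config$diastolic_window[2] - 1e-9),
    config$diastolic_window[1], config$diastolic_window[2])

  pts <- mapped[assigned, , drop = FALSE]
  two_groups <- function(d, v) {
    ok <- is.finite(d[[v]])
    length(unique(d$category[ok])) == 2L
  }
  cmp_thick <- compare_groups(pts, thickness_mm, category)
  cmp_dht <- if (two_groups(pts, "dist_ht_mm"))
    compare_groups(pts, dist_ht_mm, category) else NULL
  noscar <- pts[pts$scar_pct == 0, , drop = FALSE]
  cmp_steep <- if (two_groups(noscar, "dist_steep_mm"))
    compare_groups(noscar, dist_steep_mm, category) else NULL

  med <- function(v) stats::median(v, na.rm = TRUE)
  dpt <- pts[pts$category == "diastolic", ]
  npt <- pts[pts$category == "normal", ]
  summary <- tibble::tibble(
    quantity = c("median_thickness_diastolic_mm", "median_thickness_normal_mm",
                 "p_thickness",
                 "median_scar_transmurality_diastolic_pct",
                 "median_ht_transmurality_diastolic_pct",
                 "median_dist_ht_diastolic_mm", "median_dist_ht_normal_mm",
                 "p_dist_ht",
                 "median_dist_steep_diastolic_noscar_mm",
                 "median_dist_steep_normal_noscar_mm", "p_dist_steep",
                 "pct_diastolic_non_transmural"),
    value = c(med(dpt$thickness_mm), med(npt$thickness_mm),
              cmp_thick$test$p.value,
              med(dpt$scar_pct), med(dpt$ht_pct),
              med(dpt$dist_ht_mm[is.finite(dpt$dist_ht_mm)]),
              med(npt$dist_ht_mm[is.finite(npt$dist_ht_mm)]),
              if (!is.null(cmp_dht)) cmp_dht$test$p.value else NA_real_,
              if (!is.null(cmp_steep))
                med(noscar$dist_steep_mm[noscar$category == "diastolic"])
              else NA_real_,
              if (!is.null(cmp_steep))
                med(noscar$dist_steep_mm[noscar$category == "normal"])
              else NA_real_,
              if (!is.null(cmp_steep)) cmp_steep$test$p.value else NA_real_,
              100 * mean(dpt$scar_pct + dpt$ht_pct <
                           config$transmural_cutoff, na.rm = TRUE)))

  structure(list(phantom = ph, segmentation = seg, field = fld,
                 endo_map = emap, mesh = mesh, gradient = gf, steep = steep,
                 registration = list(landmark = lm, icp = icp),
                 points = mapped, comparisons = list(
                   thickness = cmp_thick, dist_ht = cmp_dht,
                   dist_steep = cmp_steep),
                 summary = summary, config = config),
            class = "substrate_result")
}

#' @export
print.substrate_result <- function(x, ...) {
  cat("<substrate_result>\n")
  cat("  ", nrow(x$endo_map), " endocardial nodes, ",
      nrow(x$mesh$vertices), " mesh vertices\n", sep = "")
  cat("  registration RMS ", signif(x$registration$icp$rms_mm, 3), " mm; ",
      sum(!is.na(x$points$node_id)), "/", nrow(x$points),
      " points mapped\n", sep = "")
  print(x$summary, n = nrow(x$summary))
  invisible(x)
}

#' Read an electroanatomic point table
#'
#' CSV with at least columns `x, y, z` (mm) and `time_ms`; optional
#' `category`, `label`. Lines starting with `#` are ignored.
#'
#' @param path CSV path.
#' @return Tibble of points.
#' @export
read_points <- function(path) {
  tb <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  need <- c("x", "y", "z", "time_ms")
  miss <- setdiff(need, names(tb))
  if (length(miss))
    stop("point table is missing column(s): ", paste(miss, collapse = ", "))
  tb
}

#' Write an electroanatomic point table
#'
#' Writes CSV with a `#`-comment provenance header echoing the
#' originating configuration.
#'
#' @param points Tibble/data frame of points.
#' @param path Output path.
#' @param config Optional [pipeline_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, config = NULL) {
  hdr <- paste0("# vtsubstrate point table; ",
                format(nrow(points)), " rows")
  if (!is.null(config))
    hdr <- c(hdr, paste0("# config: seed=", config$seed,
                         " scar_frac=", config$scar_frac,
                         " ht_frac=", config$ht_frac,
                         " mapping_radius=", config$mapping_radius,
                         " dt_block=", config$dt_block))
  writeLines(c(hdr, readr::format_csv(points)), path)
  invisible(path)
}
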