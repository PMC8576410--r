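make_intensity <- function(values) {
  d <- c(length(values), 1L, 1L)
  list(vol = vox_volume(array(values, d), c(1, 1, 1)),
       mask = array(TRUE, d))
}

test_that("thresholds are applied relative to the in-mask maximum", {
  mi <- make_intensity(c(100, 70, 60, 50, 40, 30, 39.9))
  seg <- classify_tissue(mi$vol, mi$mask)
  lab <- tissue_labels()
  expect_equal(as.vector(seg$data),
               unname(lab[c("scar", "scar", "scar", "ht", "ht",
                            "myocardium", "myocardium")]))
})

test_that("degenerate all-equal intensities classify as scar without crashing", {
  mi <- make_intensity(rep(42, 5))
  seg <- classify_tissue(mi$vol, mi$mask)
  expect_true(all(seg$data == tissue_labels()[["scar"]]))
})

test_that("noiseless phantom labels are recovered exactly", {
  ph <- phantom_volume(phantom_spec(
    "shell", r_endo = 12, r_epi = 18, seed = 2L,
    intensity = list(noise_sd = 0),
    scar_patches = list(scar_patch(c(1, 0, 0), 35, 0.5, 2))))
  seg <- classify_tissue(ph$intensity, ph$label)
  expect_identical(seg$data, ph$label$data)
})

test_that("classification is invariant to positive intensity scaling", {
  ph <- phantom_volume(phantom_spec("slab", slab_thickness = 6,
                                    slab_extent = c(14, 14), seed = 4L,
    scar_patches = list(scar_patch(c(0, 0), 5, 0.6, 1))))
  seg1 <- classify_tissue(ph$intensity, ph$label)
  scaled <- vox_volume(ph$intensity$data * 3.7, ph$intensity$spacing,
                       ph$intensity$origin)
  seg2 <- classify_tissue(scaled, ph$label)
  expect_identical(seg1$data, seg2$data)
})

test_that("raising the scar threshold never increases the scar count", {
  ph <- phantom_volume(phantom_spec("slab", slab_thickness = 6,
                                    slab_extent = c(14, 14), seed = 5L,
    scar_patches = list(scar_patch(c(0, 0), 5, 0.6, 1))))
  lab <- tissue_labels()
  counts <- vapply(c(0.45, 0.55, 0.65, 0.75, 0.9), function(sf) {
    sum(classify_tissue(ph$intensity, ph$label,
                        scar_frac = sf)$data == lab[["scar"]])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("invalid inputs are rejected", {
  mi <- make_intensity(c(1, 2, 3))
  expect_error(classify_tissue(mi$vol, array(FALSE, dim(mi$vol$data))),
               "empty")
  neg <- vox_volume(array(c(-5, -2, -1), c(3, 1, 1)), c(1, 1, 1))
  expect_error(classify_tissue(neg, array(TRUE, c(3, 1, 1))), "not positive")
  expect_error(classify_tissue(mi$vol, mi$mask, scar_frac = 0.3,
                               ht_frac = 0.4))
})

test_that("minimum-component filter removes isolated enhancement", {
  d <- c(9, 9, 3)
  arr <- array(20, d)
  arr[2:4, 2:4, 1:3] <- 80          # genuine 27-voxel scar block
  arr[8, 8, 2] <- 80                # isolated noise voxel
  vol <- vox_volume(array(arr, d), c(1, 1, 1))
  mask <- array(TRUE, d)
  lab <- tissue_labels()
  seg0 <- classify_tissue(vol, mask)
  expect_equal(seg0$data[8, 8, 2], lab[["scar"]])
  seg1 <- classify_tissue(vol, mask, min_component = 5)
  expect_equal(seg1$data[8, 8, 2], lab[["myocardium"]])
  expect_equal(seg1$data[3, 3, 2], lab[["scar"]])
})
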