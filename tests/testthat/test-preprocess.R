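make_grid <- function(values, spacing = c(2.73, 2.73, 3), modality = "PET_SUV",
                      origin = c(0, 0, 0)) {
  volume_grid(values, spacing, modality, origin)
}

test_that("resampling preserves constants and reproduces a linear ramp exactly", {
  cfg <- preprocess_config(target_xy_spacing = 2.73, crop_xy = 32)
  ct <- make_grid(array(40, c(20, 20, 4)), modality = "CT_HU")
  pet_const <- make_grid(array(1.7, c(20, 20, 4)))
  rs <- resample_to_common_grid(ct, pet_const, cfg)
  expect_true(all(abs(rs$pet$values - 1.7) < 1e-12))
  expect_identical(dim(rs$ct$values), dim(ct$values))  # already on target grid

  # ramp along x on a finer grid; trilinear values must match the analytic
  # ramp at the new voxel centres
  nx <- 30
  ramp <- array(rep((0:(nx - 1)) * 1.4, times = 20 * 4), c(nx, 20, 4))
  pet_ramp <- make_grid(ramp, spacing = c(1.4, 2.73, 3))  # value = x in mm
  ct2 <- make_grid(array(0, c(15, 20, 4)), spacing = c(2.9, 2.73, 3), "CT_HU")
  rs2 <- resample_to_common_grid(ct2, pet_ramp, cfg)
  xs <- rs2$pet$origin[1] + (seq_len(dim(rs2$pet$values)[1]) - 1) * 2.73
  inside <- xs >= 0 & xs <= (nx - 1) * 1.4  # clamped outside the source grid
  expect_lt(max(abs(rs2$pet$values[inside, 10, 2] - xs[inside])), 1e-9)
})

test_that("disjoint fields of view are rejected", {
  a <- make_grid(array(0, c(8, 8, 2)), modality = "CT_HU")
  b <- make_grid(array(0, c(8, 8, 2)), origin = c(1000, 1000, 1000))
  expect_error(resample_to_common_grid(a, b, preprocess_config(crop_xy = 16)),
               "disjoint")
})

test_that("central crop picks the expected window and pads small inputs", {
  v <- make_grid(array(seq_len(192 * 192 * 2) + 0, c(192, 192, 2)))
  cr <- crop_center(v, 128)
  expect_identical(dim(cr$values), c(128L, 128L, 2L))
  expect_identical(attr(cr, "crop_offset"), c(32L, 32L))
  expect_identical(cr$values[1, 1, 1], v$values[33, 33, 1])
  expect_identical(cr$values[128, 128, 2], v$values[160, 160, 2])

  small <- make_grid(array(1, c(100, 100, 2)), modality = "CT_HU")
  pd <- crop_center(small, 128)
  expect_identical(dim(pd$values), c(128L, 128L, 2L))
  expect_identical(pd$values[1, 1, 1], -1000)      # CT pads with air
  expect_identical(pd$values[64, 64, 1], 1)        # original centred
  pd_pet <- crop_center(make_grid(array(1, c(100, 100, 2))), 128)
  expect_identical(pd_pet$values[1, 1, 1], 0)      # PET pads with zero
})

test_that("default crop and spacing give the expected transaxial field of view", {
  cfg <- preprocess_config()
  fov_mm <- cfg$crop_xy * cfg$target_xy_spacing
  expect_equal(fov_mm, 349.44)
  expect_lt(abs(fov_mm / 10 - 35), 0.5)  # approximately 35 cm
})

test_that("mask back-mapping inverts the central crop on the cropped region", {
  v <- make_grid(array(rnorm(40 * 40 * 3), c(40, 40, 3)))
  cr <- crop_center(v, 24)
  mask <- array(0L, dim(cr$values))
  mask[5:10, 7:9, 2] <- 1L
  full <- autobsuv:::uncrop_mask(mask, attr(cr, "crop_offset"), dim(v$values))
  again <- crop_center(volume_grid(full + 0, v$spacing, "MASK", v$origin), 24)
  expect_identical(array(as.integer(again$values), dim(mask)), mask)
})

test_that("per-plane normalization maps to [0,1], is idempotent, zeroes constants", {
  vals <- array(rnorm(16 * 16 * 5, sd = 300), c(16, 16, 5))
  vals[, , 3] <- 7  # constant plane
  n1 <- normalize_slices(make_grid(vals, modality = "CT_HU"))
  for (k in c(1, 2, 4, 5)) {
    expect_equal(min(n1[, , k]), 0)
    expect_equal(max(n1[, , k]), 1)
  }
  expect_true(all(n1[, , 3] == 0))
  expect_equal(normalize_slices(n1), n1)  # idempotence
  # affine midpoint example: plane with min -1000, max 1000 maps 0 to 0.5
  pl <- array(0, c(4, 4, 1)); pl[1, 1, 1] <- -1000; pl[4, 4, 1] <- 1000
  expect_equal(normalize_slices(pl)[2, 2, 1], 0.5)
})

test_that("slice stacks preserve plane count, [0,1] range, and label mass", {
  cs <- make_dataset(1, base_seed = 8)[[1]]
  cfg <- preprocess_config(crop_xy = 64)
  st <- build_slice_stack(cs$ct, cs$pet, cs$label, cfg)
  expect_identical(dim(st$ct)[3], dim(cs$ct$values)[3])
  expect_true(all(st$ct >= 0 & st$ct <= 1))
  expect_true(all(st$pet >= 0 & st$pet <= 1))
  expect_true(all(st$label %in% c(0L, 1L)))

  # no label supplied: images unaffected, label absent
  st0 <- build_slice_stack(cs$ct, cs$pet, NULL, cfg)
  expect_null(st0$label)
  expect_identical(st0$ct, st$ct)
  expect_identical(st0$pet_raw, st$pet_raw)

  # nearest-neighbour label resampling from a finer grid: the resampled mask
  # must equal the analytic rasterization of the cylinder cores on the target
  # lattice, and its physical volume must match the analytic cylinder volume
  # within 10%
  spec <- clean_spec(grid_shape = c(88L, 88L, 20L),
                     voxel_spacing = c(2.0, 2.0, 3.0))
  ph <- generate_phantom(spec)
  lab <- ground_truth_label(ph$truth)
  expect_gte(sum(lab$mask), 100)
  st2 <- build_slice_stack(ph$ct, ph$pet, lab, cfg)
  core_r <- spec$aorta_radius - 8
  xs <- st2$origin[1] + (seq_len(dim(st2$label)[1]) - 1) * st2$spacing[1]
  ys <- st2$origin[2] + (seq_len(dim(st2$label)[2]) - 1) * st2$spacing[2]
  disk <- function(ctr) sqrt(outer((xs - ctr[1])^2, (ys - ctr[2])^2, "+")) <= core_r
  expected_plane <- disk(spec$aorta_centers$asc) | disk(spec$aorta_centers$desc)
  labeled_planes <- which(apply(lab$mask, 3, sum) > 0)
  for (k in labeled_planes)
    expect_identical(st2$label[, , k], array(as.integer(expected_plane),
                                             dim(expected_plane)))
  expect_identical(sum(st2$label[, , -labeled_planes]), 0L)
  vol_true <- 2 * pi * core_r^2 * length(labeled_planes) * spec$voxel_spacing[3]
  vol_dst <- sum(st2$label) * prod(st2$spacing)
  expect_lt(abs(vol_dst - vol_true) / vol_true, 0.10)
})
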