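test_that("noiseless, unblurred phantom has exact blood activity at the centerline", {
  spec <- clean_spec()
  ph <- generate_phantom(spec)
  ax <- axes_of(spec)
  i <- vox_at(spec$aorta_centers$desc[1], spec$voxel_spacing[1])
  j <- vox_at(spec$aorta_centers$desc[2], spec$voxel_spacing[2])
  k <- vox_at(30, spec$voxel_spacing[3])  # mid-thorax plane, outside bias band
  expect_identical(ph$pet$values[i, j, k], spec$blood_activity)
  expect_identical(ph$ct$values[i, j, k], 45)
})

test_that("PSF-blurred centerline value matches the Gaussian disk-convolution oracle", {
  # oracle: an infinite cylinder of radius R on background b, blurred by an
  # isotropic Gaussian (sigma = FWHM/2.3548), has in-plane centre value
  # b + (a - b) * (1 - exp(-R^2 / (2 sigma^2))); computed independently of
  # the generator's separable convolution.
  spec <- clean_spec(psf_fwhm = 6, aorta_radius = 15)
  ph <- generate_phantom(spec)
  i <- vox_at(spec$aorta_centers$desc[1], spec$voxel_spacing[1])
  j <- vox_at(spec$aorta_centers$desc[2], spec$voxel_spacing[2])
  k <- vox_at(30, spec$voxel_spacing[3])
  got <- ph$pet$values[i, j, k]
  sigma <- 6 / (2 * sqrt(2 * log(2)))
  oracle <- spec$tissue_activity + (spec$blood_activity - spec$tissue_activity) *
    (1 - exp(-15^2 / (2 * sigma^2)))
  expect_lt(abs(got - spec$blood_activity) / spec$blood_activity, 0.02)
  expect_lt(abs(got - oracle) / oracle, 0.01)
})

test_that("phantom generation is a pure function of (spec, seed)", {
  spec <- phantom_spec(seed = 123L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$pet$values, b$pet$values)
  expect_identical(a$ct$values, b$ct$values)
  spec2 <- phantom_spec(seed = 124L)
  expect_false(identical(generate_phantom(spec2)$pet$values, a$pet$values))
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(aorta_radius = -1), "aorta_radius")
  expect_error(phantom_spec(blood_activity = 0), "blood_activity")
  expect_error(phantom_spec(psf_fwhm = -1), "psf_fwhm")
  # lesions must be avid relative to blood, and inside the grid
  expect_error(phantom_spec(lesion_list = list(lesion(c(80, 90, 30), 6, 1.0))),
               "exceed blood_activity")
  expect_error(phantom_spec(lesion_list = list(lesion(c(500, 90, 30), 6, 5))),
               "outside grid")
  # overlapping arch/abdominal intervals
  expect_error(phantom_spec(arch_z_range = c(5, 60)), "disjoint")
})

test_that("ground-truth label matches the analytic cylinder-core geometry voxel by voxel", {
  spec <- clean_spec()
  ph <- generate_phantom(spec)
  lab <- ground_truth_label(ph$truth, margin_mm = 8, exclusion_mm = 15)
  ax <- axes_of(spec)
  core_r <- spec$aorta_radius - 8
  # independent brute-force voxel scan of rules (a), (b) and (d)
  in_range <- function(z, r) z >= r[1] & z <= r[2]
  for (k in seq_len(spec$grid_shape[3])) {
    z <- ax$z[k]
    excluded <- in_range(z, spec$arch_z_range) ||
      in_range(z, spec$abdominal_z_range) ||
      (z > spec$artifact_zone$z_range[1] & z <= spec$artifact_zone$z_range[2])
    expected <- matrix(0L, spec$grid_shape[1], spec$grid_shape[2])
    if (!excluded) {
      for (limb in c("asc", "desc")) {
        zr <- if (limb == "asc") spec$asc_z_range else spec$desc_z_range
        if (z < zr[1] || z > zr[2]) next
        ctr <- spec$aorta_centers[[limb]]
        d <- sqrt(outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, "+"))
        expected[d <= core_r] <- 1L
      }
    }
    expect_identical(lab$mask[, , k], expected)
  }
  # margin rule holds for 100% of labeled voxels
  expect_true(all(ph$truth$wall_distance_field[lab$mask > 0] >= 8))
})

test_that("a lesion touching the aortic wall empties exactly the planes it spans", {
  spec0 <- clean_spec()
  ax <- axes_of(spec0)
  ctr <- spec0$aorta_centers$desc
  lr <- 6
  les <- lesion(c(ctr[1] + spec0$aorta_radius + lr, ctr[2], 30), lr, 6)
  spec <- clean_spec(lesion_list = list(les))
  lab0 <- ground_truth_label(generate_phantom(spec0)$truth)
  lab1 <- ground_truth_label(generate_phantom(spec)$truth)
  lesion_planes <- abs(ax$z - 30) <= lr
  for (k in seq_len(spec$grid_shape[3])) {
    if (lesion_planes[k]) {
      expect_identical(sum(lab1$mask[, , k]), 0L)
    } else {
      expect_identical(lab1$mask[, , k], lab0$mask[, , k])
    }
  }
  # a remote lesion (far from the aorta) excludes nothing
  far <- lesion(c(20, 20, 30), 5, 6)
  lab2 <- ground_truth_label(generate_phantom(clean_spec(lesion_list = list(far)))$truth)
  expect_identical(lab2$mask, lab0$mask)
})

test_that("unsatisfiable margin yields an empty mask with a warning, not an error", {
  ph <- generate_phantom(clean_spec())
  expect_warning(lab <- ground_truth_label(ph$truth, margin_mm = 14),
                 "empty")
  expect_identical(sum(lab$mask), 0L)
})

test_that("the 8 mm margin strictly reduces partial-volume bias for FWHM 4-8 mm", {
  for (fwhm in c(4, 6, 8)) {
    spec <- clean_spec(psf_fwhm = fwhm)
    ph <- generate_phantom(spec)
    core <- ground_truth_label(ph$truth, margin_mm = 8)
    full <- ground_truth_label(ph$truth, margin_mm = 0)
    b_core <- mean(ph$pet$values[core$mask > 0])
    b_full <- mean(ph$pet$values[full$mask > 0])
    expect_lt(abs(b_core - ph$truth$true_bsuv), abs(b_full - ph$truth$true_bsuv))
  }
})

test_that("make_dataset is deterministic and honours its preconditions", {
  a <- make_dataset(3, base_seed = 5)
  b <- make_dataset(3, base_seed = 5)
  expect_identical(lapply(a, function(cs) cs$pet$values),
                   lapply(b, function(cs) cs$pet$values))
  expect_identical(lapply(a, function(cs) cs$label$mask),
                   lapply(b, function(cs) cs$label$mask))
  expect_error(make_dataset(0, base_seed = 1), "n_cases")
  expect_error(phantom_ranges(aorta_radius = c(5, 2)), "invalid range")
  withls <- make_dataset(4, base_seed = 2,
                         spec_ranges = phantom_ranges(lesion_fraction = 1))
  expect_true(all(vapply(withls, function(cs)
    length(cs$truth$spec$lesion_list) >= 1, logical(1))))
  none <- make_dataset(4, base_seed = 2,
                       spec_ranges = phantom_ranges(lesion_fraction = 0))
  expect_true(all(vapply(none, function(cs)
    length(cs$truth$spec$lesion_list) == 0, logical(1))))
})

test_that("every dataset label satisfies margin and plane-exclusion rules", {
  cases <- make_dataset(5, base_seed = 31,
                        spec_ranges = phantom_ranges(lesion_fraction = 1))
  for (cs in cases) {
    spec <- cs$truth$spec
    m <- cs$label$mask
    expect_true(all(cs$truth$wall_distance_field[m > 0] >= 8))
    z <- (seq_len(spec$grid_shape[3]) - 1) * spec$voxel_spacing[3]
    bad <- (z >= spec$arch_z_range[1] & z <= spec$arch_z_range[2]) |
      (z >= spec$abdominal_z_range[1] & z <= spec$abdominal_z_range[2]) |
      (z > spec$artifact_zone$z_range[1] & z <= spec$artifact_zone$z_range[2])
    expect_identical(sum(m[, , bad]), 0L)
    # lesion-adjacent planes: recompute the in-plane gap independently
    les <- spec$lesion_list[[1]]
    for (k in which(abs(z - les$center[3]) <= les$radius)) {
      r_in <- sqrt(max(les$radius^2 - (z[k] - les$center[3])^2, 0))
      gaps <- vapply(c("asc", "desc"), function(limb) {
        zr <- if (limb == "asc") spec$asc_z_range else spec$desc_z_range
        if (z[k] < zr[1] || z[k] > zr[2]) return(Inf)
        sqrt(sum((les$center[1:2] - spec$aorta_centers[[limb]])^2)) -
          r_in - spec$aorta_radius
      }, numeric(1))
      if (any(gaps < 15)) expect_identical(sum(m[, , k]), 0L)
    }
  }
})
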