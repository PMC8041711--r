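#' Construct a 3-D volume grid
#'
#' The common carrier of the pipeline: a scalar field (CT in Hounsfield
#' units or PET in SUV) on a regular voxel grid. World coordinate of voxel
#' `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`, in mm.
#'
#' @param values 3-D numeric array, all finite.
#' @param spacing voxel spacing in mm per axis (length 3, all `> 0`).
#' @param modality `"CT_HU"`, `"PET_SUV"` or `"MASK"`.
#' @param origin world coordinate of the first voxel centre, mm (length 3).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(values, spacing, modality = c("PET_SUV", "CT_HU", "MASK"),
                        origin = c(0, 0, 0)) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  if (!all(is.finite(values))) stop("values must all be finite")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive values")
  if (length(origin) != 3L) stop("origin must have length 3")
  structure(list(values = values, spacing = as.numeric(spacing),
                 modality = modality, origin = as.numeric(origin)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid [%s]: %s voxels @ %s mm\n", x$modality,
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Describe an FDG-avid lesion
#'
#' A spherical, highly FDG-avid structure (e.g. a tumor) that may sit close
#' to the aortic wall and spill activity into the lumen.
#'
#' @param center world coordinates of the sphere centre, mm (length 3).
#' @param radius sphere radius, mm (`> 0`).
#' @param activity lesion SUV (`> 0`; phantom validation additionally
#'   requires it to exceed the blood activity).
#' @return an object of class `lesion`.
#' @export
lesion <- function(center, radius, activity) {
  if (length(center) != 3L) stop("center must have length 3")
  if (radius <= 0) stop("lesion radius must be > 0")
  if (activity <= 0) stop("lesion activity must be > 0")
  structure(list(center = as.numeric(center), radius = radius,
                 activity = activity), class = "lesion")
}

#' Specify a synthetic thoracic PET/CT phantom
#'
#' Defines a piecewise-constant torso with lungs, vertebra, ascending and
#' descending thoracic aorta connected by a half-torus arch, optional
#' aorta-adjacent lesions, a diaphragm-region artifact band with a
#' multiplicative PET bias, Gaussian point-spread blurring and additive
#' Gaussian noise. The defaults describe a 64 x 64 x 20 grid at
#' 2.73 x 2.73 x 3 mm.
#'
#' @param grid_shape voxel counts `(nx, ny, nz)`.
#' @param voxel_spacing mm per axis.
#' @param aorta_radius lumen radius, mm.
#' @param aorta_centers in-plane (x, y) world positions (mm) of the
#'   ascending and descending limb axes: list with `asc` and `desc`.
#' @param asc_z_range,desc_z_range z extents (mm) of the two limbs.
#' @param arch_z_range z interval (mm) occupied by the aortic arch
#'   (half-torus connecting the limbs above `min(arch_z_range)`).
#' @param abdominal_z_range z interval (mm) below the diaphragm.
#' @param artifact_zone list with `z_range` (mm) and multiplicative PET
#'   `bias` factor modelling attenuation artifacts above the diaphragm.
#' @param blood_activity true blood SUV (the quantity to recover).
#' @param tissue_activity background soft-tissue SUV.
#' @param lesion_list list of [lesion()] objects.
#' @param psf_fwhm PET point-spread FWHM, mm (`>= 0`; 0 disables blurring).
#' @param noise_sigma additive Gaussian PET noise SD, SUV.
#' @param ct_noise_sigma additive CT noise SD, HU.
#' @param seed integer; generation is a pure function of (spec, seed).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 20L),
                         voxel_spacing = c(2.73, 2.73, 3.0),
                         aorta_radius = 14,
                         aorta_centers = NULL,
                         asc_z_range = c(24, 45),
                         desc_z_range = c(0, 45),
                         arch_z_range = c(45, 60),
                         abdominal_z_range = c(0, 13.5),
                         artifact_zone = list(z_range = c(13.5, 21), bias = 1.2),
                         blood_activity = 2.0,
                         tissue_activity = 0.8,
                         lesion_list = list(),
                         psf_fwhm = 6,
                         noise_sigma = 0.06,
                         ct_noise_sigma = 15,
                         seed = 1L) {
  ext <- (grid_shape - 1) * voxel_spacing
  cx <- ext[1] / 2
  cy <- ext[2] / 2
  if (is.null(aorta_centers))
    aorta_centers <- list(asc = c(cx - 15, cy + 14), desc = c(cx + 15, cy + 14))
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), voxel_spacing = as.numeric(voxel_spacing),
    aorta_radius = aorta_radius, aorta_centers = aorta_centers,
    asc_z_range = asc_z_range, desc_z_range = desc_z_range,
    arch_z_range = arch_z_range, abdominal_z_range = abdominal_z_range,
    artifact_zone = artifact_zone, blood_activity = blood_activity,
    tissue_activity = tissue_activity, lesion_list = lesion_list,
    psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
    ct_noise_sigma = ct_noise_sigma, seed = as.integer(seed),
    torso_half_axes = c(0.45 * ext[1], 0.36 * ext[2]),
    torso_center = c(cx, cy)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$voxel_spacing <= 0)) stop("all voxel spacings must be > 0")
  if (spec$aorta_radius <= 0) stop("aorta_radius must be > 0")
  if (spec$blood_activity <= 0) stop("blood_activity must be > 0")
  if (spec$psf_fwhm < 0) stop("psf_fwhm must be >= 0")
  if (spec$noise_sigma < 0) stop("noise_sigma must be >= 0")
  zmax <- (spec$grid_shape[3] - 1) * spec$voxel_spacing[3]
  ab <- spec$abdominal_z_range
  ar <- spec$arch_z_range
  if (ab[1] > ab[2] || ar[1] > ar[2]) stop("z ranges must be increasing")
  if (max(ab[1], ar[1]) < min(ab[2], ar[2]))
    stop("arch_z_range and abdominal_z_range must be disjoint")
  if (ab[1] < 0 || ar[2] < 0) stop("z ranges must lie in the grid z extent")
  ext <- (spec$grid_shape - 1) * spec$voxel_spacing
  for (le in spec$lesion_list) {
    if (!inherits(le, "lesion")) stop("lesion_list entries must be lesion objects")
    if (le$activity <= spec$blood_activity)
      stop("lesion activity must exceed blood_activity (lesions are highly FDG-avid)")
    if (any(le$center < 0) || any(le$center > ext))
      stop("lesion outside grid")
  }
  invisible(spec)
}

# world coordinate axes of a spec's grid (voxel centres)
spec_axes <- function(spec) {
  list(x = (seq_len(spec$grid_shape[1]) - 1) * spec$voxel_spacing[1],
       y = (seq_len(spec$grid_shape[2]) - 1) * spec$voxel_spacing[2],
       z = (seq_len(spec$grid_shape[3]) - 1) * spec$voxel_spacing[3])
}

# Distance of every voxel to the aortic centreline (limbs as vertical lines
# over their z extents, arch as the upper half-torus circle), plus per-limb
# in-plane distance maps used by the label rules.
aorta_geometry <- function(spec) {
  ax <- spec_axes(spec)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  d2 <- function(ctr) {
    outer((ax$x - ctr[1])^2, (ax$y - ctr[2])^2, "+")
  }
  dasc2d <- sqrt(d2(spec$aorta_centers$asc))
  ddesc2d <- sqrt(d2(spec$aorta_centers$desc))
  dist <- array(Inf, c(nx, ny, nz))
  for (k in seq_len(nz)) {
    z <- ax$z[k]
    dk <- matrix(Inf, nx, ny)
    if (z >= spec$desc_z_range[1] && z <= spec$desc_z_range[2])
      dk <- pmin(dk, ddesc2d)
    if (z >= spec$asc_z_range[1] && z <= spec$asc_z_range[2])
      dk <- pmin(dk, dasc2d)
    dist[, , k] <- dk
  }
  # arch: circle of radius R in the xz-plane at y = cy, upper half only
  acy <- spec$aorta_centers$asc[2]
  arc_cx <- mean(c(spec$aorta_centers$asc[1], spec$aorta_centers$desc[1]))
  arc_R <- abs(spec$aorta_centers$desc[1] - spec$aorta_centers$asc[1]) / 2
  arc_cz <- spec$arch_z_range[1]
  for (k in seq_len(nz)) {
    z <- ax$z[k]
    if (z < arc_cz) next
    rad_xz <- sqrt(outer((ax$x - arc_cx)^2, rep((z - arc_cz)^2, ny), "+"))
    darch <- sqrt((rad_xz - arc_R)^2 +
                    matrix((ax$y - acy)^2, nx, ny, byrow = TRUE))
    dist[, , k] <- pmin(dist[, , k], darch)
  }
  list(dist = dist, dasc2d = dasc2d, ddesc2d = ddesc2d, axes = ax)
}

#' Generate a synthetic paired CT/PET thoracic phantom
#'
#' Produces piecewise-constant CT (HU) and PET (SUV) compartment volumes,
#' applies the PET point-spread blur, the diaphragm-region multiplicative
#' bias band and additive Gaussian noise, and returns the generative truth
#' (including the per-voxel distance to the aortic wall). Identical
#' `(spec, seed)` yields bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` and `pet` ([volume_grid()]s) and `truth`
#'   (class `phantom_truth`: the spec, the true blood SUV and the
#'   wall-distance field).
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  geo <- aorta_geometry(spec)
  ax <- geo$axes
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]; nz <- spec$grid_shape[3]
  cx <- spec$torso_center[1]; cy <- spec$torso_center[2]
  ta <- spec$torso_half_axes[1]; tb <- spec$torso_half_axes[2]
  torso2d <- outer(((ax$x - cx) / ta)^2, ((ax$y - cy) / tb)^2, "+") <= 1
  diaphragm_z <- spec$abdominal_z_range[2]
  ztop <- max(ax$z)
  lung_cz <- (diaphragm_z + ztop) / 2
  lung_hz <- (ztop - diaphragm_z) / 2 + 2
  lung2d <- function(side) {
    lcx <- cx + side * 40
    lcy <- cy - 8
    outer(((ax$x - lcx) / 26)^2, ((ax$y - lcy) / 32)^2, "+")
  }
  lungL <- lung2d(-1); lungR <- lung2d(1)
  vert2d <- sqrt(outer((ax$x - cx)^2, (ax$y - (cy + 42))^2, "+")) <= 11
  lumen <- geo$dist <= spec$aorta_radius

  ct <- array(-1000, c(nx, ny, nz))
  pet <- array(0, c(nx, ny, nz))
  lung_frac <- 0.25  # lung background uptake relative to soft tissue
  for (k in seq_len(nz)) {
    z <- ax$z[k]
    ctk <- matrix(-1000, nx, ny)
    petk <- matrix(0, nx, ny)
    ctk[torso2d] <- 40
    petk[torso2d] <- spec$tissue_activity
    if (z > diaphragm_z) {
      lz <- ((z - lung_cz) / lung_hz)^2
      inlung <- torso2d & ((lungL + lz) <= 1 | (lungR + lz) <= 1)
      ctk[inlung] <- -700
      petk[inlung] <- lung_frac * spec$tissue_activity
    }
    ctk[vert2d & torso2d] <- 700
    lum_k <- lumen[, , k]
    ctk[lum_k] <- 45
    petk[lum_k] <- spec$blood_activity
    ct[, , k] <- ctk
    pet[, , k] <- petk
  }
  for (le in spec$lesion_list) {
    zk <- which(abs(ax$z - le$center[3]) <= le$radius)
    for (k in zk) {
      r_in2 <- le$radius^2 - (ax$z[k] - le$center[3])^2
      insel <- outer((ax$x - le$center[1])^2, (ax$y - le$center[2])^2, "+") <= r_in2
      petk <- pet[, , k]
      petk[insel] <- le$activity
      pet[, , k] <- petk
      ctk <- ct[, , k]
      ctk[insel] <- 55
      ct[, , k] <- ctk
    }
  }
  if (spec$psf_fwhm > 0) {
    sigma_vox <- (spec$psf_fwhm / 2.354820045) / spec$voxel_spacing
    pet <- cpp_blur3d(pet, sigma_vox)
  }
  azr <- spec$artifact_zone$z_range
  in_artifact <- ax$z > azr[1] & ax$z <= azr[2]
  if (any(in_artifact))
    pet[, , in_artifact] <- pet[, , in_artifact] * spec$artifact_zone$bias
  ct_final <- ct
  pet_final <- pet
  if (spec$ct_noise_sigma > 0 || spec$noise_sigma > 0) {
    noise <- with_local_seed(spec$seed, {
      list(ct = array(rnorm(length(ct), sd = spec$ct_noise_sigma), dim(ct)),
           pet = array(rnorm(length(pet), sd = spec$noise_sigma), dim(pet)))
    })
    if (spec$ct_noise_sigma > 0) ct_final <- ct + noise$ct
    if (spec$noise_sigma > 0) pet_final <- pet + noise$pet
  }
  truth <- structure(list(spec = spec, true_bsuv = spec$blood_activity,
                          wall_distance_field = spec$aorta_radius - geo$dist,
                          lumen = lumen),
                     class = "phantom_truth")
  list(ct = volume_grid(ct_final, spec$voxel_spacing, "CT_HU"),
       pet = volume_grid(pet_final, spec$voxel_spacing, "PET_SUV"),
       truth = truth)
}

# planes (1-based indices) excluded by the arch / abdominal / artifact rules
excluded_planes <- function(spec) {
  z <- spec_axes(spec)$z
  in_range <- function(r) z >= r[1] & z <= r[2]
  in_range(spec$arch_z_range) | in_range(spec$abdominal_z_range) |
    (z > spec$artifact_zone$z_range[1] & z <= spec$artifact_zone$z_range[2])
}

# planes excluded because a lesion surface comes within exclusion_mm of the
# aortic wall of a limb present on that plane
lesion_excluded_planes <- function(spec, exclusion_mm) {
  z <- spec_axes(spec)$z
  excl <- rep(FALSE, length(z))
  for (le in spec$lesion_list) {
    on_plane <- abs(z - le$center[3]) <= le$radius
    for (k in which(on_plane)) {
      r_in <- sqrt(max(le$radius^2 - (z[k] - le$center[3])^2, 0))
      for (limb in c("asc", "desc")) {
        zr <- if (limb == "asc") spec$asc_z_range else spec$desc_z_range
        if (z[k] < zr[1] || z[k] > zr[2]) next
        ctr <- spec$aorta_centers[[limb]]
        gap <- sqrt(sum((le$center[1:2] - ctr)^2)) - r_in - spec$aorta_radius
        if (gap < exclusion_mm) excl[k] <- TRUE
      }
    }
  }
  excl
}

#' Rule-based ground-truth label of the usable aortic-lumen core
#'
#' Implements the delineation strategy used for manual blood-SUV ROIs: (a)
#' only the ascending and descending thoracic aorta are delineated; (b) a
#' safety margin (default 8 mm) is kept between the ROI boundary and the
#' aortic wall to avoid spill-out; (c) transaxial planes with a highly
#' FDG-avid lesion surface within `exclusion_mm` of the aortic wall are
#' excluded to avoid spill-in; (d) aortic arch, diaphragm-region artifact
#' band and abdominal aorta planes are excluded to avoid motion-induced
#' artifacts.
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param margin_mm minimum distance between labeled voxels and the aortic
#'   wall (default 8 mm).
#' @param exclusion_mm in-plane lesion-surface-to-wall distance below which
#'   a plane is excluded (default 15 mm).
#' @return a `lumen_label`: list with binary `mask` aligned to the phantom
#'   grid, plus `spacing` and `origin`. If the margin is not satisfiable
#'   (`margin_mm >= aorta_radius`) the mask is empty and a warning is
#'   emitted.
#' @export
ground_truth_label <- function(truth, margin_mm = 8, exclusion_mm = 15) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  geo <- aorta_geometry(spec)
  z <- geo$axes$z
  mask <- array(0L, spec$grid_shape)
  if (margin_mm >= spec$aorta_radius) {
    warning("margin_mm >= aorta_radius: ground-truth mask is empty")
  } else {
    core_r <- spec$aorta_radius - margin_mm
    excl <- excluded_planes(spec) | lesion_excluded_planes(spec, exclusion_mm)
    asc_core <- geo$dasc2d <= core_r
    desc_core <- geo$ddesc2d <= core_r
    for (k in seq_len(spec$grid_shape[3])) {
      if (excl[k]) next
      mk <- matrix(FALSE, spec$grid_shape[1], spec$grid_shape[2])
      if (z[k] >= spec$asc_z_range[1] && z[k] <= spec$asc_z_range[2])
        mk <- mk | asc_core
      if (z[k] >= spec$desc_z_range[1] && z[k] <= spec$desc_z_range[2])
        mk <- mk | desc_core
      mask[, , k] <- as.integer(mk)
    }
  }
  structure(list(mask = mask, spacing = spec$voxel_spacing,
                 origin = c(0, 0, 0)), class = "lumen_label")
}

#' Default randomization ranges for phantom datasets
#'
#' Each geometric/activity parameter of [phantom_spec()] is drawn uniformly
#' from its interval; `lesion_fraction` of cases carry one aorta-adjacent
#' lesion whose wall gap is drawn from `lesion_gap` (negative values touch
#' or overlap the wall).
#'
#' @param aorta_radius,blood_activity,tissue_activity,psf_fwhm,noise_sigma,
#'   artifact_bias,lesion_radius,lesion_activity,lesion_gap numeric
#'   `c(lo, hi)` intervals.
#' @param lesion_fraction fraction of cases carrying a lesion.
#' @param center_jitter maximal in-plane offset (mm) applied to the whole
#'   aorta position.
#' @return list of ranges, class `phantom_ranges`.
#' @export
phantom_ranges <- function(aorta_radius = c(12, 16),
                           blood_activity = c(1.5, 2.5),
                           tissue_activity = c(0.6, 1.0),
                           psf_fwhm = c(5, 7),
                           noise_sigma = c(0.04, 0.08),
                           artifact_bias = c(0.8, 1.2),
                           lesion_fraction = 0.5,
                           lesion_radius = c(5, 9),
                           lesion_activity = c(4, 8),
                           lesion_gap = c(-2, 12),
                           center_jitter = 4) {
  rg <- list(aorta_radius = aorta_radius, blood_activity = blood_activity,
             tissue_activity = tissue_activity, psf_fwhm = psf_fwhm,
             noise_sigma = noise_sigma, artifact_bias = artifact_bias,
             lesion_fraction = lesion_fraction, lesion_radius = lesion_radius,
             lesion_activity = lesion_activity, lesion_gap = lesion_gap,
             center_jitter = center_jitter)
  for (nm in setdiff(names(rg), c("lesion_fraction", "center_jitter"))) {
    r <- rg[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      stop("invalid range for ", nm)
  }
  if (rg$lesion_fraction < 0 || rg$lesion_fraction > 1)
    stop("lesion_fraction must be in [0, 1]")
  structure(rg, class = "phantom_ranges")
}

#' Generate a randomized phantom dataset
#'
#' Draws `n_cases` phantoms with geometry and activities sampled from
#' `spec_ranges`, generates the paired CT/PET volumes and the rule-based
#' ground-truth labels. Case seeds are derived deterministically from
#' `base_seed`, so identical arguments reproduce the dataset exactly.
#'
#' @param n_cases number of cases (`>= 1`).
#' @param base_seed integer seed for the whole dataset.
#' @param spec_ranges a [phantom_ranges()].
#' @param margin_mm,exclusion_mm label rules, see [ground_truth_label()].
#' @param grid_shape,voxel_spacing grid geometry passed to [phantom_spec()].
#' @return list of cases, each `list(ct, pet, truth, label, case_id, seed)`.
#' @export
make_dataset <- function(n_cases, base_seed, spec_ranges = phantom_ranges(),
                         margin_mm = 8, exclusion_mm = 15,
                         grid_shape = c(64L, 64L, 20L),
                         voxel_spacing = c(2.73, 2.73, 3.0)) {
  if (length(n_cases) != 1L || is.na(n_cases) || n_cases < 1)
    stop("n_cases must be >= 1")
  if (!inherits(spec_ranges, "phantom_ranges"))
    spec_ranges <- do.call(phantom_ranges, spec_ranges)
  rg <- spec_ranges
  lapply(seq_len(n_cases), function(i) {
    seed_i <- as.integer(base_seed) + 7919L * i
    spec <- with_local_seed(seed_i, {
      ru <- function(r) runif(1, r[1], r[2])
      jit <- runif(2, -rg$center_jitter, rg$center_jitter)
      ext <- (grid_shape - 1) * voxel_spacing
      cx <- ext[1] / 2; cy <- ext[2] / 2
      centers <- list(asc = c(cx - 15 + jit[1], cy + 14 + jit[2]),
                      desc = c(cx + 15 + jit[1], cy + 14 + jit[2]))
      radius <- ru(rg$aorta_radius)
      blood <- ru(rg$blood_activity)
      lesions <- list()
      if (runif(1) < rg$lesion_fraction) {
        limb <- if (runif(1) < 0.5) "asc" else "desc"
        lr <- ru(rg$lesion_radius)
        gap <- ru(rg$lesion_gap)
        ang <- runif(1, 0, 2 * pi)
        usable_z <- c(max(ext[3] * 0.3, 21), min(ext[3] * 0.75, 44))
        lz <- runif(1, usable_z[1], usable_z[2])
        ctr <- centers[[limb]]
        dxy <- (radius + lr + gap) * c(cos(ang), sin(ang))
        lc <- c(pmin(pmax(ctr + dxy, c(8, 8)), ext[1:2] - 8), lz)
        lesions <- list(lesion(lc, lr, max(ru(rg$lesion_activity), blood * 1.5)))
      }
      phantom_spec(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                   aorta_radius = radius, aorta_centers = centers,
                   blood_activity = blood,
                   tissue_activity = ru(rg$tissue_activity),
                   lesion_list = lesions,
                   artifact_zone = list(z_range = c(13.5, 21),
                                        bias = ru(rg$artifact_bias)),
                   psf_fwhm = ru(rg$psf_fwhm),
                   noise_sigma = ru(rg$noise_sigma),
                   seed = seed_i)
    })
    ph <- generate_phantom(spec)
    label <- ground_truth_label(ph$truth, margin_mm, exclusion_mm)
    list(ct = ph$ct, pet = ph$pet, truth = ph$truth, label = label,
         case_id = sprintf("case_%03d", i), seed = seed_i)
  })
}
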