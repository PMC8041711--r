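#' Preprocessing configuration
#'
#' Controls resampling of a paired PET/CT study onto a common voxel grid
#' and the transaxial crop. The defaults (2.73 mm transaxial spacing,
#' central 128 x 128 crop) give a field of view of approximately
#' 35 x 35 cm while keeping the plane size small enough for training.
#'
#' @param target_xy_spacing transaxial voxel size after resampling, mm.
#' @param crop_xy transaxial output size in voxels (even, `>= 16`).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_xy_spacing = 2.73, crop_xy = 128L) {
  crop_xy <- as.integer(crop_xy)
  if (target_xy_spacing <= 0) stop("target_xy_spacing must be > 0")
  if (is.na(crop_xy) || crop_xy < 16L || crop_xy %% 2L != 0L)
    stop("crop_xy must be even and >= 16")
  structure(list(target_xy_spacing = target_xy_spacing, crop_xy = crop_xy,
                 image_resampling = "linear", label_resampling = "nearest"),
            class = "preprocess_config")
}

grid_extent <- function(v) {
  d <- dim(v$values)
  list(lo = v$origin, hi = v$origin + (d - 1) * v$spacing)
}

# the common grid: transaxial spacing from cfg, axial grid taken from the CT
common_grid <- function(ct, cfg) {
  d <- dim(ct$values)
  ext <- (d[1:2] - 1) * ct$spacing[1:2]
  out_n <- pmax(2L, as.integer(round(ext / cfg$target_xy_spacing)) + 1L)
  out_origin <- c(ct$origin[1:2] + (ext - (out_n - 1) * cfg$target_xy_spacing) / 2,
                  ct$origin[3])
  list(dim = c(out_n, d[3]),
       spacing = c(cfg$target_xy_spacing, cfg$target_xy_spacing, ct$spacing[3]),
       origin = out_origin)
}

resample_onto <- function(v, grid, method = c("linear", "nearest")) {
  method <- match.arg(method)
  vals <- cpp_resample3d(v$values, v$spacing, v$origin,
                         as.integer(grid$dim), grid$spacing, grid$origin,
                         if (method == "nearest") 1L else 0L)
  volume_grid(vals, grid$spacing, v$modality, grid$origin)
}

#' Resample PET and CT to a common voxel grid
#'
#' The transaxial spacing is set to `cfg$target_xy_spacing` on both
#' modalities; the axial grid is defined by the CT and the PET is
#' interpolated onto it (trilinear).
#'
#' @param ct,pet [volume_grid()]s that overlap spatially.
#' @param cfg a [preprocess_config()].
#' @return list with resampled `ct` and `pet` on the identical grid.
#' @export
resample_to_common_grid <- function(ct, pet, cfg = preprocess_config()) {
  ec <- grid_extent(ct); ep <- grid_extent(pet)
  if (any(ec$lo > ep$hi) || any(ep$lo > ec$hi))
    stop("CT and PET fields of view are disjoint")
  grid <- common_grid(ct, cfg)
  list(ct = resample_onto(ct, grid, "linear"),
       pet = resample_onto(pet, grid, "linear"))
}

modality_background <- function(modality) {
  switch(modality, CT_HU = -1000, PET_SUV = 0, MASK = 0)
}

#' Crop (or pad) a volume to the central transaxial window
#'
#' Keeps the central `crop_xy` x `crop_xy` voxels of every transaxial
#' plane; the axial direction is untouched. Inputs smaller than the crop
#' are padded symmetrically with the modality's background value
#' (-1000 HU for CT, 0 for PET and masks). The origin is updated so voxel
#' world coordinates are preserved.
#'
#' @param v a [volume_grid()].
#' @param crop_xy target transaxial size in voxels.
#' @return cropped/padded [volume_grid()].
#' @export
crop_center <- function(v, crop_xy) {
  crop_xy <- as.integer(crop_xy)
  d <- dim(v$values)
  bg <- modality_background(v$modality)
  out <- array(bg, c(crop_xy, crop_xy, d[3]))
  # offset of the output window within the input grid (0-based, may be <0)
  off <- as.integer(floor((d[1:2] - crop_xy) / 2))
  src_lo <- pmax(off, 0L) + 1L
  src_hi <- pmin(off + crop_xy, d[1:2])
  dst_lo <- src_lo - off
  dst_hi <- src_hi - off
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], ] <-
    v$values[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], , drop = FALSE]
  new_origin <- c(v$origin[1:2] + off * v$spacing[1:2], v$origin[3])
  res <- volume_grid(out, v$spacing, v$modality, new_origin)
  attr(res, "crop_offset") <- off
  res
}

# place a mask defined on a cropped grid back onto the uncropped grid
uncrop_mask <- function(mask, crop_offset, full_dim) {
  d <- dim(mask)
  out <- array(0L, c(full_dim[1], full_dim[2], d[3]))
  src_lo <- pmax(-crop_offset, 0L) + 1L
  src_hi <- pmin(d[1:2], full_dim[1:2] - crop_offset)
  dst_lo <- src_lo + crop_offset
  dst_hi <- src_hi + crop_offset
  out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], ] <-
    mask[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], , drop = FALSE]
  out
}

#' Normalize each transaxial plane to the unit interval
#'
#' Every plane is independently min-max mapped to `[0, 1]`; a constant
#' plane maps to all zeros (degenerate-case convention, avoids division by
#' zero).
#'
#' @param v a [volume_grid()] or 3-D array.
#' @return 3-D array of per-plane normalized values in `[0, 1]`.
#' @export
normalize_slices <- function(v) {
  vals <- if (inherits(v, "volume_grid")) v$values else v
  out <- vals
  for (k in seq_len(dim(vals)[3])) {
    pl <- vals[, , k]
    rng <- range(pl)
    out[, , k] <- if (rng[2] > rng[1]) (pl - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out
}

#' Build the normalized 2-channel slice stack for the network
#'
#' Composes resampling to the common grid (trilinear for images, nearest
#' neighbour for the label), the central transaxial crop, and per-plane
#' min-max normalization. The cropped but un-normalized PET (SUV units) is
#' carried alongside: blood-SUV quantities are meaningless on the
#' normalized intensities.
#'
#' @param ct,pet [volume_grid()]s.
#' @param label optional binary mask: a `lumen_label` or a 3-D array on the
#'   CT grid.
#' @param cfg a [preprocess_config()].
#' @return object of class `slice_stack`: normalized `ct` and `pet` arrays
#'   `[crop, crop, nz]`, `pet_raw` in SUV, optional binary `label`,
#'   `spacing`, `origin` and `provenance` (pre-crop grid and crop offset)
#'   for back-mapping masks to the study grid.
#' @export
build_slice_stack <- function(ct, pet, label = NULL, cfg = preprocess_config()) {
  rs <- resample_to_common_grid(ct, pet, cfg)
  label_rs <- NULL
  if (!is.null(label)) {
    lab_vals <- if (inherits(label, "lumen_label")) label$mask else label
    lab_origin <- if (inherits(label, "lumen_label")) label$origin else ct$origin
    lab_spacing <- if (inherits(label, "lumen_label")) label$spacing else ct$spacing
    lab_grid <- volume_grid(lab_vals + 0, lab_spacing, "MASK", lab_origin)
    grid <- common_grid(ct, cfg)
    label_rs <- resample_onto(lab_grid, grid, "nearest")
  }
  ct_c <- crop_center(rs$ct, cfg$crop_xy)
  pet_c <- crop_center(rs$pet, cfg$crop_xy)
  off <- attr(ct_c, "crop_offset")
  stack <- list(ct = normalize_slices(ct_c),
                pet = normalize_slices(pet_c),
                pet_raw = pet_c$values,
                label = NULL,
                spacing = ct_c$spacing,
                origin = ct_c$origin,
                provenance = list(resampled_dim = dim(rs$ct$values),
                                  resampled_origin = rs$ct$origin,
                                  crop_offset = off,
                                  ct_dim = dim(ct$values), ct_origin = ct$origin,
                                  ct_spacing = ct$spacing))
  if (!is.null(label_rs)) {
    lab_c <- crop_center(label_rs, cfg$crop_xy)
    stack$label <- array(as.integer(lab_c$values > 0.5), dim(lab_c$values))
  }
  structure(stack, class = "slice_stack")
}

#' @export
print.slice_stack <- function(x, ...) {
  d <- dim(x$ct)
  cat(sprintf("slice_stack: %d planes of %dx%d (%s mm)%s\n", d[3], d[1], d[2],
              paste(signif(x$spacing, 4), collapse = "x"),
              if (is.null(x$label)) "" else ", labeled"))
  invisible(x)
}

# number of planes in a stack
stack_planes <- function(stack) dim(stack$ct)[3]

# assemble a [H, W, 2, N] network input from stack planes
stack_input <- function(stack, planes = seq_len(stack_planes(stack))) {
  H <- dim(stack$ct)[1]; W <- dim(stack$ct)[2]
  x <- array(0, c(H, W, 2L, length(planes)))
  x[, , 1L, ] <- stack$ct[, , planes]
  x[, , 2L, ] <- stack$pet[, , planes]
  x
}

# voxel volume of a stack/grid in ml
voxel_volume_ml <- function(spacing) prod(spacing) / 1000
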