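#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored with mm voxel spacings in the header and a diagonal
#' qform carrying the grid origin; data are written in double precision so
#' synthetic volumes round-trip exactly.
#'
#' @param v a [volume_grid()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   [volume_grid()].
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume_grid"))
  a <- v$values
  attr(a, "pixdim") <- v$spacing
  img <- RNifti::asNifti(a, datatype = "double")
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param modality modality tag to attach on read.
#' @export
read_volume <- function(path, modality = c("PET_SUV", "CT_HU", "MASK")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- RNifti::xform(img)[1:3, 4]
  vals <- array(as.numeric(img), dim(img))
  volume_grid(vals, spacing, modality, origin)
}

#' Write a phantom case to disk
#'
#' Emits `ct.nii.gz`, `pet.nii.gz`, `label.nii.gz` and a `truth.json` with
#' the generative parameters (true blood SUV, geometry, seed).
#'
#' @param case one element of a [make_dataset()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(case$ct, file.path(dir, "ct.nii.gz"))
  write_volume(case$pet, file.path(dir, "pet.nii.gz"))
  lab <- volume_grid(case$label$mask + 0, case$label$spacing, "MASK",
                     case$label$origin)
  write_volume(lab, file.path(dir, "label.nii.gz"))
  spec <- case$truth$spec
  spec$lesion_list <- lapply(spec$lesion_list, unclass)
  truth <- list(case_id = case$case_id, seed = case$seed,
                true_bsuv = case$truth$true_bsuv, spec = unclass(spec))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom case written by [write_phantom_case()]
#'
#' @param dir case directory.
#' @return list with `ct`, `pet`, `label` ([volume_grid()]s / mask) and the
#'   parsed `truth` metadata.
#' @export
read_phantom_case <- function(dir) {
  lab <- read_volume(file.path(dir, "label.nii.gz"), "MASK")
  list(ct = read_volume(file.path(dir, "ct.nii.gz"), "CT_HU"),
       pet = read_volume(file.path(dir, "pet.nii.gz"), "PET_SUV"),
       label = structure(list(mask = array(as.integer(lab$values > 0.5),
                                           dim(lab$values)),
                              spacing = lab$spacing, origin = lab$origin),
                         class = "lumen_label"),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}
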