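# Shared fixtures: everything is generated in code, nothing is stored.

# a clean (noiseless, unblurred, lesion-free) default phantom
clean_spec <- function(...) {
  defaults <- list(noise_sigma = 0, psf_fwhm = 0, ct_noise_sigma = 0)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# world coordinates of voxel centres for a spec
axes_of <- function(spec) {
  list(x = (seq_len(spec$grid_shape[1]) - 1) * spec$voxel_spacing[1],
       y = (seq_len(spec$grid_shape[2]) - 1) * spec$voxel_spacing[2],
       z = (seq_len(spec$grid_shape[3]) - 1) * spec$voxel_spacing[3])
}

# nearest voxel index (1-based) to a world coordinate along one axis
vox_at <- function(world, spacing) round(world / spacing) + 1L

# a small trained-enough network fixture is intentionally avoided: tests that
# need predictions use untrained nets (shape/determinism contracts) or train
# tiny ones on the spot.
tiny_net <- function(base = 2L, depth = 2L, seed = 42L) {
  build_unet(unet_config(base, depth), seed = seed)
}
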