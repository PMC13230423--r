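# A desk-scale phantom (24 x 24 x 4 grid) used by the unit tests; the
# acceptance suite uses the full default 64 x 64 x 8 geometry.
small_phantom_spec <- function(noise_sigma = 0, seed = 1L, ...) {
  phantom_spec(
    dims = c(24L, 24L, 4L, 30L),
    tissue = list(
      core = list(
        class = tissue_class("core", cbf = 0.002, mtt = 8, delay = 0),
        box = rbind(c(12, 2, 1), c(17, 7, 2))
      ),
      penumbra = list(
        class = tissue_class("penumbra", cbf = 0.00875, mtt = 6, delay = 7.5),
        box = rbind(c(2, 2, 1), c(9, 9, 3))
      )
    ),
    # vessel boxes separated by more than the 8-voxel search radius so ROI
    # correction cannot jump from the artery onto the (higher-AUC) vein
    aif_box = rbind(c(18, 2, 3), c(20, 4, 4)),
    vof_box = rbind(c(18, 19, 3), c(20, 21, 4)),
    landmarks = data.frame(
      name = c(paste0("AIF_", 0:4), paste0("VOF_", 0:2)),
      x = c(18, 19, 20, 18, 19, 18, 19, 20),
      y = c(2, 2, 2, 3, 3, 19, 20, 21),
      z = c(3, 3, 3, 4, 4, 3, 3, 4),
      stringsAsFactors = FALSE
    ),
    noise_sigma = noise_sigma,
    seed = seed,
    ...
  )
}

# standard clean arterial enhancement curve used across tests
test_aif <- function(n_frames = 30L, dt = 1.5) {
  make_bolus_curve(bolus_params(150, 6, 2, 1.5), n_frames, dt)
}
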