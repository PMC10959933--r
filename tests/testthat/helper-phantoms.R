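# Shared miniature phantom geometries used across the suite. Small extents
# keep rendering fast; proportions (band thicknesses relative to the axial
# extent, pit and hole relative to the field) mirror the native anatomy.

tiny_spec <- function(...) {
  args <- list(...)
  base <- list(
    n_slices = 16L, n_axial = 192L, n_lateral = 96L, scan_width = 2400,
    axial_pitch = 3.2,
    layer_thicknesses = c(nfl = 15, gcl = 25, ipl = 25, inl = 25, opl = 20,
                          onl = 60, elm = 8, ez = 15, rpe = 20, choroid = 80),
    pit_depth = 60, pit_width = 700, hole_diameter = 350, noise_sd = 6,
    seed = 1L)
  base[names(args)] <- args
  do.call(phantom_spec, base)
}

# Taller geometry for registration: enough axial headroom that rotations of
# a few degrees keep the retina inside the field.
reg_spec <- function(...) {
  tiny_spec(n_slices = 24L, n_axial = 480L, n_lateral = 64L,
            scan_width = 3000, axial_pitch = 2.6, noise_sd = 0, ...)
}

# Grid points (um) of a truth RPE surface, in (slice, axial, lateral) order.
truth_rpe_points <- function(case) {
  g <- case$post$geometry
  s <- g$n_slices
  l <- g$n_lateral
  cbind(rep((seq_len(s) - 1) * g$slice_pitch, l),
        as.vector(case$truth$rpe_surface),
        rep((seq_len(l) - 1) * g$lateral_pitch, each = s))
}

smoke_vae_config <- function(...) {
  args <- list(...)
  base <- list(image_size = 64L, base_channels = 8L, latent_dim = 32L,
               fc_hidden = c(256L, 128L, 64L, 64L), batch_size = 32L,
               max_epochs = 12L, recon_switch_epoch = 12L, kld_warmup = 8L,
               lr = 1e-3, seed = 11L)
  base[names(args)] <- args
  do.call(octvae_config, base)
}
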