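# Shared phantom configurations. "Analytic" settings (no noise, no background,
# hard-edged nuclei, no misalignment) make rasterization exactly invertible so
# truth-table comparisons can be exact.

analytic_phantom_config <- function(n_cells = 25L, seed = 11L,
                                    tissue_extent = c(88, 88, 30),
                                    divisions_max = 8L, ...) {
  phantom_config(n_cells = n_cells, seed = seed, tissue_extent = tissue_extent,
                 divisions_max = divisions_max, noise_sd = 0,
                 background_level = 0, misalignment_range = c(0, 0, 0),
                 edge_softness_px = 0, ...)
}

# A single mid-field section with plenty of nuclei, used as stitching content.
dense_section <- function(seed = 5L, extent_px = 128, n_cells = 60L) {
  cfg <- phantom_config(n_cells = n_cells, seed = seed,
                        tissue_extent = c(extent_px * 0.44, extent_px * 0.44, 12),
                        misalignment_range = c(0, 0, 0), noise_sd = 2,
                        non_touching = FALSE)
  ph <- generate_phantom(cfg)
  ph$sections[[3L]]
}
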