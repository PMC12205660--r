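# Shared fixtures, built in code.

# A small multi-phase study with analytic enhancement (no noise) on a
# cuboid tumor; `pe_map` optionally assigns per-voxel kinetics.
make_study <- function(dims = c(12, 12, 10), times = c(0, 60, 120, 180),
                       kin = c(wash_in = 0.03, wash_out = 0.002, pe = 1.5),
                       mask_box = list(4:9, 4:9, 3:8), timepoint = "T0",
                       s0 = 100) {
  mask <- array(0L, dim = dims)
  mask[mask_box[[1]], mask_box[[2]], mask_box[[3]]] <- 1L
  phases <- lapply(times, function(t) {
    v <- array(0.35 * s0, dim = dims)
    e <- enhancement_curve(t, kin["wash_in"], kin["wash_out"], kin["pe"])
    v[mask > 0] <- s0 * (1 + e)
    v
  })
  structure(list(patient_id = "TST01", timepoint = timepoint,
                 phases = phases, phase_times_s = times,
                 voxel_spacing_mm = c(1, 1, 1), tumor_mask = mask),
            class = "dce_study")
}

# Tiny-grid phantom config for fast cohort-level tests.
tiny_phantom <- function(n, seed = 1L, ...) {
  phantom_config(n_patients = n, grid_shape = c(14L, 14L, 12L),
                 seed = seed, ...)
}

# Small network config exercising every code path cheaply.
tiny_sti_config <- function(...) {
  sti_config(patch_shape = c(16L, 16L, 16L), embed_dim = 16L,
             encoder_channels = c(4L, 6L), n_heads_spatial = 2L,
             n_heads_temporal = 2L, ...)
}
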