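# Shared builders for fast test configurations.

# A short single-gap bed: 2 mm long channel with one 10 um pillar gap.
toy_bed <- function(length_mm = 2, spacing_um = 10, size_um = 10,
                    depth_um = 50, width_mm = 0.1) {
  bed_geometry(length_mm, width_mm, depth_um, "circular",
               size_um, spacing_um, 1)
}

fast_cfg <- function(seed = 1, n = 1000, halfwidth = 0.02, ...) {
  simulation_config(n_particles_per_batch = n, max_batches = 20,
                    seed = seed, convergence_halfwidth = halfwidth, ...)
}

# Absorbing-wall plug-flow run on an arbitrary (D, u, gap, L) combination,
# for comparison against the closed-form slab survival series.
absorbing_run <- function(D, u_mean, gap_um, length_mm, n = 10000, seed = 1) {
  bed <- toy_bed(length_mm = length_mm, spacing_um = gap_um)
  # choose Q to give the requested interstitial velocity
  q_m3s <- u_mean * bed_open_area_for_test(bed)
  ctx <- transport_context(q_m3s * 60 * 1e9, diffusivity = D)
  kin <- kinetics_params("per_encounter", p_encounter = 1,
                         encounter_radius_nm = 1)
  cfg <- simulation_config(
    n_particles_per_batch = ceiling(n / 2), max_batches = 2, seed = seed,
    convergence_halfwidth = Inf, launch = "uniform", profile = "plug"
  )
  res <- simulate_bed(bed, ctx, kin, cfg)
  expected <- 1 - slab_survival(D, gap_um * 1e-6,
                                length_mm * 1e-3 / u_mean)
  list(mc = res$recovery, closed_form = expected)
}

bed_open_area_for_test <- function(bed) {
  frac <- bed$pillar_spacing / (bed$pillar_spacing + bed$pillar_size)
  bed$width * bed$depth * frac
}
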