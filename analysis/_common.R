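# Shared study configuration for the analysis scripts.
# Bench scale: 3-ring scanner for margin sweeps; 6-ring for 2D-vs-3D.

BENCH_GEO <- build_geometry(n_rings = 3, ring_pitch_mm = 6, n_angles = 32,
                            n_radial = 112, radial_pitch_mm = 2.44,
                            max_ring_difference = 2)
AXIAL_GEO <- build_geometry(n_rings = 6, ring_pitch_mm = 6, n_angles = 32,
                            n_radial = 112, radial_pitch_mm = 2.44,
                            max_ring_difference = 5)
SARGS <- list(scatter_grid_mm = 8, coarse_angles = 16, coarse_radial = 28)
BENCH_PHANTOM <- list(head_radius_mm = 70, skin_thickness_mm = 7,
                      regions = default_regions(70))
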