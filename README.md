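# acfmargin

Desk-scale simulation study of **scatter-scaling failure under
transmission–emission mismatch in brain PET**, and of the ACF-margin that
cures it.

Model-based scatter correction (single scatter simulation, SSS) fixes the
scale of its scatter estimate by fitting it to the measured counts in the
sinogram *tail* — bins outside the head, identified by thresholding the
attenuation correction factor (ACF) sinogram at 1.03. If the patient moves
between the transmission scan and the emission scan, the ACF object band is
displaced relative to the emission data and true emission LORs — notably
from tracers with prominent skin/rim uptake, such as P-gp substrates — leak
into the nominal tail:

```
s_p = Σ_tail( y · m ) / Σ_tail( m² )        (per-plane tail fit, clamped ≥ 0)
```

so the fitted scale `s_p` is biased upward, scatter is over-subtracted, and
reconstructed activity and the volume of distribution

```
V_T = K1/k2            (single-tissue model with blood volume fraction Vb)
V_T = K1/k2 (1+k3/k4)  (reversible two-tissue model)
```

drop in rim-adjacent regions. The **ACF-margin** dilates the
above-threshold object band radially by a fixed number of bins *before*
extracting the tail (attenuation correction itself is untouched), moving
the contaminated bins out of the fit.

The package implements the full chain with known ground truth:

| module | contents |
|---|---|
| scanner model | cylindrical geometry, exact-adjoint ray projectors, ACF, Poisson noise (`build_geometry`, `forward_project`, `compute_acf`, …) |
| phantom factory | head phantoms with a skin rim, three tracer kinetic profiles, the printed 20/16-frame protocols, Feng-type input functions, full dynamic acquisitions with a rigid μ-map mismatch (`make_head_phantom`, `simulate_acquisition`, …) |
| scatter | Klein–Nishina physics, 2D/3D SSS with energy-window acceptance, ACF tail masks with margins, tail fitting (`sss_estimate`, `tail_mask`, `fit_tail_scale`, `scatter_correct`) |
| reconstruction | ordinary-Poisson OSEM (12 iterations × 16 subsets default) with additive scatter, dynamic pipeline (`osem_reconstruct`, `reconstruct_dynamic`) |
| kinetics | plasma-input 1T/2T models with Vb, LM fitting, VOI TACs (`model_tac`, `fit_tac`, `voi_tacs`) |
| motion QC | √(Δx²+Δy²+Δz²), NCC rigid registration, frame QC (`motion_qc_frames`) |
| experiments | margin sweeps and 2D-vs-3D comparisons (`run_margin_sweep`, `run_sss_mode_comparison`) |

## Worked example

A skin-rim phantom scanned once with an aligned μ-map and once with the
μ-map shifted 5 mm, then tail-fitted at increasing ACF-margins:

```r
library(acfmargin)

g   <- desk_geometry()                       # 8 rings, 96 x 128 @ 2.44 mm
ph  <- make_head_phantom(phantom_spec(head_radius_mm = 88,
                                      skin_thickness_mm = 5), g, nx = 64)
sa  <- list(scatter_grid_mm = 10, coarse_angles = 20, coarse_radial = 28)

for (shift in c(0, 5)) {
  acq <- simulate_acquisition(ph, tracer_profile("verapamil_like"),
                              frame_schedule(3600), make_input_function(),
                              g, mismatch = rigid_shift(shift, 0, 0),
                              scatter_fraction = 0.35, counts_total = 2e6,
                              seed = 11, sss_args = sa)
  fr  <- acq$frames[[1]]
  m   <- do.call(sss_estimate, c(list(fr$truth, acq$mu_delivered, g), sa))
  r   <- sapply(seq(0, 14, 2), function(mar)
           fit_tail_scale(fr$emission, m,
                          tail_mask(acq$acf, 1.03, mar))$global_scale /
             fr$s_star)
  cat(sprintf("shift %d mm:  %s\n", shift,
              paste(sprintf("%.3f", r), collapse = "  ")))
}
```

which prints (margins 0, 2, …, 14 bins; fitted / true scatter scale):

```
shift 0 mm:  1.015  1.008  1.008  1.008  1.004  1.004  1.009  1.007
shift 5 mm:  1.230  1.031  1.034  1.034  1.039  1.041  1.042  1.048
```

Aligned, the tail fit recovers the true scale within ~1.5 % at every
margin. With a 5-mm mismatch the margin-0 fit overestimates the scatter
scale by 23 % — real rim emission contaminates the tail — and any margin
that clears the displaced rim restores the estimate to within ~5 %.

## Analysis workflow

The study itself lives in `analysis/`, thin numbered drivers over the
package functions; each prints what it found and writes tables under
`results/`:

```sh
Rscript analysis/01_simulate.R             # write example acquisitions + manifest
Rscript analysis/02_margin_sweep.R         # V_T vs margin, aligned and 5-mm shifted
Rscript analysis/03_sss_mode_comparison.R  # 2D vs 3D SSS, V_T ratios per VOI
Rscript analysis/04_motion_qc.R            # frame motion QC table
```

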