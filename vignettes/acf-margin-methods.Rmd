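---
title: "Scatter scaling under transmission-emission mismatch: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scatter scaling under transmission-emission mismatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(acfmargin)
```

## The problem

Model-based scatter correction in brain PET estimates the *shape* of the
single-scatter contribution by simulation and fixes its *scale* by fitting
the model to measured counts in sinogram bins outside the head — the
scatter tail, where every recorded coincidence must be scatter. The tail is
identified on the attenuation correction factor (ACF) sinogram: bins with
ACF at most a threshold (1.03 by default) saw essentially no attenuating
tissue and are treated as background.

This breaks when the patient moves between the transmission scan (which
produces the attenuation map, hence the ACF) and the emission scan. The
object band of the ACF sinogram is then displaced relative to the emission
data, true emission LORs — especially from tracers with high skin/rim
uptake — leak into the nominal tail, and the fitted scatter scale is biased
upward. Over-subtracted scatter depresses reconstructed activity and, after
kinetic modelling, the volume of distribution \(V_T\), most visibly in
regions adjacent to the rim.

The remedy studied here is the *ACF-margin*: before extracting the tail,
the above-threshold object band is dilated along the radial axis by a fixed
number of bins. The margin affects **only** the scatter scaling; attenuation
correction always uses the undilated ACF. This package implements the whole
chain — scanner model, phantom/acquisition simulator, 2D/3D single scatter
simulation (SSS), tail fitting, OSEM reconstruction, kinetic modelling, and
motion QC — so the mechanism and its cure can be reproduced end to end at
desk scale with known ground truth.

## Scanner model

A parallel-beam sinogram parameterisation is used: per axial plane, bins
are (projection angle × signed radial offset); planes are grouped into
segments by ring difference, and each (segment, plane) pair is one ordered
ring pair, with oblique LORs tilting axially between their two ring
positions. Endpoints sit on a detector circle of radius 1.5× the FOV
radius — the bore-to-FOV proportion of a dedicated brain scanner. That
ratio matters: with a bore barely larger than the FOV, the inverse-square
detector terms make the simulated scatter tail unphysically sensitive to
small displacements of the attenuation map.

Projection is ray sampling with trilinear interpolation; back projection
uses the identical sample positions and weights, so the pair is exactly
adjoint (the dot-product test holds to floating point). The default
geometry has 8 rings, 96 angles and 128 radial bins at 2.44 mm pitch —
twice the HRRT voxel pitch, scaled so a 180-mm head fits the FOV while the
full margin ladder (0–14 bins) still leaves usable tails. The
margin-in-voxels to millimetre conversions quoted for the clinical system
(8 voxels ≈ 10 mm, 14 ≈ 17 mm) refer to its native 1.22-mm pitch.

## Single scatter simulation

For each LOR \((A, B)\) the estimator sums over scatter points \(S\) (an
8-mm grid restricted to attenuating tissue):

* emission line integrals along \(A\!-\!S\) or \(S\!-\!B\);
* attenuation at 511 keV on the unscattered leg and, on the scattered leg,
  scaled by the total Klein–Nishina cross-section ratio
  \(\sigma(E')/\sigma(511)\);
* the Klein–Nishina differential weight at the scattering angle, with
  \(E' = 511/(2-\cos\theta)\);
* inverse-square distances to both detectors; and
* an energy-window acceptance: a step at the lower level discriminator
  (400 keV) smoothed by a Gaussian energy resolution of 17 % FWHM,
  both configurable — values typical of a dedicated brain system.

The estimate is computed on a coarse (angle × radial) grid and bilinearly
interpolated to full resolution; the scatter sinogram is smooth by
construction, and halving the scatter-point grid changes the estimate by
under 3 % RMS (tested).

**2D versus 3D.** `sss3d` evaluates every segment's true oblique geometry
with volumetric scatter points. `sss2d` takes only scatter coincidences in
non-oblique planes into account: each direct plane is evaluated with
scatter points and endpoints confined to that plane, and oblique planes are
filled by axial-midpoint interpolation between direct planes. The two
definitions therefore differ in the *physics*, not merely the fill: with
full-3D physics on direct planes the modes agree to a fraction of a percent
everywhere and no 2D-vs-3D experiment exists. Because the 2D restriction
changes the absolute amount of modelled scatter, the two modes are
comparable only up to the global scale that tail fitting sets downstream;
the collapse/separation tests normalise the models accordingly.

A consequence worth noting: for axially *linear* activity variation the
midpoint fill is exact to first order. The simulator's axial profile option
is therefore a smooth off-centre `tanh` step (hot toward the lower slices,
emulating the steep falloff of uptake toward the vertex), whose curvature
is what genuinely separates the modes.

## Tail masks and tail fitting

The tail mask is the complement of the object band `ACF > threshold`
dilated by the margin along the radial axis only — the mismatch displaces
the object's radial silhouette, and this matches how the widened band looks
on the clinical system. Scale factors are fitted per plane by non-negative
least squares, \(s_p = \sum y m / \sum m^2\) clamped at zero (verified
against a brute-force scan over candidate scales); planes with fewer than
20 tail bins, or a zero model on their tail, are flagged and take the
nearest fitted plane's scale. A pooled (global) scale over all tail bins is
always computed as well; scalar summaries in the reports quote the pooled
scale, while reconstruction uses the per-plane fits.

## The simulator and what "truth" means

`simulate_acquisition()` builds each frame's activity image from regional
compartment-model curves (identical to the kinetics module's — a tested
invariant), projects it through the *aligned* attenuation map to get the
trues, and emulates patient motion by computing the delivered ACF from the
attenuation map rigidly shifted by the configured mismatch while the
emission stays in place. Mismatch magnitudes of a few millimetres (means
~3–5 mm, max under 8 mm) are the clinically observed range.

Ground-truth scatter is generated by the same SSS operator on the true
configuration, scaled so a stated scatter fraction (default 0.35 of total
counts; brain-PET scatter can reach half the events) holds in expectation,
then broadened by a Gaussian **along the angular axis only** (σ = 2 bins)
so that estimator-vs-truth comparisons are not circular. The broadening
axis is deliberate: radial smoothing of the steeply falling tail inflates
it by tens of percent in relative terms and would corrupt the very profile
tail fitting depends on, while angular smoothing decorrelates the shapes
without touching the radial tail. Emission data are Poisson draws with
per-frame seeds derived from the acquisition seed; identical seeds give
bitwise-identical acquisitions.

The reference scale \(s^\*\) attached to each frame is the projection of
the broadened truth onto the unbroadened shape over the aligned margin-0
tail — the value an ideal tail fit should recover.

Default kinetic parameters realise the qualitative tracer profiles rather
than published numbers (none exist for this purpose): the verapamil-like
tracer is single-tissue with low uptake (\(V_T = 1\)) and a skin rim fitted
with threefold uptake; the raclopride-like tracer is reversible two-tissue
with elevated striatal \(k_3/k_4\); the flumazenil-like tracer is
single-tissue with high \(K_1\) (\(V_T = 5\)). Only the verapamil-like
profile has rim uptake above brain — the condition that makes the
mismatch artefact prominent.

## Reconstruction

Ordinary-Poisson OSEM with the forward model \(y = P(x)/\mathrm{ACF} + s\):
attenuation acts on the trues and the tail-scaled scatter estimate is the
additive term in the measured count domain (it is never divided by the
ACF — the model mirrors how the simulator composes the data, and the
choice is recorded here because conventions differ). Defaults are 12
iterations × 16 subsets with bit-reversed subset ordering, uniform
initialisation inside the FOV cylinder, and an optional radial Gaussian PSF
in projection space (off by default; the clinical resolution model is not
reproducible from published information). With one subset the update is
MLEM and conserves total modelled counts exactly each iteration — exactly,
however, only with a zero additive term, since with scatter the EM update
conserves a scatter-weighted functional instead; the conservation test
therefore uses \(s = 0\).

`reconstruct_dynamic()` estimates the scatter shape once from a preliminary
no-scatter reconstruction of the summed frames, then tail-fits the scale
per frame — the shape varies slowly over the scan while the scale tracks
each frame's counts. One scatter-update outer loop is the default; the
margin-sweep experiment uses two, because the shape estimated from the
uncorrected preliminary image carries that image's scatter bias into the
fitted scale, while one update after the first correction essentially
removes it.

## Kinetics

Plasma-input compartment models with a blood volume fraction:
\(C_\mathrm{model} = (1-V_b) C_\mathrm{tissue} + V_b C_b\), with the 1T
impulse response \(K_1 e^{-k_2 t}\) and the reversible-2T bi-exponential;
\(V_T = K_1/k_2\) or \(K_1/k_2 (1 + k_3/k_4)\) holds exactly for every
returned fit. Convolution uses an exact-within-step exponential recursion
on a 1-s grid (the input is piecewise linear), verified against the closed
form for an exponential input to 1e-4. Fits are Levenberg–Marquardt with
box bounds (\(K_1, k_2, k_3, k_4 \in (0, 2]\), \(V_b \in [0, 0.2]\)),
frame-duration weights (the weighting scheme is an assumption — not
specified clinically), and three fixed-seed starts with best-of selection;
non-convergence flags the fit rather than erroring. The synthetic input
function is a Feng-type linear rise followed by three decaying
exponentials; whole blood is plasma × 0.8 in lieu of metabolite modelling.

## Motion QC

Translation-only: the displacement metric is
\(\sqrt{\Delta x^2+\Delta y^2+\Delta z^2}\); registration is exhaustive
normalised cross-correlation over a translation grid with parabolic
refinement (rotations are out of scope — clinical motion is summarised as
displacements). Frame QC registers each frame against a counts-weighted
sum of the first minute, so motion inside that window is undetectable by
design; frames under 10³ counts are skipped as unregistrable.

## Problem sizes and numerical choices

Three frozen study scales serve different purposes:

* **desk** (8 rings, 96×128 @ 2.44 mm, head radius 88 mm, 64² grid) for the
  scatter-scale criteria — it keeps ≥ 14 radial bins of tail beyond the
  head so the whole margin ladder remains fittable;
* **bench** (3 rings, 32×112, head 70 mm, 40² grid) for dynamic
  margin sweeps, where 160 reconstructions must stay affordable;
* **axial** (6 rings, same transverse layout) for 2D-vs-3D, where oblique
  tilts need several ring differences.

Simulated scans use 2×10⁶ counts for single-frame scatter studies and
2×10⁷ for dynamic ones. The OSEM system model samples one point per voxel
pitch (forward and back always share the step, preserving adjointness);
the simulator's reference projections sample at half that. Ties and
degeneracies: tail-fit scales clamp at zero; flagged planes inherit the
nearest fitted plane; zero-count frames reconstruct to zero with a
warning; zero-sensitivity voxels are masked from updates.

## What the synthetic data do and do not show

The generator reproduces the *mechanisms*: rim-uptake tracers, rigid
transmission-emission mismatch, tail contamination, its cure by radial
margins, and the axial-physics difference between 2D and 3D SSS. It omits
randoms, dead time, decay, normalisation, multiple and out-of-FOV scatter,
metabolite kinetics, rotational motion and anatomical realism. Passing
tests therefore demonstrate that the implemented chain behaves as the
mechanism predicts under controlled conditions — not that clinical
magnitudes (tens-of-percent artefacts) are reproduced; those depend on
patient-specific uptake and motion and are deliberately out of scope. In
the same spirit, effect sizes here are smaller than clinical ones: the
margin-sweep V_T changes are a few percent and the central-VOI 3D/2D
\(V_T\) ratio exceeds one by about a percent, mirroring directions, not
magnitudes.

## Known limitations

Single scatter only, no outside-FOV scatter (a known limitation of the
clinical chain as well, reproduced rather than fixed); translation-only
registration; piecewise-constant phantoms with cylindrical heads; V_T at
bench scale carries substantial partial-volume bias in small VOIs —
margin and mode comparisons are therefore always within-pipeline ratios,
which cancel that bias.
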