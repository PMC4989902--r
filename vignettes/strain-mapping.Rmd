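---
title: "Strain mapping of contracting airways in precision-cut lung slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain mapping of contracting airways in precision-cut lung slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A precision-cut lung slice (PCLS) is a thin (~250 µm) living slab of lung in
which an airway, its smooth muscle, and the surrounding alveolar parenchyma
remain mechanically coupled.  When the airway smooth muscle is activated
(e.g. by methacholine), the lumen narrows and the deformation is transmitted
outward through the tethered parenchyma.  The classic readout — lumen area
versus time — collapses all of that spatial mechanics into one number.

`pclstrain` recovers the full picture from an ordinary bright-field
time-lapse: dense per-pixel displacement fields between a reference frame
and every frame of interest, local strain tensors on a regular grid, and
summaries tailored to the annular geometry of an airway — circumferentially
averaged strain as a function of distance to the lumen, kymographs of those
profiles over time, and "spokes" sampled along rays normal to the lumen that
expose directional heterogeneity (a neighbouring vessel or secondary airway
shows up as one deviant section).

## Model and procedure

### Displacements

Frames are first put on a common `[0, 1]` intensity scale and
percentile-stretched (`stretch_contrast`, defaults 2nd–98th percentile; the
exact percentiles are configuration, not science).  Displacements from the
reference frame to a target frame are estimated by a coarse-to-fine dense
optical flow: a Gaussian image pyramid (factor 0.5 per level), and at each
level several iterations of warp → gradient → per-pixel 2×2 weighted
least-squares solve, with the spatial weighting done by a Gaussian window.
Warping uses Catmull–Rom bicubic interpolation: bilinear warping attenuates
fine speckle unevenly with subpixel phase, and that interpolation bias
appears directly as spurious strain.  After each iteration the field is
lightly smoothed with a plain Gaussian; this regularises weakly textured
spots without biasing affine motions, because Gaussian smoothing preserves
fields linear in position.

The estimator is validated, not trusted: a rendered rigid shift of
(+3, −2) px must be recovered within 0.2 px, flow must be antisymmetric
under frame exchange, a 10° whole-frame rotation must produce strains below
0.01 everywhere in the interior, and the contraction benchmark below must be
reproduced within a stated fraction of peak strain.  Any estimator meeting
this contract could be substituted.

### Strain

With reference coordinates $(X, Y)$ and deformed coordinates
$(x, y) = (X + u, Y + v)$, the deformation gradient
$F = \partial(x, y)/\partial(X, Y)$ is formed from the four displacement
samples at $(X \pm h, Y)$ and $(X, Y \pm h)$ by central differences
(exact for displacement fields linear in position).  The Lagrangian strain

$$E = \tfrac{1}{2}(F^\top F - I)$$

is invariant to rigid motion: whole-slice drift changes the displacement
field but not the strain field.  Its eigenvalues follow from the invariants
$I_1 = E_{11} + E_{22}$ and $I_2 = E_{11}E_{22} - E_{12}^2$:

$$\lambda_\pm = \frac{I_1 \pm \sqrt{I_1^2 - 4 I_2}}{2},
\qquad I_1^2 - 4I_2 = (E_{11}-E_{22})^2 + 4E_{12}^2 \ge 0 ,$$

so both are always real.  For a contracting airway the major eigenvalue
$\lambda_+$ is essentially the radial strain (expansive, positive) and the
minor $\lambda_-$ the circumferential strain (compressive, negative); the
package uses those labels as nomenclature without projecting onto geometric
axes.  The major eigenvector is proportional to
$(E_{12}, \lambda_+ - E_{11})$ and its sign is fixed by the convention that
a component points toward the lumen.  Two degenerate cases are handled
explicitly: a diagonal tensor with $E_{11} > E_{22}$ (the formula's row
vanishes; the eigenvector is the x-axis) and a truly repeated eigenvalue
(any direction works; the unit radial direction toward the lumen is used).
An exactly tangential eigenvector keeps its input sign.

Strains are evaluated on a regular grid (default spacing 7 px, matching the
display convention of showing displacement of 7×7 px sub-regions), with the
stencil half-width tied to the spacing (`h = 7 px`) so the strain resolution
is self-consistent.  Values at grid points off the tissue mask are set to
zero for display, and excluded (not averaged as zeros) from every profile
statistic — including them would bias bin means toward zero.

### Tissue and lumen segmentation

Tissue is textured; lumen interior, agarose voids and background are smooth,
whatever their brightness.  The tissue mask therefore thresholds a local
standard-deviation map (Gaussian window σ = 2 px) with Otsu's criterion,
bridges speckle gaps by morphological closing (disc radius 5 px), erodes by
the estimator's support (disc radius 3 px) so boundaries land on the texture
edge, and cleans small components (<100 px) and holes (<200 px).  Both the
SD map and the threshold are normalised, making the mask invariant to global
intensity scaling.  If Otsu's two-class assumption fails — the "background"
class is not markedly smoother than the "tissue" class — the frame is
treated as all tissue.

The lumen is segmented by two competing methods — bright-component
thresholding (Otsu, keep the component at the seed) and tolerance-based
region growing from the seed — and the candidate whose boundary has the
higher mean gradient magnitude wins (ties go to the larger region).  A valid
lumen must be markedly smoother than the shell of wall tissue immediately
around it; a frame of pure speckle is a segmentation error, not a guess.
Per-frame segmentation is seeded with the previous frame's centroid.  An
ellipse is fitted to the boundary pixels by direct least squares (conic with
the ellipse constraint) for the spokes geometry and reporting.

### Radial profiles, kymographs, spokes

Distance to the airway is the exact Euclidean distance transform of the
lumen mask, in µm.  (Distance, strain) couples are sorted into half-open
15 µm bins and averaged per bin; empty bins are missing, never zero.  By
default binning uses the *reference-frame* lumen: the strains are Lagrangian
quantities indexed by reference position, so the Lagrangian-consistent
distance is the reference one.  A configuration flag (`distance_from =
"frame"`) switches to the per-frame segmented lumen for users who want the
per-frame convention.  Stacking profiles over frames gives the kymograph;
fixed-distance rows (defaults 0, 15, 30, 45, 60 µm, containment rule) give
the time series.

Spokes: the area around the airway is split into 8 equal angular sections
(section 1 starts at polar angle 0 by convention), each holding 7 rays that
start on the lumen ellipse at angularly equispaced points and extend along
the local ellipse normal with a fixed radial step (default one strain-grid
cell, 7 px ≈ 8 µm) up to 400 µm.  Displacements at sample points are
bilinearly interpolated and projected on the inward ray direction; strains
are computed at each sample point from four bilinearly interpolated stencil
displacements, and the radial/circumferential values reported along spokes
are the eigenvalues (not projections of E onto the ray).  Means and standard
deviations are taken over each section's rays at each radial position.

## The synthetic-data generator

No recordings are distributed with the package, so validation rests on a
simulator with exact analytic truth.

* **Texture** — multi-octave Gaussian speckle: octaves at the feature scale
  (4 px) and at 4× and 16× that scale with weights (1, 0.5, 0.3).  The
  coarse octaves are not cosmetic: bright-field tissue images have structure
  at many scales, and it is exactly that coarse structure which survives
  pyramid downsampling and lets flow lock onto large motions.  A
  single-band speckle is an unrealistically adversarial input for any
  pyramidal estimator.
* **Contraction kinematics** — a circular lumen of reference radius
  $R_0$ = 100 µm contracts to $r_0$ = 80 µm.  The default map is
  area-preserving, $r(R) = \sqrt{R^2 - R_0^2 + r_0^2}$, because parenchyma
  is nearly incompressible in-plane at these scales and the strains have
  closed forms: $E_{rr} = ((\mathrm{d}r/\mathrm{d}R)^2 - 1)/2$ with
  $\mathrm{d}r/\mathrm{d}R = R/r$, and $E_{\theta\theta} = ((r/R)^2 - 1)/2$.
  At the wall these give $E_{rr} = 0.28125$ (radial stretch) and
  $E_{\theta\theta} = -0.18$ (circumferential compression) — the sign
  structure the whole analysis is meant to reveal.  An exponential-decay
  mode ($r(R) - R = (r_0 - R_0)e^{-(R-R_0)/L}$, default $L$ = 60 µm)
  emulates the steeper strain decay seen beyond ~120 µm in real slices.
* **Temporal profile** — `r0_trajectory()` falls logistically from $R_0$
  toward $r_0$ during the agonist phase (midpoint 150 s, time constant
  60 s) and recovers exponentially (time constant 120 s) after the relaxant
  at $t_1$ = 600 s: fast narrowing, a slower asymptotic phase, then
  dilation.
* **Rendering** — frames are backward-warped from the texture through the
  exact inverse map (bilinear), the lumen drawn bright and smooth (0.95),
  the beyond-tissue background smooth (0.85), tissue texture mapped to
  [0.05, 0.80], and Gaussian noise of SD 0.01 added.  Calibration matches
  the acquisition the package targets: 1.15 µm/px, 1 frame / 2 s.  Rigid
  and stretch movies mirror-pad the texture so content entering the field
  of view is genuine texture — tissue does not end at the image border in
  a real recording.
* **Heterogeneity** — an optional stiff circular inclusion (radius 40 µm,
  cosine-blended over 20 µm, centred 150 µm from the airway at polar angle
  22.5° so it sits wholly inside one spokes section) that does not deform,
  emulating a collapsed vessel or secondary airway.

What the generator does *not* emulate: uneven illumination, focus drift,
out-of-plane motion, non-axisymmetric muscle activation, viscoelastic
agarose, and the irregular anatomy of real parenchyma.  Passing the
synthetic benchmarks therefore demonstrates that the estimator and the
bookkeeping are correct under controlled kinematics — not that every real
slice will be tracked with the same accuracy.

## Numerical choices

* Flow defaults: 4 pyramid levels (scale 0.5), integration window 21 px,
  6 iterations per level, presmoothing σ = 1.1 px, flow smoothing σ = 3 px,
  per-iteration step cap of half a window.  The window and smoothing were
  chosen on the validation suite: with fewer levels a 10° rotation does not
  converge, and with a 15 px window the spurious strains under rigid motion
  exceed 0.01 on some texture seeds.  Larger windows trade spatial
  resolution of the strain field for noise robustness; at 21 px the
  contraction profiles are still recovered within a few percent of peak.
* The per-pixel 2×2 solve carries a small Tikhonov term (10⁻⁶ of the mean
  gradient energy) so flat windows yield zero update rather than noise.
* Pyramid levels are capped so the coarsest image stays ≥ 32 px, and the
  window σ is clamped to fit small levels.
* All Gaussian smoothing uses replicate boundaries; circular (FFT)
  boundaries would wrap content across frame edges.
* Degenerate inputs: constant frames yield an all-zero stretch with a
  warning and an empty tissue mask; an empty mask makes all strains zero
  with a warning; segmentation failure on >20% of frames is an error, below
  that failed frames are interpolated with a warning.
* Determinism: every source of randomness (texture, rendering noise) is
  seeded; repeated runs with the same configuration produce byte-identical
  CSV outputs.

## Validation problem sizes

The shipped tests and the acceptance script use: the canonical contraction
movie at 440×440 px (1.15 µm/px; tissue annulus 100–220 µm, so profiles are
validated to ~105 µm from the wall over seven 15 µm bins), rigid-motion and
stretch movies at 256×256 px, and a smaller contraction movie (R0 = 60 →
48 µm, same 0.64 area ratio) for the command-line and determinism checks.
These sizes keep a full validation run in the low minutes on one CPU while
leaving every geometric regime of the method exercised; nothing in the
implementation depends on them.

## Worked example

```{r example}
library(pclstrain)

# a synthetic bronchoconstriction recording with known ground truth
sq <- simulate_scenario("annulus", seed = 11, shape = c(440L, 440L),
                        n_frames = 2L)   # R0 = 100 um -> r0 = 80 um

lum <- segment_lumen(sq$frames[[1]])
ell <- fit_ellipse(lum)
fld <- estimate_displacement(sq, 2)
sf  <- strain_field(fld, grid_spacing = 7, h = 7,
                    mask = tissue_mask(sq$frames[[1]]),
                    lumen_center = ell$center)
prof <- bin_average(sf, distance_map(lum, sq$pixel_size), bin_width = 15)
head(prof, 4)
# near the wall the radial (major) strain is expansive and the
# circumferential (minor) strain compressive, decaying with distance

spk <- build_spokes(ell, frame_shape(sq), sq$pixel_size)
dp  <- spoke_displacement_profile(fld, spk)
subset(dp, distance_um == 0)   # ~20 um inward displacement, all sections
```

## Known limitations

* Strain estimates in the first ~8 µm from the lumen edge are biased low:
  the finite-difference stencil straddles the featureless lumen where flow
  is extrapolated, an effect any image-correlation method shares at a
  texture boundary.  Bin means are compared against identically binned
  closed forms for exactly this reason.
* The flow assumes locally smooth motion; a true material discontinuity
  (slippage, tearing) will be smoothed over a window width.
* 2-D analysis of a 3-D slab: out-of-plane motion appears as apparent
  in-plane strain.
* Stress is out of scope — it needs a constitutive model; this package
  measures kinematics only.
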