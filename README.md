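# pclstrain

Spatio-temporal strain mapping of contracting airways in precision-cut
lung slices (PCLS).

A PCLS is a thin living slab of lung tissue in which an airway, its smooth
muscle and the surrounding alveolar parenchyma stay mechanically coupled.
During agonist-driven bronchoconstriction the classic readout — lumen area
versus time — discards all spatial mechanics.  `pclstrain` recovers them
from ordinary bright-field time-lapse movies:

* **dense displacement fields** between a reference frame and each frame of
  interest, by coarse-to-fine optical flow;
* **Lagrangian strain tensors** `E = (FᵀF − I)/2` on a regular evaluation
  grid, with the deformation gradient `F` from central differences of the
  displacements; the principal strains follow from the invariants,
  `λ± = (I₁ ± √(I₁² − 4I₂))/2`, with the major (≈ radial) eigenvector
  oriented toward the lumen.  `E` is invariant to whole-slice rigid motion,
  which the displacement field is not;
* **lumen segmentation and ellipse fitting**, giving the airway-caliber
  time series;
* **radial profiles and kymographs**: strain averaged circumferentially in
  15 µm bins of distance-to-airway, stacked over time;
* **spokes analysis**: displacement and strain sampled along rays normal to
  the lumen in 8 angular sections × 7 rays, exposing directional
  heterogeneity (vessels, secondary airways);
* a **synthetic contraction simulator** with exact analytic displacement
  and strain ground truth (area-preserving annular contraction:
  `E_rr = ((R/r)² − 1)/2`, `E_θθ = ((r/R)² − 1)/2`), used to validate the
  entire pipeline end to end.

## Worked example

A synthetic recording of an airway with relaxed lumen radius 100 µm
contracting to 80 µm (calibration 1.15 µm/px), analysed exactly like a real
movie:

```r
library(pclstrain)

sq  <- simulate_scenario("annulus", seed = 11, shape = c(440L, 440L),
                         n_frames = 2L)
lum <- segment_lumen(sq$frames[[1]])
ell <- fit_ellipse(lum)
#> <lumen_ellipse> centre (219.5, 219.5) px, semi-axes 87.3 x 86.3 px, angle 31.1 deg

fld <- estimate_displacement(sq, 2)
#> <displacement_field> 440 x 440 px, frames 1 -> 2, |d| max 19.8 px (22.8 um)

sf   <- strain_field(fld, grid_spacing = 7, h = 7,
                     mask = tissue_mask(sq$frames[[1]]),
                     lumen_center = ell$center)
prof <- bin_average(sf, distance_map(lum, sq$pixel_size), bin_width = 15)
head(prof, 4)
#>   bin_center_um mean_major mean_minor   n
#> 1           7.5      0.193    -0.1595 177
#> 2          22.5      0.167    -0.1199 178
#> 3          37.5      0.117    -0.0947 204
#> 4          52.5      0.091    -0.0768 219
```

The radial (major) strain is expansive and the circumferential (minor)
strain compressive, both largest near the airway wall and decaying with
distance — the closed forms at the wall are `E_rr = 0.28125` and
`E_θθ = −0.18`, and the 15 µm bin means match the identically binned closed
forms to within a few percent of peak.  The spokes see the contraction as a
uniform ~20 µm inward wall displacement in all 8 sections:

```r
dp <- spoke_displacement_profile(fld, build_spokes(ell, frame_shape(sq),
                                                   sq$pixel_size))
subset(dp, distance_um == 0)
#>   section distance_um mean_displacement_um sd_displacement_um n
#> 1       1           0                 19.8              0.105 7
#> 2       2           0                 19.9              0.199 7
#> ...                                   (all sections ≈ 20 µm)
```

and the segmented lumen area ratio is 0.644 against the true
`(80/100)² = 0.64`.

Real movies enter through `load_sequence()` (multipage TIFF or ordered
PNG/TIFF frames with pixel size and frame interval) and the same functions,
or through the command-line interface:

```sh
Rscript inst/cli/pclstrain.R analyze --input movie.tif --out results/ \
        --pixel-size 1.15 --frame-interval 2
Rscript inst/cli/pclstrain.R profile --input movie.tif --out results/
Rscript inst/cli/pclstrain.R spokes  --input movie.tif --out results/
Rscript inst/cli/pclstrain.R simulate --scenario annulus --out fixture/
```

Every figure the commands write has a CSV containing the plotted numbers,
and the effective configuration is echoed to `config.yaml` next to the
outputs.

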