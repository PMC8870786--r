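# trabkit

Quantitative analysis of trabecular bone microarchitecture on 2D grayscale
slices, written for bone researchers comparing imaging modalities:
high-resolution micro-CT (bright bone over dark marrow, ~0.05 mm pixels)
against high-field MRI (bone as a signal void against bright marrow,
~0.13 mm pixels). Because MRI resolution sits at the trabecular dimension
(~0.1–0.2 mm), partial-volume mixing biases every histomorphometric metric;
`trabkit` provides the full measurement pipeline plus the tooling needed to
quantify that bias: a resolution-degradation experiment, slice registration
across modalities, agreement statistics, and a synthetic phantom generator
with exact ground truth so every estimator is testable without cadaveric
data.

## What it computes

Given a segmented region of interest, the standard histomorphometric set:

- **BVF** — bone volume fraction: bone pixels / all in-ROI pixels.
- **Tb.Th, Tb.Sp** (mm) — trabecular thickness and spacing: the
  pixel-weighted mean of the *aperture map*, which assigns to every pixel
  of a phase the diameter of the largest disk fully enclosed in that phase
  and covering the pixel (a sub-pixel local-thickness map computed from an
  exact Euclidean distance transform on a half-integer grid).
- **Tb.N** (1/mm) — trabecular number, defined as BVF / Tb.Th.
- **Tb.OrP, Tb.OrS** (degrees) — principal and secondary trabecular
  orientation. Per-pixel orientations come from the eigenvectors of the
  multi-scale Hessian (Gaussian scales σ = 1…5 px, scale-normalized
  response selection); the orientation histogram over bone pixels is fitted
  with

  `Y = a + m·x + A₁·N(x; μ₁, σ₁) + A₂·N(x; μ₂, σ₂)`

  where `N` is a unit-area Gaussian on wrapped angular residuals. Tb.OrP is
  (μ₁, σ₁); Tb.OrS is reported both as the raw μ₂ and as |μ₂| − μ₁, with
  "ND" when no secondary component is detected.
- **Tb.Int** (degrees) — trabecular interconnectivity: the angular standard
  deviation of the whole orientation distribution about μ₁,
  `sqrt(Σ density(θ)·Δ(θ, μ₁)²)` with Δ the wrapped difference capped at
  90°. Low values mean strictly aligned trabeculae; higher values mean a
  richer set of orientations around the main load axis.
- **Ab.V** (mm³) — air-bubble volume from three-phase (bone/marrow/air)
  segmentation, absolute and relative to an initial fill or to the marrow
  volume.

Supporting operations: automatic local-threshold binarization
(sliding-window Otsu with interpolated thresholds, polarity-aware for
CT-like vs MR-like contrast), integer block-merge resolution degradation
(factor 2: 0.051 → 0.102 mm), mutual-information affine slice-to-stack
registration with Pearson correlation scoring, and Kruskal–Wallis / OLS /
Bland–Altman / intraclass-correlation agreement statistics.

## Worked example

```r
library(trabkit)

# a micro-CT-like phantom: 0.26 mm struts every 1.12 mm, principal
# orientation 67 deg with 12 deg jitter, a 25% secondary family at +90 deg
spec <- phantom_spec(theta_p = 67, sigma_p = 12,
                     secondary_fraction = 0.25, seed = 7)
ph   <- generate_phantom(spec)

mask <- binarize_local(ph$image)
bvf  <- compute_bvf(mask)
tbth <- summarize_thickness(compute_aperture_map(mask, "BONE"))
tbsp <- summarize_thickness(compute_aperture_map(mask, "MARROW"))

dist <- orientation_distribution(hessian_orientation(ph$image), mask)
fit  <- fit_dual_gaussian(dist)
met  <- compute_orientation_metrics(dist, fit)

morphometry_report(bvf, tbth, tbsp,
                   tborp_mean = met$tborp["mean"], tborp_sd = met$tborp["sd"],
                   tbors = met$tbors, tbint = met$tbint)
```

prints

```
<morphometry_report> BVF 0.282  Tb.Th 0.289 mm  Tb.Sp 1.293 mm  Tb.N 0.977 /mm
  Tb.OrP 75.7 +/- 15.2 deg  Tb.OrS 90.7 deg  Tb.Int 42.2 deg
```

against generator ground truth BVF 0.282, Tb.Th 0.285 mm, Tb.Sp 1.293 mm:
the volume fraction is recovered essentially exactly, thickness within 2%,
the principal orientation lands near the 67° family (pulled a few degrees
toward the secondary family, as expected for overlapping networks), and the
secondary component is detected near 67° + 90°. The large Tb.Int reflects
the 25% of bone mass lying 90° away from the principal axis.

## Command line

```sh
Rscript inst/cli/trabkit.R phantom  --spec spec.json --out img.tif
Rscript inst/cli/trabkit.R segment  --in img.tif --modality CT_LIKE --out mask.tif
Rscript inst/cli/trabkit.R morpho   --in img.tif --modality CT_LIKE --out report.csv
Rscript inst/cli/trabkit.R degrade  --in img.tif --factor 2 --out dg.tif
Rscript inst/cli/trabkit.R register --in moving.tif --stack a.tif,b.tif --out reg.json
Rscript inst/cli/trabkit.R stats    --in metrics.csv --reference uCT --out summary.csv
```

Every flag can also live in a JSON config passed as `--config cfg.json`.

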