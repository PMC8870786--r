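---
title: "Trabecular morphometry with trabkit: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular morphometry with trabkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabkit)
```

# The measurement problem

Trabecular bone is a network of struts and plates on the order of 0.1–0.3 mm.
Micro-CT resolves it comfortably (0.05 mm voxels) but cannot be used in
vivo; high-field MRI reaches ~0.13 mm in-plane, right at the trabecular
dimension, so every metric extracted from MRI carries partial-volume bias.
`trabkit` implements a 2D slice-based measurement pipeline for both
modalities and the machinery to characterize that bias: controlled
resolution degradation, cross-modality registration, agreement statistics,
and a phantom generator with exact ground truth.

All angles in the package are strut-axis orientations in degrees on
[0, 180), measured counter-clockwise from the +x (column) axis of a
row-major, top-left-origin raster. Angular arithmetic is modulo 180 with
minimal-difference wrapping. All physical outputs are in mm and degrees;
air volumes are reported in mm³ (when a slice thickness is available) —
the source literature is inconsistent between µm³ and mm³ for this
quantity and `trabkit` standardizes on mm³.

# Segmentation

`binarize_local()` performs automatic local thresholding: overlapping
windows (default side: a quarter of the smaller image dimension, at least
8 px), an Otsu threshold per window on a 256-bin histogram, bilinear
interpolation of the per-window thresholds between window centres, and a
global-Otsu fallback for windows with degenerate content. The construction
is deterministic, invariant to positive affine intensity rescaling, and
robust to the smooth coil-profile shading typical of MR images. Polarity
(bone-bright vs bone-dark) follows the modality tag. Connected bone
components and marrow holes below 4 px are absorbed into the surrounding
phase; without this cleanup, noise speckles contaminate the orientation
distribution and the aperture statistics far out of proportion to their
pixel count.

`segment_three_phase()` splits CT-like images into air/marrow/bone with a
two-threshold (3-class) Otsu criterion, merging air components below 4 px
into marrow; when three intensity modes are not distinguishable it falls
back to two-phase segmentation with an empty air phase and a warning.
`quantify_bubbles()` promotes air areas to volumes via the slice thickness
and reports percentages against a reference initial volume and against the
marrow volume.

# The aperture map and the thickness metrics

The aperture map assigns to every pixel of a phase the diameter of the
largest disk fully enclosed in the phase and covering that pixel. The
phase is modelled as the union of the closed unit squares of its pixels;
candidate disk centres live on the half-integer subgrid and the radius at
a centre is its exact Euclidean distance to the background region,
computed with an exact distance transform (the nearest point of an
axis-aligned background square to any half-integer sample is itself a
half-integer sample, so a point distance transform on the refined grid is
exact, with no approximation). Diameters are real-valued — sub-pixel
precision — and a bar of width w pixels measures exactly w pixel-widths
for odd and even w alike. The implementation is verified against an
exhaustive brute-force oracle (direct minimum over background squares,
explicit propagation) on random masks.

Boundary convention: in-image pixels of *any* other label (marrow, air,
outside-ROI) terminate a disk, but the image border itself does not — a
field-of-view cut must not bias thickness, so disks may extend past the
border, and a mask with no background at all is capped at the image
diagonal. The consequence is that an edge-touching band of a phase has a
half-open geometry and inherits inflated diameters from the open side;
exact-geometry tests therefore wrap their patterns in outside-ROI margins.

Tb.Th (bone) and Tb.Sp (marrow) are the pixel-weighted means of the
positive aperture values — "the mean of the aperture-map distribution"
reads as a per-pixel distribution, and pixel weighting (rather than
per-disk weighting) is what makes a uniform bar measure its nominal
width. Tb.N is always recomputed as BVF / Tb.Th rather than independently
estimated.

# Orientation analysis

Per-pixel orientation comes from the Hessian of the Gaussian-smoothed
image at scales σ = 1…5 px (Gaussian-derivative convolutions, mirror
padding). Eigenvalues are scale-normalized (×σ²) and, per pixel, the scale
with the largest response magnitude is selected — the standard
structure-scale choice; the scale list is a parameter. For a ridge the
dominant eigenvector is transverse to the strut, so the reported axis is
that eigenvector's angle + 90° (mod 180). The dominant eigenvalue is the
most negative one for bright struts (CT-like), the most positive for dark
struts (MR-like), and the largest in magnitude when the modality is
unknown; this makes the orientation field invariant to intensity negation
once the polarity tag is flipped.

The orientation distribution is a unit-mass histogram (default 1° bins)
of orientations over bone pixels. Pixels within twice the largest scale
of the image border are excluded: mirror padding reflects strut
orientations there and the corrupted margin otherwise contributes heavy
spurious tails (this was measured on phantoms — every pixel with > 20°
error against ground truth sat within 8 px of the border).

## The mixture model

The distribution is fitted by nonlinear least squares with

Y = a + m·x + A₁·N(x; μ₁, σ₁) + A₂·N(x; μ₂, σ₂),

N a unit-area Gaussian evaluated on wrapped angular residuals. The
literal printed form of this model has no amplitude parameters, which
cannot match a unit-mass histogram with a baseline, and could never
produce a "not detected" secondary; amplitudes are therefore free by
default (`strict_printed = TRUE` pins them to 1 for comparison).

Numerical choices, all visible in `fit_dual_gaussian()`:

- σ₁, σ₂ are bounded to (bin width, 90°] and amplitudes to (0, 2] via
  logistic reparameterization; the model is penalized for dipping below
  zero (densities are nonnegative). Without these constraints the second
  Gaussian reliably degenerates into a flat surrogate baseline (σ → large,
  amplitude balanced by a negative intercept).
- A fitted component with σ ≥ 60° is classified as baseline, not as an
  orientation band: a wrapped Gaussian that broad is nearly collinear with
  the intercept, while genuine principal bands fit well below that even
  for highly disordered bone.
- Initialization: baseline from a robust line fit to the lowest-density
  quartile, μ₁ at the histogram mode, μ₂ at the residual peak after
  removing the primary component (restricted > 25° away), plus a
  perpendicular-offset start and five jittered restarts (data-derived
  seed; the global RNG state is restored). Nelder-Mead followed by a BFGS
  polish, best of all starts.
- Component labelling: the larger-mass component is principal; when the
  two masses are within 20% of each other the *broader* component is
  taken as principal. The tie-break matters for balanced networks, where
  amplitude ordering is a coin flip across seeds; published fits of this
  model consistently carry the larger SD on the principal component, and
  the broader band is the natural reading of a "principal" orientation
  family.
- "Not detected" (ND): the secondary is reported absent when its
  amplitude is below 5% of the principal's, when the two means are closer
  than 2·max(σ₁, bin width), when it is baseline-classified, or when the
  fit failed to converge.

Tb.OrP is (μ₁, σ₁). Tb.OrS is reported both as the raw μ₂ and as
|μ₂| − μ₁ — the source table and the source text disagree on which is
printed, and the package takes no side. Tb.Int is computed from bin-level
densities (not from the fit): `sqrt(Σ density(θ)·Δ(θ, μ₁)²)`, Δ wrapped
and capped at 90°, so Tb.Int ∈ [0°, 90°] and equals 0 exactly when all
mass sits at μ₁. The histogram is density-scaled by default; whether the
original analysis fitted counts or densities is unstated, and both are
supported.

# Resolution degradation

`degrade()` merges factor×factor pixel blocks by arithmetic mean — the
2D section of merging voxels in blocks of 8 (factor 2) or 27 (factor 3) —
and multiplies the spacing accordingly (0.051 → 0.102 → 0.153 mm). The
mean is chosen because partial-volume averaging is precisely the
phenomenon under study. Global mean intensity and physical field of view
are preserved up to the cropped remainder rows/columns.

# Registration

`register_slice()` matches a moving slice against each slice of a
candidate stack: affine transform (translation, rotation, isotropic
scale, shear) about the image centre, optimized by maximizing mutual
information (32-bin joint histogram) with an integer-grid translation
warm start, a translation-only polish, then the full 5-parameter
Nelder-Mead search with parameter scaling; the affine stage is discarded
if it fails to improve on the warm start. Mutual information makes the
similarity modality-agnostic (a contrast-inverted copy still matches);
the reported score is the Pearson correlation of the registered pair
after z-normalization, so scores are comparable across modalities. The
transform is returned as a 2×3 matrix mapping moving to fixed pixel
coordinates.

# Agreement statistics

`kruskal_wallis()` computes the tie-corrected rank statistic with a
chi-square p-value (validated against the base-R implementation as an
independent oracle). `linear_r2()` is ordinary least squares with R² as
the squared Pearson correlation. `bland_altman()` reports the mean
(relative) difference with 1.96·SD limits. `icc()` defaults to the
two-way mixed-effects, absolute-agreement, single-measurement form —
the standard choice for method-agreement studies; the source cites its
ICC reference without naming the form — with bands low (< 0.5),
good (0.5–0.75), excellent (> 0.75). `max_percent_diff()` uses the CT
measurement as the denominator, and ND values are excluded pairwise with
a logged count.

# The phantom: what it emulates and what it does not

`generate_phantom()` builds bone as a union of straight struts: a
principal family whose per-strut orientation is drawn from
Normal(θ_P, σ_P²), plus an optional secondary family at a fixed offset
(default 90°) whose strut spacing is set so it holds the requested
fraction of bone mass. Struts are rasterized with anti-aliased coverage
and thresholded at 0.5, anchored so axis-aligned bars of integer width
rasterize to exactly their nominal width. Intensities follow the
modality (CT-like: bone 200 / marrow 50 / air 10; MR-like: bone 30 /
marrow 200 / air 20), then a Gaussian point-spread blur (default
0.03 mm ≈ 0.6 px) and additive Gaussian noise (default SD 8 ≈ 5% of the
bone-marrow contrast — high-SNR micro-CT-like; a Rician option is
deliberately absent since the emulated analyses never model noise).
Defaults mirror the published acquisition: 0.051 mm pixels, 0.26 mm
struts every 1.12 mm (BVF ≈ 0.23, Tb.Sp ≈ 0.86 mm), θ_P = 67°,
σ_P = 12°. A fixed seed yields a bit-identical phantom; the global RNG
state is restored.

Ground truth is mask-derived: BVF is exactly the bone-pixel share of the
emitted mask; Tb.Th/Tb.Sp run the package's exact aperture map on the
truth mask (the aperture implementation is itself proven equal to a
brute-force oracle, keeping truth decoupled from the gray-level
estimation path); the per-pixel strut angles are recorded so orientation
truth is available as the realized angle distribution, not just the
nominal parameters. Air bubbles are stamped as disks into marrow; for
MR-like images the signal void is enlarged by a blooming factor while
the truth mask keeps the nominal extent, emulating susceptibility
artifacts.

The phantom does **not** emulate: plate-like structures or 3D topology,
curved or terminating struts, marrow heterogeneity, MRI bias fields
beyond smooth shading, or Rician noise floors. A green phantom test
therefore establishes correctness of the measurement machinery on
strut-network geometry, not fidelity to any particular anatomy.

# Known limitations

- **Orientation recovery at high angular disorder.** The acceptance
  property "principal orientation within 2°, interconnectivity within 10%
  of the truth-mask value over phantoms with σ_P ∈ {5°, 15°, 25°}" is
  asserted unweakened and fails partially at σ_P 15–25° (and
  occasionally for Tb.Int at σ_P = 5°). The causes are structural, not
  implementation defects: a field holds ~15 struts, so the realized
  angle sample is ragged, and the fitted principal-Gaussian mean (a
  mode-seeking functional) legitimately differs from the axial circular
  mean of that sample by more than 2°; and per-pixel Hessian
  measurement noise (~2° at strut edges and crossings) adds in
  quadrature, which alone exceeds 10% relative when the true spread is
  ~4°. Zero-jitter recovery is within 2° across the angle range.
- **Tb.OrS ambiguity** (raw μ₂ vs difference) is inherited from the
  source material; both are reported.
- The aperture boundary convention makes edge-touching phase bands read
  thicker; supply an ROI that excludes them when exact geometry matters.
- Registration assumes the stack slices share one pixel grid; the moving
  image is upscaled bilinearly when coarser. Slice selection by anatomy
  is out of scope — the caller supplies the candidate stack.

# A complete run

```{r example, eval = FALSE}
spec <- phantom_spec(theta_p = 67, sigma_p = 12,
                     secondary_fraction = 0.25, seed = 7)
ph   <- generate_phantom(spec)
mask <- binarize_local(ph$image)
dist <- orientation_distribution(hessian_orientation(ph$image), mask)
fit  <- fit_dual_gaussian(dist)
met  <- compute_orientation_metrics(dist, fit)
morphometry_report(
  bvf  = compute_bvf(mask),
  tbth = summarize_thickness(compute_aperture_map(mask, "BONE")),
  tbsp = summarize_thickness(compute_aperture_map(mask, "MARROW")),
  tborp_mean = met$tborp["mean"], tborp_sd = met$tborp["sd"],
  tbors = met$tbors, tbint = met$tbint)
```

The README shows this run's printed output next to the generator ground
truth.
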