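---
title: "Quantifying amyloid, vascular and astroglial pathology in fluorescence sections"
author: "histoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid, vascular and astroglial pathology in fluorescence sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoquant)
```

## The measurement model

Everything this package quantifies reduces to boolean algebra on aligned
binary rasters. Each stained channel of a section — X-34 (fibrillar
amyloid), CD31 (endothelium), GFAP (astrocytes), ICAM-1 (vascular
inflammation) — is segmented into a mask, a region of interest (ROI)
polygon is rasterized into a mask, and every reported quantity is a ratio
of pixel counts:

* **Total area fraction** of marker $M$ in ROI $\Omega$:
  $100\,|M \cap \Omega| / |\Omega|$.
* **Associated (vascular / plaque-associated) fraction** of target $T$
  against reference $R$: $100\,|T \cap R \cap \Omega| / |R \cap \Omega|$.
  Vascular GFAP is GFAP against the CD31 mask; plaque-associated GFAP is
  GFAP against the X-34 mask; vascular ICAM-1 is ICAM-1 against CD31.
* **Parenchymal fraction**: total minus reference-associated positive
  pixels, normalized to the ROI (parenchymal ICAM-1 is total minus
  vascular ICAM-1). The pixel identity
  $|M \cap \Omega| = |M \cap R \cap \Omega| + |M \cap \lnot R \cap \Omega|$
  holds exactly, and is asserted in the test suite.
* **CAA metrics**: cerebral amyloid angiopathy (CAA) area over the
  cortical ROI, vascular-GFAP area inside the CAA mask over CAA area, and
  the reverse normalization over vascular-GFAP area.

Fractions with empty denominators are recorded as `NA`, never as zero: a
section with no CAA has an undefined CAA-associated GFAP fraction, and
coercing it to zero would bias group means downward.

Masks carry their provenance (`threshold_global`, `threshold_bernsen`,
`roi`, `manual`, `derived`, `ground_truth`), so every number in the output
is traceable to how its masks were made.

## Segmentation

Two thresholding schemes mirror how such sections are segmented in
practice:

* **Global threshold** (X-34, GFAP, ICAM-1): one intensity cutoff per
  channel, applied to every image of that channel. Positivity is inclusive
  (`>= T`): the chosen cutoff is the lowest positive grey value.
  `suggest_global_threshold()` supplies a reproducible default from the
  pooled histogram of all images of a channel (Otsu's between-class
  variance scan, or the triangle method, which suits sparse-foreground
  fluorescence where Otsu tends to split the dominant background mode).
* **Bernsen auto-local threshold** (CD31): for each pixel, the local
  contrast is `hi - lo` over a circular window (pixel-center Euclidean
  distance ≤ r, clipped at image borders). High-contrast pixels compare
  against the local midgrey `(lo + hi) / 2`; low-contrast pixels take a
  configured assignment (background by default, so empty parenchyma does
  not flood the vessel mask). This accommodates the regional variation in
  endothelial staining intensity that defeats a single global cutoff.

The window radius and contrast floor are not standardized anywhere, so the
package exposes both. `threshold_config()` defaults to r = 15 px and
c = 15 grey levels, the defaults of the common auto-local-threshold
implementation. The *pipeline* default for the contrast floor is 100 grey
levels instead: the floor must sit above the within-window background
noise range — approximately eight noise standard deviations, ~80 grey
levels for 8-bit data with read noise near 10 — and below the stain
contrast (~160). A floor of 15 classifies pure noise as structure on such
data. Both values are logged in the run manifest.

The min/max filters are evaluated as grayscale erosion/dilation with a
disc structuring element (EBImage), which uses border-clipped
neighbourhoods; the test suite proves exact equality with a per-pixel
brute-force scan over the same window.

## ROIs and rasterization

ROIs are simple closed polygons in 0-based pixel coordinates (x right, y
down), with vertices at pixel centers. A pixel belongs to the ROI iff its
center is inside the polygon under the even-odd rule; centers exactly on
the boundary count as inside. The canonical file dialect is a small JSON
format; ImageJ `.roi` polygon files are read for interoperability.

## CAA: separating vascular from parenchymal amyloid

The faithful reproduction path ingests manually drawn vascular-amyloid
masks and intersects them with the segmented X-34 mask (so CAA is always a
subset of segmented amyloid). Because manual discrimination is not an
algorithm, the package also provides an automated morphological surrogate:
8-connected amyloid components of at least 20 px are classified as
vascular iff either

* at least half the component lies inside the CD31 mask dilated by 2 px
  (vessel apposition), or
* the component's best-fit-ellipse axis ratio is at least 3 (vessel-wall
  amyloid tracks the vessel and is elongated; compact plaques have ratios
  near 1).

Axis ratios come from the second central moments of the component's pixel
coordinates with the single-pixel variance (1/12 px²) added, so
one-pixel-wide lines get a finite, large ratio. The two output masks
partition the retained amyloid pixels. All thresholds are config-exposed;
outputs flag the classification as automated. On the synthetic benchmark
(below) the surrogate labels components with ~100% accuracy, but it is a
stand-in for judgment, not a reproduction of it: on real tissue the manual
path remains the reference.

CAA metrics are computed in the cortical ROI by default, reflecting that
vascular amyloid in this model occurs in cortical but not hippocampal
vessels; other ROIs can be enabled.

## Vessel morphometry

Vessel geometry is measured on the CD31 mask: Zhang–Suen thinning to a
medial-axis skeleton, conversion to a junction/endpoint graph (pixels
classified by Yokoi crossing number, which correctly treats the staircase
corners thinning leaves on oblique vessels as chain pixels), and iterative
pruning of terminal branches shorter than 10 px, which also removes
compact non-vessel artifacts.

Numerical conventions, chosen once and validated on phantoms:

* **Local radius** at a skeleton pixel is its Euclidean distance-transform
  value minus half a pixel — the mask boundary is taken to lie halfway
  between the last foreground and first background pixel centers. On
  axis-aligned bars of odd width this is exact; the raw distance-transform
  value would carry a constant +1 px diameter bias. Edge diameter is twice
  the path-length-weighted mean radius.
* **Path length** is measured on the chain resampled as a polyline with a
  vertex every 4 px (plus endpoints). The naive chain code (1 per
   4-step, √2 per diagonal) overestimates digitized curves by 12–20%
  through staircase jitter; resampling is exact on straight chains and
  within ~2% on semicircular and sinusoidal phantoms.
* **Tortuosity** is path length over chord length, ≥ 1, exactly 1 for
  collinear chains. Closed loops (which would have zero chord) are split
  at their farthest-point pair during graph construction.
* Per-animal summaries weight edges by path length, because long segments
  dominate the vasculature; an unweighted option exists.

Phantom recovery, re-run in the test suite: width error ≤ 1 px for widths
3–11 px at 0°/30°/45°/90°; straight-tube tortuosity exactly 1; semicircle
within 5% of π/2; sine tube within 5% of its quadrature arc length.

## The synthetic histology generator

No imaging data accompanies the measurement procedure this package
re-implements, so validation uses a generator with exported ground truth.
A section (default 256×256 px at 1 µm/px) contains:

* **Vessels**: biased random-walk centrelines entering from the borders,
  Gaussian cross-sections, occasional branches; widths 4–8 px; walks are
  added, with lengths adapted to the remaining deficit, until the target
  CD31 area fraction (default 0.08) is realized.
* **Plaques**: radially decaying blobs (radius 4–10 px) placed clear of
  vessels, as parenchymal plaques are.
* **CAA**: amyloid rings (±1 px band around the vessel wall radius) along
  randomly chosen vessel segments of 25–60 px.
* **Astrocytes**: soma plus radial processes; placed within a few pixels
  of a vessel with probability 0.45, at a plaque rim with probability
  0.25, else uniformly. Associated astrocytes scale process length and
  count with a reactivity multiplier — this is what gives vascular and
  plaque-associated GFAP their tunable true effect sizes.
* **ICAM-1**: endothelial signal on a subset of vessels, rendered at 80%
  of the CD31 tube radius (adhesion molecules line the endothelium inside
  the CD31-positive wall), plus parenchymal blobs.

Every structure field is blurred with a Gaussian point spread (σ = 0.6 px)
and rendered as `bias × (background + amplitude × field) + noise`, with a
unit-mean quadratic-polynomial illumination bias (±8%) and Gaussian read
noise (default amplitude 160, background 40, noise SD 10 — SNR 16 on the
8-bit scale). The multiplicative bias is what makes the global-vs-local
thresholding distinction matter, exactly as regional staining variation
does in real sections.

**Ground truth is the half-maximum level set of the blurred structure
field.** This makes truth and segmentation consistent by construction: a
global threshold at `background + amplitude/2` recovers the true mask up
to symmetric noise flips at boundaries, and the stored true metric values
are, verbatim, the package's own mask algebra evaluated on the true masks
(asserted exactly in the tests). Determinism is total: a spec and seed
reproduce every pixel.

Cohorts impose a 2×2 design (amyloid transgene × apoA-I genotype) through
group-level multipliers on the spec: by default wild-type groups carry no
amyloid and quiescent astrocytes, and the transgenic apoA-I-knockout group
carries 3.25× parenchymal amyloid, 5× vascular amyloid and 1.4× astrocyte
reactivity relative to the transgenic hemizygous group — the direction and
rough magnitude of the group differences reported for this mouse model
(cortical amyloid 0.28→0.91% area, CAA 0.01→0.05%, cortical vascular GFAP
1.80→3.86%). Between-animal variability is lognormal (CV 0.25 on burden
and reactivity). For statistical calibration studies that need hundreds of
cohorts, `simulate_metric_table()` draws per-animal metric values directly
from the same lognormal between-animal model (CV 0.35, typical of
histological area fractions) without rendering images.

### What the generator does and does not emulate

It reproduces the *statistical structure the analysis assumes*: tubular
vessel networks, compact vs vessel-apposed amyloid, astrocyte placement
biased toward vessels and plaques, illumination bias, read noise, and
known overlap fractions. It does not emulate staining chemistry,
section-to-section registration, z-plane overlap (markers stacked in
different depths of a 40 µm section can overlap in 2D projection and
inflate association metrics — uncorrectable in 2D and out of scope),
point-spread anisotropy, or tissue autofluorescence. Passing the recovery
benchmark therefore shows the *pipeline arithmetic* is faithful at
realistic SNR, not that segmentation of real tissue is unbiased.

## The statistics stage

Per-animal values (the unweighted mean of the three sections, NA sections
dropped, matching one plotted point per mouse; pooled pixel counts are a
config alternative) enter:

* **Two-way omnibus ANOVA** with interaction, Type III sums of squares
  under sum-to-zero coding — computed directly as full-vs-reduced
  least-squares model comparisons, the definition itself, so the test
  oracle agrees to 1e-10. Type III is the stated assumption for the
  unbalanced group sizes (N = 5–19 in the motivating study); in balanced
  designs it coincides with the sequential decomposition (asserted in
  tests). Zero residual variance is flagged, with p undefined.
* **Sidak pairwise comparisons** on the pooled residual mean square,
  `p_adj = 1 − (1 − p_raw)^m`, with the family defaulting to the four
  simple-effect comparisons of the 2×2 layout (m = 4, always reported).
  They are computed only when an omnibus effect is significant at α = 0.05
  (the gate can be disabled).
* **Unpaired t** (pooled variance; Welch optional) and **Mann-Whitney**
  for the amyloid/CAA outcomes, which exist only in transgenic animals and
  are compared between the two transgenic groups. Test choice per metric
  is declared in the plan, as it was by the original analysts — the
  package does not auto-select by normality testing.

Mann-Whitney uses `U = Σ[x_i > y_j] + ½[x_i = y_j]`. For combined samples
up to 16 the two-sided p is exact by complete enumeration of all
`C(n_x + n_y, n_x)` labelings of the observed values — valid under ties,
since the distribution is conditioned on the observed pool. Larger samples
use the normal approximation with tie and continuity corrections.

Calibration, re-run in the test suite on 500 simulated null cohorts at
n = 7 per group: empirical omnibus type-I error at α = 0.05 within
[0.03, 0.07]; with the reported vascular-GFAP group means as the
alternative, the Sidak comparison of the two transgenic groups is
significant in ≫ 50% of replicates.

## Validation study sizes

The bundled validation uses problem sizes chosen to exercise every code
path while keeping the whole suite fast on one CPU: 50 random 64×64
images for the Bernsen oracle; ≥ 1000 random mask triples for the algebra
identities; 20 full-default sections (~0.9 Mpx total) for ground-truth
recovery — every listed area-fraction metric is recovered within ±10%
relative error on average, most within 3% — and ~200 amyloid components
for classifier accuracy; 500 null cohorts for calibration. The analysis
scripts under `analysis/` run a 20-animal, 60-section cohort end to end.

## Known limitations

* Difference-based metrics (parenchymal ICAM-1) inherit the absolute
  errors of both masks; when the true parenchymal signal is sparse, their
  relative error is the least stable of the panel.
* CAA-associated GFAP has a small numerator confined to the vessel-wall
  boundary — exactly where the globally thresholded GFAP mask and the
  locally thresholded CD31 mask disagree most — and shows the largest
  seed-to-seed recovery spread (occasionally just over 10% relative at the
  default conditions).
* The automated CAA classifier is a surrogate for manual morphological
  discrimination and is validated only against the generator's notion of
  vascular amyloid.
* Otsu's method on sparse-foreground channels can split the background
  mode; the triangle method or an explicit cutoff is preferred there, and
  the pipeline logs whichever was used.
* All analysis is 2D per section; no correction for plane overlap or
  section-to-section correlation beyond per-animal averaging.
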