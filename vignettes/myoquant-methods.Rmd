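---
title: "Methods: models, parameters and design choices in myoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in myoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoquant)
```

# Scope

myoquant quantifies cultured myoblasts from multi-channel 8-bit
fluorescence micrographs: nucleus counting on the DAPI channel, per-nucleus
marker calling on the green/red channels, myotube recognition on the MyHC
channel, the proliferation / differentiation / fusion indices, and a
regression layer comparing coatings over culture days. A synthetic-image
generator with full ground truth stands in for microscope data, so every
claim a test makes is checked against a known truth.

# The segmentation model

## IsoData thresholding

Each channel is binarized with the iterative-intermeans rule on the 256-bin
histogram: starting from the global mean, iterate
$t \leftarrow \big(\mathrm{mean}(x \le t) + \mathrm{mean}(x > t)\big)/2$
(rounded to the nearest bin) to a fixed point; foreground is the bright
class, `image > t`. We deliberately implement the *classic* intermeans rule
on the full histogram rather than any particular tool's variant (some
popular implementations quietly ignore the extreme bins), because the
classic rule is exactly reproducible from its definition. A guard breaks
the rare round-off 2-cycle. A constant image is reported as "no
foreground" (empty mask, threshold = the constant) instead of erroring,
since blank control fields are a legitimate input.

## Watershed on the distance transform

Touching nuclei are split by seeded watershed: the exact Euclidean distance
transform of the nuclear mask is smoothed (Gaussian, sigma 1 px) and its
regional maxima become seeds, subject to a minimum peak separation of 5 px
(Chebyshev window). Plateau maxima — common on symmetric disks, where the
distance map is locally flat — are merged into one seed at the plateau's
central pixel, so a clean disk yields exactly one label. Flooding runs on
the *unsmoothed* negated distance map restricted to the foreground, with a
FIFO tie-break so label assignment is deterministic. Every foreground pixel
receives a label (no watershed-line pixels), which keeps segment areas
faithful to the threshold mask.

Two overlapping disks whose centres are 8 px apart produce two distance
peaks beyond the separation limit and are split into two labels; pairs much
closer than ~6 px merge into one object, which is the expected behaviour of
this family of algorithms and one of the failure modes the synthetic
overlap fraction (below) is designed to exercise.

## Size and border filtering

Nucleus segments are kept when their area lies in the **inclusive** window
[15, 230] px — the phrase "range of 15–230" is read as inclusive at both
ends, and the unit tests pin areas 15 and 230 as retained, 14 and 231 as
rejected. Segments touching the first or last row/column are partial nuclei
and are dropped. Marker segments get the same size window but are *not*
border-filtered: only partial nuclei bias counting, whereas marker signal
clipped at the edge still indicates staining of a retained interior
nucleus. Watershed runs before the size filter, so the fragments of a split
clump are size-checked individually.

Connectivity is 8-connected everywhere, matching the default of the common
desktop image-analysis tools this pipeline emulates.

# Marker calling and myotubes

A nucleus is positive for a channel when at least one size-filtered marker
segment intersects its region in ≥ 1 pixel (default `"intersection"`
rule). The stricter reading — the marker segment lies entirely within one
nucleus — is available as `rule = "containment"`; intersection is the
default because nuclear marker blobs are routinely clipped by the nucleus
boundary after thresholding, and full containment then undercounts.
`double_positive` is defined as `green_positive & red_positive`, never
computed independently.

Myotube recognition thresholds the MyHC channel, discards components below
`min_myotube_area` (default 300 px, roughly four nucleus areas — MyHC
speckle is much smaller, true myotubes are much larger), assigns each retained
nucleus whose centroid lies inside a component to that component, and keeps
components with ≥ 2 assigned nuclei. Centroid assignment gives each nucleus
at most one myotube, which keeps the fusion-index numerator well defined.

# Indices and pooling

The three indices are plain percentage ratios of counts. An index with a
zero denominator is **undefined** and propagates as `NA` into the analysis
table — not as 0, which would fabricate a measurement from an empty field.
Wells pool their five fields by **summing counts first** and applying the
formula once; the mean-of-ratios alternative is unstable when single fields
are sparse (a field with 2 Pax7⁺ nuclei would contribute a ratio quantized
to {0, 50, 100}%). For fields with identical composition the two rules
agree, which the tests verify.

# The regression layer

Each outcome is modeled per well (the well, not the field, is the unit of
analysis; with triplicate wells this matches how such experiments are
reported) by least squares with categorical coating and categorical day —
day is categorical because the outcomes are estimated *at* days 1/5/7/9,
not assumed linear in time. The reference level is matrigel. The
coating × day interaction enters only when the partial F-test comparing
additive and interaction models is significant at α = 0.05; the simulated
type-I error of this selection under an additive null is checked to sit in
the 99% binomial band around 0.05 (1000 replicates). For myotube number and
the differentiation index the day-1 rows can be excluded before fitting,
since both are essentially zero then and day 1 only wastes degrees of
freedom.

Contrasts (coating − matrigel at each day) are computed as linear
combinations of coefficients with t-based p-values on the residual degrees
of freedom. No multiple-testing correction is applied, mirroring standard
practice for this design; readers should treat borderline p-values
accordingly. Two numerical edge cases are handled explicitly: on a
noiseless saturated fit the partial F is indeterminate, so the interaction
counts as an improvement iff it reduces the residual sum of squares beyond
a relative tolerance of 1e-10; and on a zero-residual fit contrasts are
exact, so their p-values are reported as 0/1 by whether the estimate is
nonzero rather than from a degenerate t distribution. Similarly,
`validate_counts()` reports the paired-t p-value of a constant nonzero
difference (zero variance) as 0 — the exact-difference case — and of
identical vectors as 1.

# The synthetic world

The generator renders what a 10×, 8-bit, three/four-channel field of a
myoblast culture looks like to this pipeline:

* **Pixel scale**: 1 µm/px. At this scale a nucleus of diameter 10 µm
  (the typical muscle-cell nucleus) covers ≈ 78 px, comfortably inside the
  [15, 230] px window — this choice is what makes the printed size window
  meaningful. Diameters are drawn N(10, 1.2) µm and clamped to [6, 16] µm
  so rendered areas stay inside the window by construction.
* **Field size**: 512 × 512 px; densities of 50–400 nuclei per field span
  sparse day-1 cultures to near-confluent day-9 ones. (Cell densities per
  field are not published for this kind of experiment; this range is a
  plausibility choice, fixed once.)
* **Placement**: rejection sampling with a minimum centroid separation of
  `max(12, r_i + r_j + 3)` px; a deliberate `overlap_fraction` (default
  8%) of nuclei is placed at 0.8 × (rᵢ+rⱼ) — touching, but with distinct
  distance-transform peaks — to exercise the watershed split. Unfused
  nuclei are kept out of myotube capsules (with a 3 px buffer) so that
  generated membership and centroid-in-component assignment agree.
* **Markers**: one uniform draw per nucleus partitions
  {double, green-only, red-only, negative} with
  P(double) = `p_double` ≤ min(`p_green`, `p_red`). Specifying the joint
  directly lets a target index `100·p_double/p_green` be dialed in
  exactly. Marker disks are nuclear-localized (radius r−1, floored at
  2.5 px so the rendered blob never falls below the 15 px marker size
  filter); MyHC is cytoplasmic.
* **Myotubes**: rotated capsules, length 60–200 px, width 10–20 px, placed
  with capsule-to-capsule clearance > 2 px (rejection sampling, 400
  attempts). Member nuclei are spread along the axis; member counts are
  drawn 2 + Poisson(mean − 2) per tube and then rebalanced toward longer
  tubes (capacity ≈ length/12 nuclei), because nuclei cannot physically
  overlap inside a short tube — without this, short crowded tubes produce
  watershed merges that bias the fusion index downward in the high-fusion
  regime.
* **Imaging**: per-object intensity jitter, Gaussian PSF blur
  (σ = 0.8 px), additive Gaussian read noise (σ = 5 grey levels), clip to
  [0, 255], quantize. "8-bit with moderate noise" is all the imaging
  physics the pipeline's behaviour depends on.
* **Determinism**: one seed per field; study generation derives per-field
  seeds from the master seed with a fixed integer recurrence, so a study
  regenerates bit-identically.

What the generator does **not** emulate: uneven illumination, vignetting,
photobleaching, chromatic misregistration, out-of-focus planes,
non-elliptical nuclei, cytoplasmic marker background, fibroblast
contamination. A green test on synthetic data therefore establishes that
the *algorithmic* pipeline is correct and unbiased under the stated imaging
model — not that it is robust to every artifact of a real microscope.

# Numerical and interface choices

* Coordinates are row-major with origin at the top-left; bounding boxes are
  half-open; image matrices are `[row, col]` integer matrices in 0–255.
* The five-spot well sampler places the four satellite fields exactly one
  field-size from the centre crop (centres at centre ± field px), which
  makes the five crops pairwise disjoint and deterministic; the true
  microscope stage offsets are unpublished, and any deterministic
  convention serves the analysis equally.
* TIFF I/O is a minimal self-contained baseline codec (uncompressed
  grayscale, 8-bit write, 8/16-bit read, both byte orders) because the
  supported R stack offers no TIFF reader; a round-trip test validates it
  against an independent Python reader available in the same environment.
* Config files are YAML; channel semantics (e.g. green = Pax7 vs
  green = MyoG) are a config-level `channel_map`, since the same channel
  colour carries different antibodies in different staining combinations.

# Known limitations

* Heavily overlapping nuclei (< ~6 px centre distance) merge; at very high
  densities automated counts drop a few percent below truth. The
  counting-fidelity check asserts correlation with truth across a 16-field
  density sweep, not exactness.
* The intensity model is binary-ish (bright objects on dark background);
  IsoData behaves differently on low-contrast real images than on these
  renders.
* The statistics layer fits plain linear models; field-within-well nesting
  is resolved by pooling to wells rather than by mixed-effects modeling.
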