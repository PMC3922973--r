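---
title: "Methods: detecting whales in VHR satellite imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting whales in VHR satellite imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalesat)
```

This vignette is the package's own account of its models and the design
choices behind them: the scene model, the simulator's attenuation
phenomenology, the threshold-optimization statistic, the classifier
baselines, the evaluation arithmetic, and the numerical decisions that a
maintainer would otherwise have to reverse-engineer from the code.

## 1. Scene model

A scene is a dual-resolution stack: eight multispectral (MS) bands at 2 m
ground sample distance and one panchromatic band at 0.5 m, both recording
dimensionless 11-bit digital numbers (DN, ceiling 2047). Working in raw DN
is deliberate: over open water the dominant unknowns (surface roughness,
water-column turbidity) cannot be inverted to absolute reflectance from a
single image, so only *relative* illumination is meaningful.

Raster conventions, stated once and used everywhere: 0-based (row, col),
origin at the upper-left corner, pixel-centre registration, row increases
southward. Annotations are stored in world metres so one annotation set
serves both grids. MS and pan are kept as separate grids — nothing in the
detection path pansharpens, because fusing pan detail into a colour band
would manufacture spatial information the colour band never measured.

The band table fixes three roles that the analysis depends on: band 5 is
the coastal band (400–450 nm, the far-blue light that penetrates deepest
into the water column), band 1 is red and band 8 is NIR2 (the 1-8-5
false-colour display convention). The remaining wavelength ranges follow
the standard WorldView2 band set; they only matter through their
attenuation ordering (section 2). The 11-bit DN ceiling is the sensor's
radiometry; the delivered product's bit depth is not independently
documented, so `dn_max` is a config default rather than a hard-coded
constant.

## 2. The simulator and its attenuation model

Real VHR scenes of whales are proprietary, so every downstream stage is
exercised on synthetic scenes with known truth. The generator emulates:

* a flat water background (default mean 180 DN) with iid Gaussian sensor
  noise — sd 8 DN in the MS bands and 20 DN in pan, because the fine pan
  grid resolves wavelets and ripples the 2 m bands average away;
* a shared low-frequency surface-texture field (amplitude 4 DN,
  correlation length 60 m), bilinearly interpolated at pan resolution and
  block-averaged into MS;
* ellipsoidal whales, 5–15 m long with minor/major ratio 0.25–0.45 and a
  bright callus spot at one end of the head (+150 DN over a 15 % span of
  the semi-major axis) — the values a field guide would give for southern
  right whales seen from above;
* the confounder taxonomy seen in real imagery: seabird clusters
  (scattered 1–2-pan-pixel dots), bubble slicks (diffuse elongated
  patches at ~1.5 background sd), boats (uniform rectangles 20–30 m,
  strictly brighter than any whale pixel, with a linear wake) and shallow
  rocks (static patches, identical contrast in every band).

**Attenuation.** Submersion multiplies a whale's surface contrast `S` by
`exp(-K_d(band) * d)` at depth `d`, with a per-band two-way diffuse
attenuation coefficient `K_d`. No radiative-transfer model is claimed —
the empirical constraint is purely qualitative (all bands see surface
features; only the coastal band sees submerged ones), and the two-way
exponential is the simplest monotone model consistent with it. Defaults
(per metre)

| band | red | blue | green | yellow | coastal | red edge | NIR1 | NIR2 | pan |
|------|-----|------|-------|--------|---------|----------|------|------|-----|
| K_d  | 1.6 | 0.5  | 0.7   | 1.1    | **0.25**| 2.5      | 4.0  | 5.0  | 1.0 |

are ordered the way clear-water optics orders absorption, with the coastal
band strictly minimal (a validated invariant). They are chosen so that all
three visibility regimes are realisable: all-band (surface), weak-pan
(shallow), and coastal-only. The coastal-only window is computable in
closed form from the two inequalities `S·exp(-K5·d) ≥ 2σ_MS` and
`S·exp(-K_b·d) < σ_b` for every other band; with the defaults it is

```{r}
band5_only_depth_window(simulation_config())
```

i.e. roughly 7–11 m. These depths are *configuration, not claims*: how deep
a real sensor sees is an open calibration question that would need in-water
reference panels, which is why the window is exposed as a function of the
config rather than stated as a constant.

**Mixed pixels.** Objects are rasterized on the pan grid (membership of
pixel centres) and MS bands receive the 4×4 area-weighted aggregate. This
matters: a 5 m whale 1.3 m wide can contain *no* 2-m-pixel centre, and a
binary membership test would delete it from the MS bands entirely, while
physically it still contributes half a pixel's worth of radiance. With
area weighting, every whale visible in pan deposits proportional DN in MS,
and the zero-noise recall of coastal-band thresholding is exactly 100 %.

**Determinism.** One seeded generator per scene with a fixed draw order
(background, whales, confounders in taxonomy order), so `(config, seed)`
is bit-reproducible and partial configs stay reproducible. Placement is
rejection sampling with a 20 m minimum centroid separation, bounded at
1000 retries before a "placement failure" error. Whale truth classes
emulate the manual digitizer deterministically: pan contrast ≥ 2 pan-sd →
probable; inside the coastal-only window → band5_only; otherwise possible.
Boats and rocks get an `NA` class label — a manual digitizer recorded
whale-like features only — and are excluded from the evaluation reference
by `truth_reference()`.

**What the simulator does not model:** sun-glint BRDF, wave refraction,
turbidity gradients, whale behaviours that deform the ellipse (rolling,
tail slapping, blowing), and radiometric calibration. Tests passing on
synthetic scenes establish that the *algorithms* behave as specified under
the stated phenomenology — not that the defaults match any particular
ocean. An optional pan-speckle glint term exists for robustness
experiments only and is off by default, matching the calm-sea-state image
selection the method assumes.

## 3. Threshold optimization

The detection statistic exploits the one shape prior that survives 2 m
pixels: whales are multi-pixel clumps, noise is single pixels. For each
candidate threshold the band is binarized (strictly above), 8-connected
components are labelled, and

```
ratio(t) = n_multi(t) / max(n_single(t), 1)
```

is maximized. Decisions a reader should know about:

* *Connectivity* is 8 by default: a whale's body at coarse resolution
  produces diagonal pixel runs that 4-connectivity would fragment.
* *Candidates* default to every integer DN from the band median (open
  water dominates the histogram, so the median is background) to the band
  maximum — an exhaustive search that subsumes manual iteration.
* *Eligibility.* Thresholds inside the noise bulk keep a large fraction
  of the grid; near the site-percolation regime the background itself
  forms many multi-pixel clusters and the ratio becomes large and
  meaningless (on a pure-noise pan grid it peaks around 1.6 half a sd
  above the mean). The argmax is therefore restricted to candidates
  keeping ≤ 5 % of pixels — the upper-tail regime a histogram-guided
  analyst searches — while the full trace is still returned for plotting.
* *Tie-break* goes to the highest threshold: fewest residual noise pixels.
* The `max(·, 1)` guard defines the degenerate no-singles case; a scene
  with one clean blob and no noise then scores `ratio = n_multi`.
* The implementation is a single incremental union-find sweep over pixels
  sorted by DN (all thresholds in one pass); tests hold it equal to
  exhaustive per-threshold relabelling with an independent flood-fill /
  graph-components oracle.

Component shape comes from second-order moments: axis length = 4·sd of the
pixel coordinates (exact for a filled ellipse) plus a 1/12-pixel variance
term for pixel extent. The size filter keeps 5–16 m major axes with one
GSD of slack at each bound, because the moment estimator carries about half
a pixel of bias per end on a coarse grid — a 15 m whale measuring 16.2 m on
the 2 m grid must stay in, while 20 m+ boats remain out. Single-pixel
objects are never discarded (a deep whale can legitimately return one
bright pixel) but cannot pass the shape flag, so they land in "possible".

**Three-class labelling** formalizes the manual protocol: detections from
the coastal band are matched one-to-one (greedy nearest-first within 10 m)
against panchromatic detections; shape-passing, adequately contrasted
objects are *probable*; weak/small/misshapen ones *possible*; coastal
detections with no pan counterpart *band5_only*. The rules are explicit
arguments so a user can tighten them. For the MS-stack classifiers the
band5_only override is computed from the object's own per-band contrast
(coastal ≥ 2 sd, every other band < 1 sd).

## 4. Classifier baselines

*k-means* follows the classical description exactly: initial class means
evenly distributed in the data space (along the diagonal from the per-band
minimum to maximum), then Lloyd iterations to the nearest mean. The
deterministic initialization means classification needs no seed. Empty
clusters are dropped deterministically with a warning. The per-iteration
within-cluster sum of squares is recorded and is non-increasing (a
property test); agreement with the reference Lloyd implementation in
`stats::kmeans` under the same initialization is a cross-check in the
suite, not the implementation.

*ISODATA* wraps the same core with structural moves — discard clusters
below `min_cluster_size`, split clusters whose largest per-band sd exceeds
`split_sd` (means offset ±sd/2 along that band), merge pairs closer than
`merge_dist` (size-weighted, closest pair first). With splitting and
merging disabled it is pixel-identical to `kmeans_segment()` — that
degeneration is asserted in the tests, which pins the extra machinery as
inert when switched off.

*Maximum likelihood* assigns each pixel to the class with the highest
multivariate-normal log-likelihood given user-supplied (or
annotation-derived) signatures, via Cholesky factorization; singular
covariances are ridge-regularized with a warning. With realistic
overlapping signatures it commits more false positives than thresholding —
the qualitative failure mode that rules it out in practice, reproduced as
a test rather than a fixed number.

Cluster maps reduce to candidate masks by `cluster_to_candidates()`: the
modal cluster is water; clusters whose mean intensity exceeds the water
mean by 2 background sd (in the per-pixel band-mean image) are candidates,
intersected with pixels above the water mean.

## 5. Evaluation arithmetic

Matching is greedy nearest-first one-to-one within 10 m (about a whale
half-length plus an MS pixel of slack; the original assessment was visual,
so no spatial tolerance is documented anywhere). Greedy matching is
order-stable and, at realistic densities, within one pair of the optimal
assignment — bounded in the suite against an exact bipartite-matching
oracle. A matched detection is tallied under the *reference* object's
class: the comparison table counts "probable matches" by the manual class,
not the detector's own label.

The metric denominators are pinned by regenerating all twenty percentage
cells of the published four-method table from its count rows: percentages
of matches use the manual grand total (91 = 55 + 23 + 13), the probable
percentage uses the manual probable total (55), and the false-positive
percentage uses the method's own total signals, with `% good` its
complement. Rounding is half-up to one decimal — the printed table's
23.8 (= 100·24/101 = 23.762) against a truncated 23.7 in running text
resolves in favour of the table. These identities (e.g. 101 = 49+15+13+24,
77 found + 14 missed = 91) are asserted for every column.

## 6. Numerical and degenerate-input decisions

* DN grids are stored as doubles holding integers; scenes are quantized
  (round, clip to [0, 2047]) once at the end of simulation.
* 16-bit TIFF round-trips 11-bit DN exactly (value/65535 encoding).
* A band with nothing above its median ("no signal above threshold")
  yields an empty detection set in the pipeline rather than an error —
  a featureless calm-water tile is a valid input.
* `k` larger than the number of distinct pixel values degenerates to
  fewer clusters via the empty-cluster drop, with a warning.
* Cross-section profiles sample nearest-pixel on each band's own grid;
  `section_contrast()` can remove a linear background trend (the texture
  field masquerades as contrast over a 40 m transect otherwise) and
  accepts known per-band noise sds for its sigma units, since the sd of a
  line-averaged profile understates pixel noise.
* World↔pixel conversions compose to within half a GSD (property-tested);
  points on the shared lower/right edge belong to the last pixel.

## 7. Problem sizes in the shipped tests

The suite exercises scenes of 40×40 to 150×150 MS pixels (up to 600×600
pan, i.e. 300 m tiles), 20-seed recovery runs at 20 whales per scene, and
50-scene oracle sweeps — sizes chosen so the full suite demonstrates every
claim comfortably on a laptop-class single core. Nothing in the
implementation is tile-size-bound: the threshold sweep is O(N log N) in
pixels, and a full 113 km² WorldView2 scene would simply be processed as
windowed tiles by the same functions.

## 8. Known limitations

Global (not spatially adaptive) thresholds; no object-oriented or texture
features; no multi-image change detection for rock rejection (stereo pairs
would resolve rocks trivially); whale pairs rendered touching are one
truth annotation, mirroring the manual digitizer's inability to separate
mother and calf; and the simulator's realism caveats of section 2. The
"possible" class rule is a formal approximation of a manual judgement that
mixed contrast, shape and context; its parameters are exposed rather than
hidden.
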