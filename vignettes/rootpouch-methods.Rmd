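---
title: "Methods: pouch-image root phenotyping, from pixels to heritability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pouch-image root phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootpouch)
```

## The measurement problem

Two-dimensional growth pouches image a seedling's root system as bright
strands on a dark filter-paper background. Converting such an image into
quantitative root traits faces two systematic artifacts. First, small
bright particles — root debris, dust, paper fibres — pass a global
brightness threshold and are counted as extra root *tips*, inflating
tip-dependent traits. Second, when pouches are photographed in air, a
water meniscus forms along each root/paper edge and reflects light, so
roots appear wider and sprout spurious bright protrusions; imaging the
pouch submerged in water removes this, and the package's synthetic
generator can emulate both conditions. `rootpouch` implements the
cleaning pipeline that addresses the first artifact, the trait
extraction that turns a cleaned mask into twelve standard root traits,
a synthetic-image generator with analytic ground truth to validate both,
and the supporting statistics (tip-count validation R², broad-sense
heritability, linkage-block Bonferroni thresholds) used to qualify such
a phenotyping platform for genetic mapping.

## Cleaning pipeline

`clean_image()` composes three stages:

1. **Lightness thresholding** (`segment_foreground`). RGB is converted
   to CIELAB and only the lightness channel L is kept; L is linearly
   stretched between two percentiles to the full 0–255 range and
   binarized at a global threshold (Otsu's method by default, a fixed
   level optionally). The stretch anchors matter: roots typically
   occupy ~1–3% of the frame, so the upper anchor defaults to the
   99.9th percentile — a 99th-percentile anchor would stretch
   background noise instead of the background-to-root range.
2. **Connected-component labelling** (`label_components`), 8-connected
   by default so thin diagonal strands remain one object.
3. **Filtering** (`filter_components`). A component survives iff its
   pixel area reaches `min_area_px` *and* its centroid lies within
   `max_center_dist_frac` of the half-diagonal from the image centre
   (rejecting staged off-centre objects such as rulers). The largest
   component is kept unconditionally by default, so the root system can
   never reject itself. The surviving mask multiplies the original
   image to give the "cleaned" image.

`min_area_px` defaults to 200 px at 100 px/cm — a physical cut-off of
2 mm² — and `default_cleaning_config(pixels_per_cm)` rescales it as
the square of resolution. The area-only filter follows the original
design intent; a shape-descriptor hook would slot into
`filter_components` if eccentricity filtering were ever needed.

**A numerical caveat we chose to document rather than hide:** L* is
nonlinear in encoded grey level, so any histogram split computed in L
(Otsu or intermeans — both land within one grey level here) cuts the
anti-aliased stroke edge at ~0.38 coverage rather than 0.5, widening
every stroke by ~0.24 px. This is invisible at DSLR resolutions
(~150 px/cm) but measurable on 3-px-wide laterals at 50 px/cm, where it
inflates area-derived traits (SOL) by up to ~10% of their value. The
validation suite therefore exercises trait *recovery* at 100 px/cm and
tip counting (insensitive to edge width) at 50 px/cm.

## Trait extraction

`measure_all()` computes the seven morphological and five architectural
traits from a cleaned mask and the pixel scale:

- The mask is thinned to a one-pixel skeleton (Zhang–Suen), and spurs —
  endpoint-to-branch side paths shorter than `min_spur_px` (default
  5 px) — are pruned as thinning artifacts. Branch and end points are
  classified by *crossing number* (connected neighbour runs), not raw
  neighbour counts, which misread staircase corners as branches.
- **Tips (TRT)**: skeleton endpoints, minus one for the collar (the
  endpoint at the root/shoot junction, which is not a root tip).
  Every connected component is counted; removing non-root components is
  deliberately the cleaning stage's job, so the uncleaned-vs-cleaned
  comparison is meaningful.
- **Length (TRL)**: skeletons are decomposed into ordered paths;
  each path's coordinates are smoothed with a short running mean
  (window ±3 px, endpoints pinned) before summing Euclidean segments,
  and each free endpoint receives a round-cap allowance of
  (radius − 0.5) px. Raw 8-connected chain sums with 1/√2 weights
  overestimate curved-root length by up to ~8–10% (staircase effect);
  smoothing removes that bias while leaving straight axis-aligned bars
  exact (a 101-pixel axial skeleton at 100 px/cm measures 1.00 cm).
- **Diameter field**: at each skeleton pixel the local diameter is
  `2 * (EDT − 0.25) px`, where EDT is the Euclidean distance-transform
  value of the mask. The −0.25 centres a parity artifact: the raw EDT
  half-width overshoots by 0.5 px for odd stroke widths and matches for
  even ones. From the per-pixel diameter d and step length l:
  TSA = π Σ d·l, TRV = π/4 Σ d²·l, DIM = Σ d·l / Σ l, and TSA1/TSA3
  restrict TSA to the [0, 0.5) and [1.0, 1.5) mm diameter classes
  (contiguous half-open 0.5-mm bins; `tsa_by_class()` shows the full
  partition, which sums to TSA exactly).
- **Architecture**: TRW is the horizontal pixel extent; TCA the convex
  hull of the root pixels, taken over pixel *corners* so a solid
  rectangle has solidity exactly 1; SOL = root area / TCA; COPM the row
  centroid of root pixels below the junction (the topmost root pixel,
  ties broken toward the centroid column); RDI the fraction of skeleton
  surface area strictly below one-third of the junction-to-deepest-pixel
  depth.

Resolution sensitivity differs by trait class: TRT, TRL, COPM, RDI,
TCA and TRW are stable to <2% between 50 and 100 px/cm, while DIM, TRV
and the diameter-class areas hinge on sub-pixel width estimation and
should only be compared across images taken at one scale — which is how
pouch campaigns operate (one ruler shot fixes the scale per session).

## The synthetic world

`generate_model()` builds a parametric dicot root system: one tap root
grown downward with auto-correlated heading noise ("wiggle") and
gravitropic relaxation, and `n_laterals` first-order laterals emerging
at alternating sides at jittered-even spacing, with correlated
insertion angles (a developmental gradient that also keeps dense
systems placeable), truncated-normal lengths scaled acropetally (upper
laterals longer), and linear width taper. Defaults (20 cm tap, 1.2 mm
tap / 0.55 mm lateral basal diameters, mean lateral 1.4 cm) emulate a
10-day-old pouch-grown soybean seedling: ~60 laterals give TRL
≈ 140 cm, DIM ≈ 0.5 mm, COPM ≈ 9 cm, matching the observed trait
ranges at five days after transplanting; requested lateral counts of
25–212 span the observed tip-count range 26–213.

Laterals are rejection-sampled (≤100 retries) against a clearance
constraint — no two strand centrelines closer than the sum of radii
plus 0.3 mm — so ground-truth tip counts stay unambiguous after
rasterization. Free endpoints get a wider protected neighbourhood
(0.5 mm plus radii, including the tap tip), because any strand grazing
a tip would erase it from the mask. A lateral that cannot be placed is
truncated before the collision (with the tip re-checked at the wider
margin) or dropped; *truth always describes the realized geometry*. At
the extreme of ~212 requested laterals on a 20-cm tap, crowding caps
realized tip counts near ~130 — the requested range still follows the
study design, and every validation compares measured values against
realized truth.

Ground truth (`truth_traits`) is computed analytically from the
polylines: cylinder-model integrals for TRL/TSA/TRV/DIM and the
diameter classes, offset-point convex hulls for TCA/TRW, and — for the
projected-area traits SOL and COPM, where strand overlap at insertions
must be counted once, as in an image — a rasterization at 120 px/cm,
independent of and finer than anything the measurement pipeline does.
RDI's rooting depth includes the root cap radius, so a uniform
vertical bar scores 0.664 rather than the idealized 2/3.

`render_scene()` rasterizes strands as anti-aliased bright strokes
(width = diameter·px/cm/10) on a dark background, then adds the two
artifact models:

- **Debris**: `debris_count` bright blobs with areas uniform in
  `debris_area_px`, placed uniformly at random but disjoint from the
  root mask (≥4 px clearance) and from each other — each particle is
  thus a guaranteed false tip if not filtered. A rasterized disk
  occasionally thins to a two-endpoint path, so n particles contribute
  between n and 2n false tips; the validation design only requires that
  the inflation *vary* across images (a constant offset would leave the
  correlation untouched).
- **Meniscus halo** (in-air imaging): a half-brightness rim of
  `halo_width_px` around every root plus small full-brightness
  protrusions seeded on root edges. The rim widens apparent roots
  (TSA, TRV, DIM up) and the protrusions add spurious tips and length
  (TRT, TRL up), reproducing the *direction* of the air-vs-water
  comparison; the paper's real-data magnitudes depend on unreported
  meniscus optics and are not reproduced.

Gaussian pixel noise (default sd 5 grey levels) is added last and the
result quantized to 8-bit grey RGB. Everything is deterministic given
the parameter seeds. What a green test establishes: the pipeline
recovers known geometry under this artifact model. What it does not:
robustness to filter-paper texture, uneven illumination, root overlap
in 3D pressed to 2D, or colour variation of real roots — none of which
the generator emulates.

## Statistics

- `r_squared` / `paired_t`: textbook formulas, cross-checked in the
  test suite against independent closed forms to 1e-10.
- `heritability`: H² = Vg/(Vg + Ve/r) with one-way random-effects
  variance components by method of moments (within-genotype mean
  square = Ve; Vg = (between MS − within MS)/r, truncated at zero).
  For balanced designs this equals the mixed-model estimate; for
  unbalanced data r is the standard ANOVA group-size coefficient and
  the result is flagged `balanced = FALSE`. Simulation at G = 286,
  r = 5 recovers the analytic H² within ±0.03 over 50 replicates.
- `count_linkage_blocks`: greedy left-to-right clumping per chromosome
  (a SNP joins the current block iff within 200 kb of the block seed
  and squared correlation with the seed ≥ 0.2, else seeds a new
  block). This is an approximation of Plink clumping — seed-based
  rather than all-member-based — so block counts on real data will
  differ from published values; the Bonferroni threshold
  `-log10(alpha/B)` ("−log" is base 10; only log10 reproduces the
  published 6.6 at B = 212,612) is exact given B.

## Numerical and degenerate-input choices

- Blank image + Otsu: falls back to a fixed midpoint threshold with a
  warning rather than erroring, so batch runs continue.
- All components rejected by the filter: empty mask plus a warning
  (the usual cause is a mis-set threshold), unless
  `keep_largest_always` rescues the largest object.
- Empty mask into skeletonization or measurement: error
  `"no foreground"`; single-pixel mask into the hull: error
  `"degenerate hull"`.
- Junction ties (several topmost pixels): nearest the mask centroid
  column, then the smaller column — deterministic.
- Zero-variance paired differences: flagged degenerate with NA p-value
  (a zero shift returns t = 0, p = 1).
- Negative genetic variance estimates are truncated to zero, keeping
  H² in [0, 1].
- Derived per-image seeds are reduced modulo a 31-bit prime so any
  integer master seed is safe.

## Known limitations

- Sub-pixel diameter traits (DIM, TRV, TSA1, TSA3) carry a
  quantization floor of roughly ±0.5 px/scale; compare them within one
  imaging session, not across resolutions.
- The cleaning filter is area + centre-distance only; debris larger
  than `min_area_px` or overlapping the root system survives by
  design.
- Tip counting assumes the collar produces exactly one skeleton
  endpoint; root systems entering the frame from above satisfy this.
- The greedy linkage-block scan and the seed-based r² convention are
  stated approximations; do not compare absolute block counts against
  Plink output.
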