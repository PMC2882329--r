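---
title: "Methods: quantifying retinogeniculate projection territories in the dLGN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying retinogeniculate projection territories in the dLGN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlgnquant)
```

## The measurement problem

In the mouse, retinal ganglion cell axons from the two eyes occupy largely
non-overlapping territories in the dorsal lateral geniculate nucleus (dLGN):
a small ipsilateral patch embedded in a contralaterally innervated nucleus,
with a corresponding label-free "gap" on the other side. Manipulations such
as monocular enucleation rearrange these territories, and the effect is read
out from serial coronal fluorescence sections in which one eye's axons are
labelled with an anterograde tracer (CTB). `dlgnquant` implements that
readout as a reproducible pipeline: thresholded area fractions, gap
measurement with flood-fill exclusion, normalized intensity profiles, and
patch extents along the two anatomical axes, followed by a variance-gated
two-sample testing procedure. Because the original histology is not publicly
available, the package also ships a synthetic phantom generator whose ground
truth is known exactly, so that every stage can be validated end to end.

## Per-animal quantification

Sections arrive as a rostral-to-caudal ordered stack at 50 µm spacing with
1.00 µm² pixels. The analysis section is the one 100 µm — exactly two
sections — rostral to the section with the largest dLGN cross-sectional
area; ties in area break toward the more rostral section so the choice is
deterministic. Stacks whose area argmax lies within the first two sections
have no analysis section and the animal is excluded, with the exclusion
counted and reported.

The off-tissue background is the mean of a 40,000-pixel region ventromedial
to the dLGN. Only the pixel count is anatomically fixed; the placement is
not, so the default is a 200 × 200 px square whose top-right corner sits
10 px down-left of the dLGN bounding box, and any placement can be supplied
explicitly. The background is subtracted per pixel with clamping at zero
(subtraction is monotone, and idempotent once nothing new is clamped).

**Ipsilateral side.** The threshold `Ti` is referenced to `Mi`, the maximum
background-subtracted intensity over the five consecutive sections centred
on the area argmax, taken inside the dLGN masks only (bright optic-tract
pixels outside the nucleus would corrupt a whole-image maximum). We use the
proportional form `Ti = alpha * Mi`. A max-referenced proportional threshold
is the only form consistent with the way such thresholds are described for
this assay; the coefficient defaults to `alpha = 0.3`, calibrated once on
phantoms spanning noiseless to 10%-noise conditions, and is configurable.
The CTB-positive area counts pixels strictly above `Ti` inside the mask;
the fraction is that area over the dLGN area. For axis measurements the
binarized image is cleaned by removing connected components of 150 px or
fewer (8-connected); the surviving components are the ipsilateral patches.

**Contralateral side.** The threshold `Tc = beta * Mc` (default
`beta = 0.5`) is referenced to `Mc`, the mean of 10,000 pixels of the
ventrolateral monocular segment — fully labelled territory. The subsample is
taken in raster order, a deterministic choice in place of an unspecified
sampling rule. Sub-threshold pixels inside the dLGN are split into
4-connected components; those containing a contour pixel are flood-filled
away, and what remains is the gap. Foreground at 8- and background at
4-connectivity is the standard complementary pairing of digital topology and
avoids paradoxes at diagonal contacts.

A section whose gap reaches the dLGN contour cannot be measured and must be
discarded. The criterion for "reaches the contour" is operationalized here
with an erosion depth: the section is flagged invalid when a
contour-connected sub-threshold component penetrates more than
`max_rim_depth` px (default 5) into the nucleus interior. A thin unlabelled
rim at the contour is normal and harmless; central label-free territory that
drains to the contour is not.

**Profiles.** The intensity profile samples a straight 40-px-wide strip from
the dorsomedial tip to the ventrolateral tip, averages each 1 × 40 px
transverse bin with bilinear interpolation, and divides every bin mean by
the mean of the final 200 bins (the monocular segment of the strip,
200 × 40 px). The profile is therefore invariant to uniform intensity
rescaling. The VGLUT1 variant subtracts a no-primary-antibody control mean
(clamped at zero) and normalizes by the whole-strip average instead,
absorbing between-experiment intensity differences.

## Axis geometry

Patch extents are measured on the binarized, size-filtered patch union.

* **DM-VL.** Line *r* joins the dorsomedial tip D to the ventrolateral tip
  V. Parallel lines at 1-px offsets are swept across the nucleus; on each,
  the patch span is the distance between the outermost patch intersections
  (two endpoints — interior breaks do not subtract). The offset maximizing
  the span defines *r′*; the patch length `Q1Q2` and the dLGN chord `D′V′`
  are read on *r′*, and the normalized extent is `100 * Q1Q2 / D′V′`. Ties
  prefer the larger chord, then the smaller absolute offset. Spans follow
  the unit-square pixel convention (max − min + 1), so a 70-px-wide
  rectangle spans exactly 70.
* **O-I.** Point C is the unweighted centre of mass of the patch union
  (the measurement chain is binary from the size filter onward, so an
  intensity-weighted centroid would be inconsistent). The local surface
  tangent is fitted by total least squares over an 11-point window of the
  outer boundary arc centred on the arc point nearest C — wide enough to
  smooth pixelated boundaries, and configurable. Line *s* runs through C
  perpendicular to that tangent; `LM` spans from the first outer-boundary
  crossing to the last opposite-boundary crossing (a single chord even for
  mildly concave boundaries), `P1P2` is the outermost patch span on *s*
  (zero, reported rather than an error, when *s* misses the patch), and the
  normalized extent is `100 * P1P2 / LM`. Crossings are located by sampling
  at 0.25-px steps, so chord lengths carry sub-pixel quantization error.

When several disjoint patches survive the size filter their union is used
throughout; a largest-patch-only variant would change C and `Q1Q2` and is
deliberately not the default.

## Group statistics

Two groups are compared with the study's gated procedure: a two-sided
F-test on the variances (larger variance on top, `p = 2 * min(tail,
1 - tail)`), then Student's pooled-variance t-test when the gate does not
reject (p ≥ 0.05) and Welch's t-test with Satterthwaite degrees of freedom
when it does. All tests are two-sided. Summary-statistic entry points
(`summary_t()`, `f_variance_gate()`) accept printed `(mean, SD, n)`
triplets directly, so published group summaries can be re-tested;
`sample_t()` on raw values agrees with the summary route exactly. Three or
more groups go to the Tukey–Kramer test: studentized-range p-values with
the classical unequal-n standard error and pooled within-group variance.
`stats::pf`, `stats::pt` and `stats::ptukey` supply the distributions;
the test statistics themselves are computed from the closed forms because
no base routine accepts summary statistics.

Note that printed null results (exact p-values like 0.91) were computed
from unrounded raw per-animal data; re-testing the rounded printed
summaries reproduces the significance classification, not those exact
digits.

## The phantom generator

The phantom emulates the geometry the assay sees: a crescent-shaped dLGN
built from two concentric circular arcs (default outer radius 220 px, inner
80 px, 120° span) in a 700 × 540 px frame, dorsomedial up. Across the
seven-section stack the radii scale down linearly away from the middle
section, giving a unique area maximum there, as in a real nucleus. Each
rendered section carries consistent landmarks (tips, outer arc, background
region) and a ground-truth record whose fractions are exact mask pixel
counts.

A section renders either an ipsilateral patch (an angular sector clipped to
a radial band, intensity plateau at `label_intensity` over
`background_level`) or a contralateral pattern (full labelling with a
circular interior gap and a 2-px unlabelled rim that exercises the
flood-fill exclusion) — not both, because the two signals come from
different hemispheres and a shared image would make the max-referenced
ipsilateral threshold meaningless. The O-I extent of the patch is set
exactly by the radial band thickness; the DM-VL extent is set by solving
the sector width against the target with a short bisection on the rendered
masks. Ground-truth axis lengths are measured on the noise-free masks; the
geometry engine itself is validated separately against exhaustive-sweep
oracles and analytic expectations on rectangles and annular sectors, so
truth and measurement are not circular.

Noise is additive Gaussian on top of an optional low-order multiplicative
illumination bias, and intensities are quantized to integer ADU as a camera
would (written TIFFs therefore round-trip losslessly). No image-level noise
statistics are available for the original data, so the defaults are
calibration choices: `label_intensity` 3000 and `background_level` 500 on
the 16-bit scale, validation noise at one tenth of the net plateau. What
the phantom does *not* emulate: axon-arbor texture, partial-volume edges,
section-to-section registration jitter, and delineation error in the dLGN
boundary (boundaries are inputs to the real assay too). Passing recovery
tests therefore demonstrates correctness of the measurement chain, not
robustness to segmentation error.

Cohort simulation has two deliberately distinct modes: endpoint draws
(`simulate_cohort()`), which sample the measured percentage directly from a
printed `(mean, SD, n)` model truncated at zero for the statistics stage;
and image-parameter draws (`run_quantification()` presets), which render a
phantom series per animal and push it through the full blind pipeline —
group labels are joined only at the statistics stage, mirroring blind image
analysis.

## Numerical choices and problem sizes

Strict inequalities are used at both thresholds (above `Ti`, below `Tc`)
and at the patch filter (strictly more than 150 px), matching the assay's
stated conventions. Coordinates are row-major, origin top-left, pixels are
unit squares. The validation suite runs 20 seeded phantoms with patch
fractions uniform on 5–30%, gap fractions on 5–25%, and noise at one tenth
of the plateau; the null calibration of the gated procedure uses 10,000
replicates at n = 5 vs 3. These sizes make the whole suite runnable on a
single CPU in minutes while leaving the Monte-Carlo error well below the
tolerances being checked.

## Known limitations

* The proportionality coefficients `alpha` and `beta` are calibration
  choices, not published constants; results should be reported together
  with the coefficients used.
* The contour-connection discard rule depends on `max_rim_depth`; very
  thick unlabelled rims (beyond 5 px) would require raising it.
* The profile strip is a straight line; strongly curved nuclei would need a
  curvature-following path, which is out of scope.
* Axis measurements are per-section; no 3-D reconstruction across the stack
  is attempted.
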