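# dlgnquant

Quantification of eye-specific retinogeniculate projection territories in
the mouse dorsal lateral geniculate nucleus (dLGN), for developmental
neuroscientists measuring how manipulations such as monocular enucleation
rearrange retinal axon territories after eye-specific segregation.

Retinal ganglion cell axons labelled with an anterograde tracer (CTB) form
a small ipsilateral patch and, on the other side, a near-fully labelled
nucleus with a central label-free "gap". From serial coronal fluorescence
sections this package computes, per animal:

* **analysis-section selection** — the section 100 µm rostral to the
  section with the largest dLGN cross-sectional area;
* **ipsilateral territory** — background-subtracted signal thresholded at
  `Ti = α·Mi`, where `Mi` is the in-mask maximum over the five sections
  centred on the area argmax; area, fraction of the dLGN, and the
  size-filtered (> 150 px, 8-connected) **ipsilateral patches**;
* **contralateral gap** — sub-threshold pixels at `Tc = β·Mc` (`Mc` = mean
  of 10,000 monocular-segment pixels), with contour-connected regions
  removed by 4-connected flood fill;
* **normalized intensity profiles** — 40-px strip from the dorsomedial tip,
  bins normalized by the trailing 200-bin monocular segment;
* **axis extents** — patch length along the dorsomedial–ventrolateral axis
  (`Q1Q2/D′V′ × 100`, maximizing sweep parallel to the tip-to-tip line) and
  along the outer–inner axis (`P1P2/LM × 100`, on the line through the
  patch centre of mass perpendicular to the dLGN surface);
* **group statistics** — the variance-gated procedure (two-sided F-test on
  SDs; Student's t when not rejected, Welch's t when rejected;
  Tukey–Kramer for ≥ 3 groups), usable directly on printed
  `(mean, SD, n)` summaries.

A synthetic phantom generator renders crescent-shaped dLGN section stacks
with exact ground truth (patch/gap fractions, axis extents, landmarks), so
the entire pipeline is testable without microscopy data.

## Worked example

Re-test a printed two-group summary (ipsilateral area fraction, enucleated
vs control) through the variance gate:

```r
library(dlgnquant)

p <- cohort_preset("Fig2A")
#>   group    mean    sd     n
#> 1 ME       22.1   3.6     5
#> 2 control  10.8   1.2     3

tidy(gated_compare(p[1, ], p[2, ]))
#>   test    statistic    df       p gate_p gate_statistic stars
#> 1 student      5.12     6 0.00217  0.205              9 **
```

The F-gate (F = 9, p = 0.205) finds no variance difference, so the means
are compared with Student's t: t = 5.12 on 6 df, p = 0.0022 — the enucleated
group's ipsilateral territory is significantly larger (and more than 2-fold:
22.1/10.8 ≈ 2.05).

Render a noisy phantom with a known 20% ipsilateral patch and recover it
blind through the full pipeline:

```r
ms  <- make_series(phantom_spec(patch_fraction = 0.2, noise_sd = 250, seed = 42))
rec <- quantify_series(ms$series)
rec[, c("analysis_index", "Mi", "Ti", "ipsi_fraction_pct",
        "norm_dmvl_pct", "norm_oi_pct")]
#>   analysis_index      Mi      Ti ipsi_fraction_pct norm_dmvl_pct norm_oi_pct
#> 1              2 3472.87 1041.86             20.00         35.68       79.91

ms$truth$sections[[2]][c("patch_fraction_pct", "norm_dmvl", "norm_oi")]
#> 19.99742  35.68465  79.91453
```

The recovered fraction (20.00%) and both normalized axis extents match the
rendered ground truth; `autoplot()` methods are available for profiles and
validation reports, and `run_quantification()` / `run_phantom_validation()`
orchestrate whole cohorts (a thin CLI lives in `inst/cli/dlgnquant.R`).

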