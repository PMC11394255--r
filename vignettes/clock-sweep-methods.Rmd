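---
title: "The clock-sweep brightness radar and paired reader-study evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clock-sweep brightness radar and paired reader-study evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clocksweep)
```

## The problem

Distinguishing early melanoma from clinically atypical nevi on dermoscopy is
hard even for experts, and deep-learning classifiers that do it well are
opaque. An alternative is a *transparent* image cue: a single, visually
explainable statistic overlaid on the image that a clinician can integrate
with their own judgment. This package implements one such cue — the
"clock-sweep radar" of angular brightness irregularity — together with the
machinery to evaluate, in a paired reader study, whether showing the cue
changes diagnostic accuracy.

## The clock-sweep statistic

Imagine a clock face superimposed on the lesion, centred on its centroid.
For each clock angle $\theta$ (measured clockwise from 12 o'clock), the
*arm brightness* $m(\theta)$ is the mean image intensity along the segment
from the centroid to the peripheral margin at that angle. The cue is

$$\frac{\Delta}{\bar m} = \frac{\max_\theta m(\theta) - \min_\theta m(\theta)}{\frac{1}{n}\sum_\theta m(\theta)},$$

a dimensionless measure of angular brightness irregularity: 0 for a lesion
whose brightness is the same in every direction, larger when one sector is
much darker or lighter than another — the kind of asymmetry dermoscopists
look for. Three "hands" annotate the overlay: blue at the darkest angle,
green at the brightest, red at the angle of maximum brightness variation
(the peak of the absolute circular derivative of $m$).

Interpretation choices the definition leaves open, and how we fixed them:

* **"Brightness on the arm" is the along-arm mean.** An angle-indexed
  brightness functional could also be the margin sample or a length-weighted
  integral; the arm mean is the simplest functional of the whole arm and is
  what the implementation uses. With no radial trend in the interior the
  choices coincide, which is exactly the regime the synthetic ground truth
  covers; on real images the choice matters and cannot be validated without
  the original material.
* **The denominator is the mean of the angular profile**, not the mean over
  all lesion pixels, so the statistic is a functional of the profile alone.
  `sweep_statistic(..., mean_value = lesion_mean_intensity(...))` provides
  the whole-lesion alternative; for radially flat lesions the two agree to a
  few percent.
* **The variation hand** uses a central difference on the circular grid
  after a circular moving average (default window 5 samples) because a raw
  pixel-level derivative is noise-dominated. Ties in all argmin/argmax are
  broken toward the smallest angle (closest to noon, clockwise), making
  results deterministic.

## Segmentation

The sweep needs a centroid and a margin. Images are converted to grayscale
by Rec. 601 luminance, thresholded by Otsu's criterion with the lesion as
the *darker* class (the usual pigmented-lesion polarity), reduced to the
largest 4-connected component with holes filled, and summarized by the
binary centroid. The margin radius at each of 360 clock angles is the
distance to the **last** in-mask sample along the ray, so concave borders
are spanned rather than clipped. Whether the original study segmented
manually or automatically is not recorded anywhere we could find;
segmentation here is a declared implementation choice, kept parameter-free.

Arm intensities are sampled by *mask-aware* bilinear interpolation: the
interpolation weights are renormalized over in-mask pixels. Without this,
the sample nearest the margin blends in the much brighter background and
biases the profile upward at every angle; with it, a uniform lesion yields
an exactly constant profile and statistic 0.

## Synthetic lesions with analytic ground truth

`lesion_spec()` / `generate_lesion_image()` emulate a single roughly
elliptical pigmented lesion, darker than the skin background, with

* margin $r(\theta) = R_0\,(1 + \sum_k a_k \cos(k\theta + \phi_k))$
  (low-order harmonics give realistic border irregularity),
* interior intensity $L_0\,(1 + A\sin(\theta + \phi))$, $A \in [0,1)$,
* optional additive Gaussian pixel noise, clipped to $[0, 255]$.

Because the interior has no radial dependence, the arm mean equals
$L_0(1 + A\sin(\theta+\phi))$ analytically and the statistic is exactly
$2A$, so the whole imaging chain can be tested for recovery. Defaults
(1024×1024 px, $R_0 = 350$, background 200, $L_0 = 80$, noise 0) emulate the
one-megapixel low end of cropped dermoscopy photographs; at this scale the
chain recovers $2A$ within about 0.4 % relative (the dominant residual is
the $O(1/n_{\text{samples}})$ dilution from the centroid endpoint of each
arm, which at much smaller scales — e.g. a 60 px lesion radius — grows to
about 2 %). What the generator does **not** emulate: colour, hair, air
bubbles, pigment networks, radial pigment gradients, or camera optics —
passing tests show the estimator chain is correct, not that the statistic
separates melanoma from nevus on real images.

## The paired reader study

The evaluation design: each reader classifies every image as melanoma or
nevus twice, first from the image alone, then with the cue overlay, giving
paired binary decisions per (reader, image). Scoring uses melanoma as the
positive class:

* sensitivity = hits / melanomas, specificity = correct rejections / nevi;
* discriminability $d' = z(\text{hit rate}) - z(\text{false-alarm rate})$
  under the equal-variance Gaussian model, with the standard $1/(2n)$
  correction for rates of exactly 0 or 1 (never triggered by the shipped
  study data);
* per-metric matched-sample $t$-tests on the per-reader with-minus-without
  differences, $df = n_{\text{readers}} - 1$, two-sided by default with a
  one-sided option (the two conventions explain the two families of
  p-values quoted for the same comparisons in different places in published
  summaries of this design).

`reader_spec()` / `simulate_reader_responses()` generate such data from the
same model: evidence $x \sim N(0,1)$ for nevi and $N(d',1)$ for melanomas,
response "melanoma" iff $x >$ criterion, with per-reader $d'$ per condition
and truth labels shared across conditions. The default criterion is
$d'_{\text{without}}/2$ (unbiased at baseline). At study scale
(38 + 40 images) the plug-in $d'$ estimator carries a small positive
finite-sample bias (about +0.04 at $d' = 0.94$; see
`analysis/04_reader_simulation.R`), which disappears at large $n$ — a
caveat for reading any small-study $d'$ table, not a defect of the scoring.

## The shipped study summary, and reproducing it

`published_reader_summary()` returns the printed accuracy table of a
published ten-reader melanoma-versus-nevus study (sensitivity/specificity
percentages, their increases, and $d'$ per condition, plus a Mean row),
included as reference input data. Three reproduction conventions matter and
are deliberate:

* **$d'$ from printed rates.** Recomputing $d'$ from the 1-decimal printed
  percentages reproduces all 20 printed $d'$ cells and all 10 increase
  cells to 2 decimals; recomputing from exact reconstructed counts changes
  one cell by 0.01. `build_study_report()` therefore rounds per-reader
  rates to 1 decimal (percent) before the $z$-transform — parity with how
  such tables are evidently produced.
* **Mean row.** Per-reader cells are rounded first and the Mean row
  averages the rounded cells; the Mean of each increase column is the
  difference of the two condition means. This reproduces every printed Mean
  entry (0.94, 1.41, 0.47 for $d'$).
* **Denominators.** The printed percentages are only consistent with 38
  melanomas and 40 nevi per reader — `infer_denominators()` shows this
  split of the 78 images is unique — although the accompanying text
  describes 39 + 39 with the first two demonstration images shown
  separately. We use the implied 38/40 and document, rather than resolve,
  the discrepancy. One printed sensitivity-increase cell (2.5) is
  internally inconsistent with its own condition cells (84.2 − 81.6 = 2.6);
  the pipeline reproduces the self-consistent 2.6, and consequently a Mean
  sensitivity increase of 7.88 rather than the printed 7.87.

`reconstruct_response_table()` inverts the percentages to integer confusion
counts and lays them out as a response table; which individual images are
correct is not identifiable from the margins, and no marginal statistic
depends on that assignment.

## Problem sizes and numerical choices

The bundled analysis scripts and tests use: 360 clock angles (smoothing
window 5); arm sampling at `max(32, ceiling(margin_radius))` points;
synthetic recovery at the four modulation depths 0.05–0.4 on noise-free
1 MP lesions; simulation recovery with ten readers at 10^4 images per
reader plus 200 study-scale replicates. Margin radii are ray-marched at
0.5 px steps; a margin radius under 1 px or a threshold that fails to
separate two intensity populations raises an explicit segmentation error.
JSON artifacts are written at full precision and are byte-identical across
reruns with the same seed; only the report CSV applies the printed-table
rounding.

## Limitations

The cue's diagnostic value on real dermoscopy cannot be established here:
no deposited image set exists, so the original study's worked example value
(Δ/mean = 0.29 for one nevus) is not desk-reproducible and the imaging
chain is validated on synthetic ground truth only. The reader simulator
ignores learning, anchoring on machine output, and criterion shifts between
conditions — effects a real paired design can exhibit. JPEG input is not
supported (PNG/TIFF only).
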