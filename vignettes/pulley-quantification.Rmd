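---
title: "Quantifying pulley histopathology: methods and design notes"
author: "pulleyQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulley histopathology: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulleyQuant)
```

## The measurement problem

Grading trigger finger from H&E-stained A1-pulley sections asks a
pathologist to judge, across an entire microslide, how much of the
tissue has undergone fibrocartilaginous metaplasia and how far the
nuclear morphology has shifted from elongated fibroblast rods to round
chondrocyte-like nuclei. Both judgments are color- and shape-based and
both are exactly the kind of quantity an observer estimates poorly but
a pixel count measures well. `pulleyQuant` turns each specimen into two
numbers: the abnormal-tissue area ratio (parameter 1) and the
abnormal-nucleus number ratio (parameter 2), both of the form
abnormal / (abnormal + normal) and hence in [0, 1].

The pipeline assumes: (i) staining follows H&E conventions — collagen
pink, metaplastic matrix blue/purple, chromatin dark blue; (ii) the
empty slide is bright and nearly achromatic with a faint cool tint, so
its hue sits above the pink range; (iii) images of one study are
acquired under broadly comparable optics, with batch-to-batch color
variation that a global statistics transfer can absorb. Within those
assumptions every stage is automatic and deterministic.

## Color normalization

Statistics transfer operates in the decorrelated logarithmic lαβ space:
RGB is mapped through the cone-response matrix to LMS, a natural
logarithm is applied, and a fixed rotation yields one luminance and two
chromatic opponent axes. Per channel, the source image's mean and
standard deviation are replaced by those of a target profile; the
result is rotated and exponentiated back and quantized to 8-bit.

Numerical choices the transfer needs but the math leaves open:

- **Log clamp.** The logarithm is undefined at 0; LMS values are
  clamped to ε = 1/255 first, which preserves ordering and bounds the
  dynamic range. Black pixels therefore stay finite.
- **Log base.** Natural log, paired with a natural exponential in the
  inverse; any base works if used consistently.
- **Gamut handling.** After inversion, channels are clipped to
  [0, 255] and rounded half-up. The forward/backward matrices are a
  rounded inverse pair; a round trip is exact to within ±3 levels for
  pixels with all channels ≥ 10 (asserted over 10⁴ random pixels in the
  test suite).
- **Degenerate sources.** A constant channel has zero spread and no
  well-defined rescale; this is an error by default, and
  `onZeroSd = "identity"` downgrades it to a shift-only transfer.

Before the lossy inversion the transformed statistics equal the profile
exactly (`normalizeLab()` exposes this stage; the test suite asserts
agreement to 10⁻⁹). Target images are an operator choice — high
contrast, dark blue nuclei — supplied as paths; a profile is built once
(`buildTargetProfile()`), serialized to YAML, and reused.

## Three-step tissue segmentation

Hue is computed from the HSI model,
$\theta = \arccos\left(\tfrac{1}{2}[(R-G)+(R-B)] \,/\,
\sqrt{(R-G)^2+(R-B)(G-B)}\right)$, with $H=\theta$ if $B \le G$ and
$360-\theta$ otherwise; achromatic pixels have no hue and are flagged.
On normalized slides pink tissue is low hue, while the empty background
and the purple metaplastic areas are high hue — which is why one
threshold is not enough:

1. Otsu's threshold (exhaustive scan of k = 0…255 maximizing
   $\omega_0\omega_1(\mu_0-\mu_1)^2$, ties to the smallest k) on the hue
   histogram, scaled linearly to [0, 255], splits rough foreground
   (low hue) from rough background. Undefined-hue pixels join the rough
   background — they are white slide, not tissue.
2. Within the rough background only, a second Otsu cut on the G channel
   recovers the purple tissue that step 1 misplaced (purple is dark in
   G, slide background bright). If that population has fewer than two
   distinct values there is nothing to recover.
3. A third Otsu cut on the hue of the complete foreground separates
   normal (low hue, at or below the cut) from abnormal tissue. A
   single-hue foreground is an all-normal specimen, not an error.

Each split carries an orientation guard: if the "low" class would
swallow more than 95% of its population the split is assumed inverted
and flipped. A 9×9 majority rank filter (window cropped at borders, tie
priority BACKGROUND > NORMAL > ABNORMAL, applied once) removes the
fragmented labels that Otsu leaves along region boundaries.

Known limitation: hue is treated as a linear axis, so pink that wraps
past 360° (B marginally above G) is misread as high hue. Normalization
stabilizes hue ranges and makes this rare, but strongly blue-shifted
pink could still defeat step 1; the orientation guard catches only the
extreme case.

## Nuclei segmentation and classification

Nuclei are the darkest structures of the R channel. Because absolute
intensities vary between images, the double threshold is *active*: the
base intensity is the mean of the image's 10 darkest pixels, seeds lie
at or below base + 30, and 8-connected region growing from the seeds is
restricted to pixels at or below base + 45. The two offsets are
empirical margins for normalized images; both are parameters
(`doubleThresholdParams()`). Because the base derives from the image's
own minima, at least one seed always exists — a nuclei-free tile
segments its darkest texture, which is why such tiles are excluded at
image selection, not by the algorithm.

Each 8-connected component of at least 5 px (smaller components are
noise with meaningless shape) is measured: area; perimeter as the
Moore-traced outer contour with diagonal steps weighted √2 (reduces the
rasterization bias of pixel-count perimeters; circularity of a
rasterized disc is 1 within 0.15); circularity 4πA/P²; and the
maximum/minimum Euclidean distances from the centroid to the inner
boundary pixels. Strongly concave regions whose centroid falls outside
the pixel set are measured as stated and flagged.

The classifier is three hard gates: a normal rod requires circularity
< 0.95, elongation d_max/d_min > 3 and area < 2000 px; failing regions
are abnormal — single round nuclei below 2000 px, otherwise
multinucleus clusters. A cluster's nucleus count is its area divided by
the mean area of the *same image's* single round nuclei, rounded
half-up with a floor of one; with no single rounds in the image each
cluster counts one nucleus (with a warning). The area gate is
calibrated for 2560×1920 acquisitions and scales with magnification;
on the package's ¼-scale synthetic fields planted nuclei are a few
hundred px and sit far from the gate.

## Severity scoring and stage discrimination

Specimens aggregate sum-then-ratio: areas and counts are summed over a
specimen's images first, then the ratios are formed (the mean of
per-image ratios is a different and rejected convention — the tests
pin the distinction). Stage discrimination fits two cuts from the H/M/L
group means of the ratios, cutHM = (mean_H + mean_M)/2 and cutML =
(mean_M + mean_L)/2, requiring strictly decreasing means; a ratio
exactly at a cut takes the higher stage. Ratios are kept at full
precision and rounded to 3 decimals only for display — the boundary
convention plus full precision is what lets a specimen sitting exactly
at the printed H/M cut classify H. Normal (N) specimens are summarized
descriptively and excluded from cut fitting.

Group differences use the two-tailed two-sample t-test. The default is
Welch's unequal-variance form with Satterthwaite degrees of freedom:
the stage groups are small (6–10) with visibly unequal spread (the L
group's SD is three times the M group's), where the pooled test is
anticonservative. A pooled option exists. Two constant groups compare
as p = 1 (equal means) or p = 0 (different means).

```{r cohort}
rc <- referenceCohort()
q <- quantifyCohort(rc$tissue, rc$nuclei)
q$analysis2$groups
q$analysis2$cuts
q$analysis2$comparisons
q$analysis2$misclassified
```

## The synthetic slide generator

`simulateImage()` renders the image class the pipeline assumes, with
exact ground truth: an elliptical tissue region of pink fibers with
sinusoidal banding and low-hue jitter on a bright blue-gray slide
background; purple elliptical metaplastic patches added until a
requested fraction of the tissue is covered (patch size bounds the
overshoot below 0.02); non-overlapping dark-blue nuclei — thin rotated
elliptical rods in normal tissue, discs preferring metaplastic hosts —
with ≥ 2 px clearance so 8-connectivity never merges them; then a
horizontal illumination gradient, an optional global color cast, and
Gaussian pixel noise. One seeded RNG stream per call; identical
configurations render bitwise-identical images.

Design choices worth recording:

- **Colors.** Pink defaults to (235, 170, 150) — salmon, G clearly
  above B — because eosin pink must sit at *low* hue for the HSI-based
  segmentation, and a pink with B > G wraps to hue ≈ 350°, which is the
  documented failure mode, not the typical slide. The background
  (232, 235, 250) carries a deliberate cool tint strong enough to
  survive moment transfer and highlight clipping, keeping the slide at
  high hue as on stained acquisitions. Purple (150, 95, 175) and
  nucleus (60, 50, 110) follow H&E convention. All are overridable.
- **Geometry.** Default fields are 640×480 (¼ scale of a 2560×1920
  acquisition) with rods of semi-axes 18–28 × 1.8–2.8 px and round
  radii 8–12 px — elongations ≈ 10 and areas of 150–450 px, inside the
  classifier's gates with wide margins.
- **Host fallback.** Rounds prefer metaplastic hosts; after half the
  bounded placement attempts they accept any tissue, because at low
  abnormal fractions the patches cannot hold many discs. Genuinely
  infeasible configurations still error.
- **Specimen sets.** `simulateSpecimenSet()` draws per-image abnormal
  fractions from stage ranges (defaults H 0.24–0.28, M 0.18–0.22,
  L 0.06–0.16) and couples the round-nucleus share to the stage
  (H 0.65–0.78 down to N 0.33–0.45), mirroring the ordering of the
  reference cohort's count ratios.

What the generator does *not* emulate — and what passing tests
therefore do not show about clinical slides: stain chemistry and
optics, out-of-focus blur, touching or overlapping nuclei (the cluster
path is exercised with constructed fixtures instead), microvasculature
and debris, gradual pink-to-purple transitions, and JPEG artifacts.
Synthetic validation demonstrates that the implementation measures what
it defines; it does not replace validation on stained tissue.

## Verification strategy and problem sizes

Every algorithmic component is checked against an independent oracle:
Otsu against a from-definition brute-force maximizer over all 256
thresholds; the rank filter against a naive 81-cell counting loop;
shape features against analytic disc/ellipse geometry and hand-computed
small shapes; the double threshold against hand-traced growth on
three-level images; Welch/pooled statistics against their textbook
formulas; normalization against its exact-moment-matching contract.
End-to-end runs use seeded synthetic specimens (480×360 fields, three
specimens across H/M/L) and require the measured abnormal-area ratio to
track the true metaplastic fraction within 0.03 and planted nucleus
counts to be recovered exactly; the whole suite runs in well under a
minute. Pixel-level residuals at patch boundaries — antialiasing-free
rendering against Otsu cuts plus the rank filter — dominate the 0.03
budget, with rod nuclei (dark chromatin on pink, counted abnormal by
hue but normal-hosted in ground truth) contributing the rest.

## Limitations

- Hue wrap-around for blue-shifted pink (above) is the main failure
  mode of step 1; the 95% orientation guard only catches gross
  inversions.
- Otsu assumes a meaningfully bimodal population at every step; a slide
  that is nearly all one class drives the corresponding cut into the
  bulk mode. The all-normal short-circuit handles the exact degenerate
  case, not the nearly-degenerate one.
- Cluster nucleus counts inherit the variance of the mean single-round
  area; images with very few single rounds give noisy cluster counts.
- The stage cuts are fitted to the cohort at hand (resubstitution, no
  held-out validation) — with 26 diseased specimens that is a
  descriptive discrimination, not a validated classifier, and the two
  parameters are deliberately not combined into one score.
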