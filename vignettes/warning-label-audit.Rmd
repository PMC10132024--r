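---
title: "Auditing health-warning labels in promotional images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing health-warning labels in promotional images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warnscan)
```

## The problem

US tobacco advertising rules require a health warning that (1) occupies at
least 20% of the advertisement's area and (2) appears on the advertisement's
upper portion. Social-media promotions — influencer posts picturing little
cigars and cigarillos, for instance — are image-first advertising at a scale
where manual review does not keep up. `warnscan` provides a deterministic
computer-vision audit for this setting: detect the boxed warning in each
still image, measure its size and placement, score the two rules, and relate
warning presence to post engagement.

The detector exploits the one visual invariant such warnings have: a
rectangular box with a black border containing text that begins with the
word "WARNING". Detection is a cascade over four cues — pixel darkness,
contour area, contour shape, and recognised text — so that each cheap layer
prunes candidates for the next, and a text match is required before anything
is reported. That last requirement is what keeps the false-positive rate at
zero in practice: dark rectangles are everywhere in photographs; dark
rectangles whose contents read "WARNING" are warning labels.

## The detection cascade

For an image $I$ of width $W$ and height $H$ (pixel area $A = WH$):

1. **Dark-pixel selection.** Convert to grayscale by the standard luminance
   weights $0.299R + 0.587G + 0.114B$ and select pixels with intensity below
   a cutoff. The default cutoff is 100/255, chosen because mandated borders
   are near-black while most photographic content is not; an Otsu-threshold
   variant covers images whose border is dark only relative to the scene.
2. **Noise removal.** Optional box blur (re-binarised at 0.5) and a
   morphological opening (erosion then dilation, square kernel, default
   3 px) delete speckle smaller than the kernel while approximately
   preserving box-scale components.
3. **Contour extraction.** Connected components of the mask are traced to
   closed boundary polygons. Hole boundaries are traced too: a thick border
   is a hollow rectangle, and its inner white rectangle is an equally good
   candidate. The interior area of an external contour counts everything the
   boundary encloses — border, text, and background inside the box.
4. **Area band.** Candidates are kept when their interior area lies in
   $[600, A/2]$ px², both ends inclusive. The floor is the empirical
   smallest box whose text an OCR engine can still read; the ceiling stops
   the image frame or a dark scene half from qualifying.
5. **Shape test.** Each surviving boundary is simplified by
   Ramer–Douglas–Peucker with tolerance $0.03 \times$ perimeter; a candidate
   passes if the simplified polygon has exactly 4 vertices and is convex.
   The tolerance admits mild rotation and raster staircase noise (a
   rectangle rotated 10° still passes) while a circle of any size simplifies
   to 5 or more vertices and fails.
6. **Keyword confirmation.** The candidate's bounding box (plus a 3 px
   margin) is cropped and sent to the text-recognition backend; the
   candidate is confirmed if the recognised text contains "warning"
   case-insensitively after whitespace normalisation. Fuzzy matching (edit
   distance 1) exists behind a flag and is off by default, because it trades
   specificity for robustness the audit does not need.

The cascade runs over an ordered family of four preprocessing variants
(plain threshold 100, threshold 100 with blur + opening, strict threshold
60, Otsu) and stops at the first variant that yields a confirmed label.
Within a variant, boxes whose overlap exceeds 80% of the smaller box are
deduplicated (outer box kept — one label, one detection) and the
largest-area confirmed box is reported, since the dominant box is the
regulatory object. The variant loop only adds detection opportunities, so
removing variants can only lose detections, never invent them — a property
the tests check directly.

Reported geometry: the label's *bounding-box* area over the image area. The
contour interior area drives the 600 px² filter (it is the natural measure
of a traced shape), but the box is what a viewer sees and what the 20% rule
is written about; for the axis-aligned labels the rule targets, the two
agree.

## Compliance scoring

A detection meets the **area rule** when its area fraction is $\ge 0.20$
(inclusive — "at least 20%") and the **placement rule** when the vertical
center of its box lies strictly above $H/2$; a center exactly at $H/2$
counts as lower. The center rule is a declared convention: regulation text
speaks of the "upper portion" without defining it for borderless social
images, and a center rule is robust to label height where a
full-containment rule is not. Corpus summaries report warning prevalence
and full compliance as percentages of all posts, and the two single-rule
percentages among detected-warning posts, rounded half-up to one decimal —
the denominators audit reports conventionally use.

## Text recognition: two backends

OCR is a pluggable interface. The `tesseract` backend shells out to a
Tesseract executable when one is installed, and raises an explicit
configuration error when not — a silent "no text found" would
indistinguishably mean "no warning", which is the one failure mode an audit
tool must not have. The default `template` backend is a deterministic glyph
matcher for the package's own bundled 5×7 dot-matrix font, the font the
fixture generator renders with: dark 8-connected components in the crop are
segmented, size-filtered against the component height distribution (which
drops the border frame), rescaled to each glyph template and accepted at
mean-agreement ≥ 0.85, then assembled into lines by vertical clustering.
Matching is symmetric (component compared in the template's space and the
template in the component's) so tiny punctuation templates cannot match
arbitrary shapes. The template backend exists because engine-version drift
in a third-party OCR binary would make test results machine-dependent; it
is valid only for the bundled font and says nothing about Tesseract's
accuracy on real photographs.

## The fixture generator

`generate_corpus()` is the package's study-condition generator: seeded,
fully reproducible post-like images with a ground-truth manifest. Defaults
are fixed once and are the conditions all detector tests run under:
800×800 px canvases; label area fraction uniform on $[0.05, 0.35]$
(real labels cluster well below the 20% requirement); wide aspect ratios
(2.5–4:1); 6 px borders; backgrounds drawn from flat grays, vertical
gradients, ±35-intensity speckle noise, and blotchy low-frequency texture,
all in the light-to-mid range with mid-dark content that exercises the
dark-pixel filter's false-candidate path; a quarter of unlabelled images
carry a black-bordered decoy box with non-warning text, so specificity is
earned at the OCR layer, not by the absence of dark rectangles. Labels are
floored at 112×42 px, the smallest box that typesets the bare keyword
legibly; smaller targets are produced via the degrade path instead.

Two degrade modes reproduce the documented failure modes of
vision-based warning detection — labels *too blurry* or *too small*:
`blur` applies a Gaussian (σ = 3) to the rendered label, destroying glyph
structure while often leaving the box; `shrink` renders the label and then
down-scales the raster (default ×0.2), so its text is unreadable and, for
small base sizes, its contour area falls under the 600 px² floor. Both are
designed misses, asserted as such in the tests.

What the generator does not emulate: real photographs. There are no
perspective distortions, no partially occluded labels, no fonts other than
the bundled one, no JPEG artefacts, no humans or products. Passing the
fixture-corpus tests therefore demonstrates that the cascade's logic —
thresholds, geometry, deduplication, keyword gating — is correct and
deterministic, not that any particular recall would be achieved on real
Instagram data; on real data the OCR backend and color filtering dominate,
and those must be validated against manually coded images.

## The engagement model

Post engagement (likes; comments) is modelled as negative binomial with a
log link:

$$ y_{ij} \sim \mathrm{NB}(\mu_{ij}, \theta), \qquad
\log \mu_{ij} = \beta_0 + \beta_w \, \mathrm{warning}_{ij}
 + \beta_f \log(\mathrm{followers}_i + 1) + \gamma_{b(ij)} + u_i, $$

with $u_i \sim N(0, \sigma_u^2)$ a per-influencer random intercept
(posts by the same influencer are not independent) and NB2 variance
$\mu + \mu^2/\theta$, the standard choice for overdispersed social-count
data. Fitting uses `glmmTMB` (Laplace approximation, default convergence
tolerances); the package reports $e^{\beta}$ as incidence rate ratios with
Wald 95% CIs, and `pct_change()` converts an IRR to the "% fewer likes"
reading: $(\mathrm{IRR} - 1) \times 100$.

Declared conventions the data cannot pin down: followers enter as
$\log(\text{count}+1)$ (counts span orders of magnitude; a raw-scale option
exists), and brands are treatment-coded against the alphabetically first
level. Variance inflation factors are computed per column of the
fixed-effects design matrix as $1/(1-R^2)$ — the classic definition — and
Cohen's kappa for intercoder reliability comes straight from the two-rater
cross-tabulation.

`simulate_engagement()` draws data from exactly this generative model, for
parameter-recovery testing. Default nuisance parameters, fixed once:
intercept −1.0; follower coefficient 0.6; followers per influencer
log-normal(meanlog = log 20 000, sdlog = 1.2), giving median ≈ 20 k
followers and mean likes in the low hundreds; brand offsets 0 / +0.10 /
−0.10; $\theta = 1.5$ (variance-to-mean ratios well above 2 at these
means); $\sigma_u = 0.5$; warning prevalence 0.1, matching how rare
warnings are in observed promotional corpora. Recovery tests fit
$n = 2000$ posts from 100 influencers — large enough that the warning
coefficient's standard error (~0.07 on the log scale) separates signal
from noise, small enough to fit in about a second — and check both
closeness (within 3 SE of truth) and 95% CI coverage across 20 replicates.

## Numerical and degenerate-case choices

- Thresholds are inclusive at both ends of the area band, and the area rule
  is inclusive at 0.20; every boundary has a fixed, tested answer.
- "Half the image size" for the area ceiling means half the *pixel area*,
  consistent with the floor being an area.
- Pixel coordinates are 0-based with the origin top-left and y downward;
  bounding boxes are half-open, so widths are `x1 - x0` with no ±1
  bookkeeping.
- Collinear or sub-3-point contours classify as non-quadrilateral rather
  than erroring; an empty mask yields an empty candidate list.
- Component labeling is 4-connected for mask contours (boxes are solid;
  connectivity cannot split them) but 8-connected for glyph segmentation,
  where dot-matrix diagonals touch only at corners.
- Percentages use half-up rounding (base R's `round()` is half-to-even),
  implemented in `round_half_up()`.
- `generate_corpus()` and `simulate_engagement()` restore the caller's RNG
  state; corpus generation is byte-reproducible from its arguments.
- Detection on a corpus is embarrassingly parallel but runs serially: at
  roughly 0.7 s per negative image (all four variants) and much less per
  positive (first variant usually confirms), a 200-image audit takes about
  three minutes, and determinism is worth more to an audit than wall time.

## Problem sizes used in the shipped checks

Detector corpus checks use a seeded 200-image corpus at 10% prevalence
(clean labels) for recall/specificity, and small 4–10 image corpora for
behavioural tests; model recovery uses 2000 posts × 20 replicates. These
sizes were chosen as the smallest at which the measured properties are
stable: recall and false positives are exact counts, and the recovery SE
at n = 2000 makes the ±3 SE criterion a real constraint rather than a
formality.

## Known limitations

- The template OCR backend is font-locked; real-image audits require the
  Tesseract backend and real-image validation.
- Non-rectangular, borderless, or rotated-beyond-tolerance warnings are out
  of scope by design, as are video frames.
- The placement rule is a convention (box center above half-height); other
  defensible readings of "upper portion" exist and would change
  placement-rule counts near the midline.
- The engagement model is associational. Nothing in a fitted IRR speaks to
  whether adding a warning *causes* lower engagement.
- Area is measured from the detected box. A detection that locks onto the
  inner border edge rather than the outer (possible under heavy blur)
  understates the label by the border width; the 80% overlap deduplication
  keeps the outer box whenever both survive the cascade.
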