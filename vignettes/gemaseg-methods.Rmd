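---
title: "Adaptive brightfield segmentation with gemaseg: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive brightfield segmentation with gemaseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gemaseg)
```

## The problem

Adherent cultures (the reference system is the MCF7 breast-cancer line in
a PDMS microfluidic chamber) are imaged in brightfield every few minutes.
The biological readout is one number per frame: the percent of image area
covered by cells. It rises toward confluence during growth and falls when
apoptosis is induced with camptothecin. Brightfield frames are hard to
threshold globally — cells are nearly transparent, their contrast changes
as the culture evolves, and any fixed parameter that works at one stage of
the experiment fails at another. `gemaseg` implements a texture-based
segmenter whose single free parameter is re-estimated online from the
images themselves, so a multi-day experiment can run unattended.

## The pipeline

Every frame passes through grayscale conversion `I = (R + G + B)/3`
(rounded half-up), CLAHE, and Gaussian smoothing. Both segmentation
engines share this preprocessing.

### Gabor texture response

The adaptive engine correlates the preprocessed frame with the real part
of four Gabor filters,

$$g(x, y) = \frac{f^2}{\pi\gamma\eta}
  \exp\!\left(-\frac{x'^2 f^2}{\gamma^2} - \frac{y'^2 f^2}{\eta^2}\right)
  \cos(2\pi f x'),$$

with $x' = x\cos\theta + y\sin\theta$, $y' = -x\sin\theta + y\cos\theta$,
evaluated at $\theta \in \{0°, 45°, 90°, 135°\}$ on a $21\times21$ grid,
with $f = 3$, $\gamma = 10$, $\eta = 0.5$. Two conventions are the
package's own choices, because the formula fixes neither:

* **Coordinate units.** The kernel grid spans $[-1, 1]^2$, so $f$ counts
  carrier cycles per kernel half-width (carrier wavelength about 3.3 px in
  a 21-px kernel). This reproduces the expected appearance of the kernels
  — a few visible lobes — and keeps $f$ dimensionless.
* **Orientation fusion.** The per-pixel maximum of absolute responses
  (config-switchable to the sum). The maximum preserves thin oriented
  structures that averaging would dilute.

Each kernel is mean-subtracted so a constant region yields zero response;
the fused response is rescaled to $[0, 255]$ by its per-frame maximum. A
response whose maximum is at numerical-roundoff scale (below $10^{-6}$) is
treated as identically zero rather than rescaled — rescaling would amplify
FFT dust to full range.

### CV-scheduled adaptive threshold

The controller observes the coefficient of variation
$\mathrm{CV} = \sigma/\mu$ of each preprocessed frame (population standard
deviation: the frame's pixels are the whole population of interest) and
maintains a linear model $Y = mX + b$ of CV against frame index. The
scheduled parameter is an integer offset $c \in [5, 11]$: a pixel is
foreground iff its response exceeds the Gaussian-weighted local mean of a
51-px window (window sd = block/6, reflective border) by more than $c$.
Confluent frames binarize best near $c = 5$, sparse or apoptotic frames
near $c = 11$; the model's CV prediction is clamped to the calibration
range observed so far and mapped linearly (rounded half-up) onto the
integer range, with the direction set by an explicit `mode` flag — both
confluence and deep apoptosis minimize the CV, so the direction cannot be
inferred from the CV value alone and is a user input.

Controller details that matter in practice:

* **Cold start.** Before a model exists, growth mode holds the threshold
  at 11 (a sparse culture resembles the apoptotic extreme) and apoptosis
  mode at 5 (it starts confluent). Additionally, the observed CV range
  only counts as calibration once its relative spread exceeds
  `min_calibration_spread` (default 0.1): two CV values that differ by
  noise would otherwise swing the schedule to an endpoint on the second
  frame.
* **Refit policy.** The model is evaluated out-of-sample: the mean
  absolute relative error over the points that arrived since it was last
  fitted, capped at the `min_refit_window` (default 5) most recent points.
  When that error exceeds `refit_tolerance` (default 0.05), the model is
  refitted on all points since the previous fit, extended to at least the
  window minimum. A noiseless linear CV series is therefore fitted once
  and never refitted, while a level shift triggers a refit within a frame
  or two; over a long experiment this produces the piecewise-linear
  regression segments the method is designed around. The 5% default is
  exposed in configuration (values up to 7% are sensible).

### Morphological cleanup and the baseline

The raw adaptive mask marks texture ridges; binary closing (5×5 square)
bridges the inter-ridge gaps and dilation (3×3 square) restores the
margin lost at cell borders. Both operations are extensive, so the raw
mask is always contained in the final one. The comparison baseline is the
morphological gradient — dilation minus erosion under a 5×5 square,
binarized at the fixed threshold 25 (strict inequality; ties to
background). It shares the preprocessing stage (disableable in
configuration).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| CLAHE clip limit | 2.0 | × mean bin count | canonical CLAHE default; caps noise amplification |
| CLAHE tile grid | 8 × 8 | tiles | canonical default |
| Gaussian sigma | 1.0 | px | suppresses pixel noise below the texture band |
| Gabor f, size, γ, η | 3.0, 21, 10, 0.5 | — / px | the method's published filter bank |
| adaptive block size | 51 | px | larger than a cell's local texture scale |
| threshold offset c | scheduled 5–11 | gray levels | the method's working range |
| closing / dilation SE | 5×5 / 3×3 | px | bridge texture gaps ≤ 4 px, restore a 1-px margin |
| refit tolerance | 0.05 | fraction | the method's stated working error |
| eval block | 100 | frames | gold standards are annotated every 100th frame |

All of these are settable through `run_config()` or a YAML config file
(sections named after the modules; YAML was chosen because a parser ships
with the environment and sectioned keys map cleanly onto the module
structure).

## The synthetic generator

`generate_sequence()` emulates the study conditions so that every stage is
testable without any external data: textured elliptical cells on a flat
background (level 100), coverage following a logistic ramp from 10% to
90% over 20 frames (reversed for apoptosis), Gaussian pixel noise
(sd 2), and exact ground-truth masks by construction. Three features are
deliberate emulations of real sequences:

* **Cells are brighter than the background** (+80). Hence the frame mean
  rises as the culture fills and the raw-frame CV falls from the sparse
  start to confluence — the qualitative CV-versus-time shape that the
  threshold scheduler relies on.
* **Cell size matches real magnification.** Default radii are 75–90 px in
  a 768×768 frame, so a cell spans many 21-px filter widths. An oriented
  filter smears any response about one kernel half-width (~10 px) beyond
  a texture boundary; with cells smaller than a few kernel widths this
  halo dominates the cell area and no threshold can separate it.
* **Texture contrast fades near confluence** (sigmoid in coverage,
  midpoint 0.7, floor 5%): contact-inhibited cells flatten and lose
  optical contrast. This is precisely the regime where a fixed gradient
  threshold of 25 stops detecting cells while the contrast-normalized
  adaptive engine keeps working, so the generator reproduces the
  qualitative ranking between the two engines. Intra-cell texture is a
  crossed pair of orthogonal sinusoids (wavelength 4–8 px) at a random
  orientation: a single sinusoid would make a cell nearly invisible
  whenever its orientation falls halfway between two bank orientations,
  which real granular intracellular texture does not do.

What the generator does **not** emulate: defocus and halo optics,
illumination gradients, debris, cell motility between frames, and
annotation noise (the masks are exact). Passing the in-package tests
therefore demonstrates the mechanics and the control loop under the
stated conditions, not performance on real microscopy; for that, the
`evaluate` subcommand can score the engines against VIA-annotated
external data such as the published MCF7 sequences.

Reference problem sizes (chosen as the package's study conditions): 20
frames of 768×768 px for end-to-end runs; 100 replicates of 200-point
noisy lines for regression recovery; brute-force oracle comparisons on
images up to 32×32.

## Numerical choices and degenerate inputs

* Strict inequality at both thresholds; ties go to background
  (determinism anchor).
* Rounding is always half-up (`floor(x + 0.5)`).
* All convolutions and rank filters use a reflective border, which for
  max/min filters coincides with clipping the window at the image edge.
* CLAHE is implemented in the package (tile histograms, clip and uniform
  redistribution of the excess, per-tile equalization LUT normalized by
  the minimum CDF, bilinear interpolation between tile centers). With one
  tile and a large clip limit it reduces exactly to global histogram
  equalization, and a constant image maps to a constant image within one
  gray level — properties the test suite relies on and that available
  library implementations do not guarantee (nor do they accept arbitrary
  image sizes).
* An all-zero frame has undefined CV; the frame is skipped with a warning
  and the controller state is unchanged.
* Both-empty masks score Dice 1.0 by convention (reported via a message).
* VIA files may use the project or the region-export dialect; rectangles
  become 4-gons, circles and ellipses 32-gons. Rasterization uses the
  pixel-center-inside rule with boundaries counted as foreground.
* 16-bit TIFFs are rescaled by the sample-type maximum, not the per-image
  maximum — per-image scaling would distort the CV series across frames.

## Known limitations

* The per-frame maximum rescale of the Gabor response makes a frame with
  **no** cells at all pathological: pure sensor noise is amplified to full
  range and largely survives thresholding. With any cells in the field,
  far-background false positives are below 2%. Runs that may include
  truly empty fields should gate on the CV or on the pre-rescale response
  energy before trusting `percent_cells`.
* The response halo of the 21-px kernels biases boundaries outward by a
  few pixels; on cells at the default scale this costs roughly 0.1–0.2
  Dice at sparse coverage and is the main error term of the adaptive
  engine on the synthetic fixture.
* `percent_cells` saturates slightly below the true coverage in deep
  confluence when texture contrast approaches the noise floor; the trend
  (and hence the correlation with true coverage) is preserved.
* The controller cannot distinguish growth from apoptosis on its own —
  the `mode` flag is a required user input.
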