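# gemaseg

Real-time segmentation of adherent cell cultures in time-lapse brightfield
microscopy, for experiments run in microfluidic (lab-on-a-chip) devices
where the quantity of interest is the percent of image area covered by
cells — rising toward **confluence** during growth, falling during
drug-induced **apoptosis**. The package is aimed at labs that image a
culture every few minutes and want a headless, parameter-free area readout
per frame, plus an evaluation harness against manually annotated gold
standards.

## The method

Each frame is converted to grayscale (`I = (R + G + B) / 3`), contrast-
normalized with CLAHE, and smoothed with a small Gaussian. The adaptive
engine then works in three stages:

1. **Texture response.** A bank of four Gabor filters — the real part of

   ```
   g(x, y) = f²/(π γ η) · exp(−x′² f²/γ² − y′² f²/η²) · cos(2π f x′)
   x′ =  x cos θ + y sin θ,   y′ = −x sin θ + y cos θ
   ```

   with `f = 3.0`, kernel size 21, `γ = 10`, `η = 0.5` and
   `θ ∈ {0°, 45°, 90°, 135°}` — is correlated with the frame. The
   orientation responses are fused pixel-wise by the maximum of their
   absolute values and rescaled to `[0, 255]`; cell texture yields the
   highest response.

2. **Online threshold scheduling.** The per-frame coefficient of variation
   `CV = σ/μ` of the preprocessed intensities is modeled against the frame
   index by a linear regression `Y = mX + b` that is refitted whenever its
   mean absolute relative prediction error on recent frames exceeds 5%.
   The predicted CV is mapped linearly onto an integer threshold parameter
   in `[5, 11]`: confluent frames binarize best near 5, apoptotic/sparse
   frames near 11.

3. **Adaptive binarization and cleanup.** A pixel is foreground iff its
   response exceeds the Gaussian-weighted local mean of its 51-px
   neighborhood by more than the scheduled integer. Binary closing (5×5)
   and dilation (3×3) connect the detected texture into solid cell
   regions. `percent_cells = 100 · A_cells / A_img` is reported per frame.

A fixed-threshold baseline (morphological gradient `δ_B(I) − ε_B(I)` with a
5×5 structuring element, binarized at 25) is included for comparison, and
masks can be scored against VIA polygon annotations with pixel accuracy
`(TP + TN)/n` and Dice `2TP/(2TP + FP + FN)`; polygon areas use the
shoelace formula.

A seeded synthetic generator produces growth and apoptosis sequences with
exact ground-truth masks (textured elliptical cells that brighten the
field as it fills and lose contrast as the monolayer packs), so the whole
pipeline is testable without downloading any imagery.

## Worked example

```r
library(gemaseg)

# 20-frame synthetic growth sequence (10% -> 90% coverage) with masks
run_generate(run_config(output_dir = "fixtures"))

# adaptive segmentation + evaluation against the exact ground truth
res <- run_offline(run_config(input_dir = "fixtures", output_dir = "out",
                              gold_dir = "fixtures", eval_block = 1))
res$trace
```

```
# A tibble: 20 × 5
   frame filename          cv threshold percent_cells
   <int> <chr>          <dbl>     <int>         <dbl>
 1     0 frame_0000.png 0.201        11          13.8
 2     1 frame_0001.png 0.201        11          14.7
 ...
 9     8 frame_0008.png 0.336        10          42.5
14    13 frame_0013.png 0.235         7          70.6
20    19 frame_0019.png 0.149         5          72.6
```

The trace shows the controller at work: the CV climbs while isolated
bright cells fill the frame, then falls as the monolayer closes, and the
scheduled threshold follows it from 11 (sparse) down to 5 (confluent).
`percent_cells` tracks the true coverage (Pearson r = 0.99 on this
sequence). The evaluation summary for the same run prints

```
mean accuracy 0.841, mean Dice 0.825 over 20 frames
```

Masks are written as `{0,255}` PNGs under `out/masks/`, the trace to
`out/trace.csv`, and the per-frame scores to `out/evaluation.csv` with a
`mean` summary row. `ggplot2::autoplot()` on the trace or the evaluation
gives the corresponding time-course figures.

A thin command-line front end with the same capabilities ships at
`inst/cli/gema.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/gema.R", package = "gemaseg"))')" \
    segment --input-dir fixtures --output-dir out --engine gema --mode growth
```

Subcommands: `segment` (offline batch), `watch` (online polling of a
growing directory, crash-safe and resumable), `generate` (synthetic
fixtures), `evaluate` (score written masks against a gold directory), and
`dump-config` (print the full YAML configuration with defaults).

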