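# hemochroma

Image-based hematology for point-of-care hemolysis monitoring during
mechanical circulatory support (ECMO, VADs, cardiopulmonary bypass).

From one 8-bit RGB photograph of a centrifuged blood micro-channel,
`hemochroma` measures:

* **Plasma free hemoglobin (PFHb, mg/dL)** — hemolysis turns plasma from
  straw-yellow toward red. The plasma color is summarized in CIELab and
  compared to a black reference marker via the chroma difference
  `ΔC = √((a_m − a_s)² + (b_m − b_s)²)`, corrected for illumination drift
  by a marker-lightness offset and mapped through a two-segment standard
  curve fitted on a dilution-series calibration.
* **Hematocrit (Hct, %)** — from the packed-column geometry:
  `Hct = 100 · L1 / L2`, where `L1` is the packed red-cell column height
  and `L2` the total blood column height in pixels.
* **Hemoglobin (Hb, g/dL)** — `Hb = Hct / 3` (the standard three-to-one
  rule), plus a four-stage hemolysis classification
  (Normal < 30, Mild 30–50, Moderate 50–70, Critical ≥ 70 mg/dL) and an
  anemia flag (Hct < 30% and Hb < 12 g/dL).

Because the physical device (centrifuge, cartridge, camera) is not
required, the package ships a synthetic cartridge-image simulator with
per-pixel ground-truth labels, so the whole pipeline — segmentation,
colorimetry, calibration, quantification — is testable end to end. The
method-comparison statistics used to validate such devices (OLS
regression with Pearson R, Bland–Altman bias and 95% limits of agreement,
replicate precision with CV%) are included and work on any paired table.

## Worked example

Calibrate a synthetic device on a dilution series (a 1,000 mg/dL
hemolysate stock diluted 1:10 … 1:100 plus a blank), then analyze a fresh
sample with true PFHb 55 mg/dL and Hct 35%:

```r
library(hemochroma)

model <- calibrate_synthetic(seed = 42)
model
#> <pfhb_calibration> two-segment standard curve
#>   breakpoint: 18.27 chroma units (ties -> low segment)
#>   low  segment: pfhb = -18.19 + 2.077 * dC'  (R2 0.9984, resid SD 0.318, n 4)
#>   high segment: pfhb = -27.49 + 2.469 * dC'  (R2 0.9967, resid SD 2.06, n 5)
#>   LOD: 0.505 mg/dL (k = 3.3); L_ref_marker: 3.837; sRGB/D65/2deg

scene <- render_channel(scene_spec(true_pfhb = 55, true_hct = 35, rng_seed = 7))
analyze_image(scene$image, model)[, c("pfhb", "hct", "hb", "hemolysis_stage", "anemia")]
#>       pfhb hct       hb hemolysis_stage anemia
#> 1 56.67318  35 11.66667        Moderate  FALSE
```

Both calibration segments fit with R² > 0.99; the sample reads back at
56.7 mg/dL (true 55 — within the ~2 mg/dL working accuracy of the
two-segment curve), Hct is recovered exactly at 35% (its error is floored
only by one-pixel quantization, 0.1% here), Hb = 35/3 ≈ 11.67 g/dL, and
the 50–70 mg/dL level is staged Moderate.

Method-comparison statistics work on any paired reference/device table:

```r
pairs <- data.frame(
  reference = c(9.6, 10.1, 12, 11.2, 10.7, 10.1, 10.8, 8, 9.5, 9.1, 9.2, 9.6),
  device    = c(9.2, 9.2, 11.8, 11.6, 11.8, 9.9, 9.9, 9.2, 10.4, 10, 9.1, 10.3)
)
regression_and_r(pairs)
#>   slope intercept pearson_r     n
#> 1 0.710      3.11     0.741    12
bland_altman(pairs)
#>    bias loa_low loa_high sd_diff     n
#> 1 0.208   -1.27     1.69   0.755    12
precision_summary(c(51.9, 53.1, 54.2))
#>    mean    sd cv_percent     n
#> 1  53.1  1.15       2.17     3
```

`autoplot(model)`, `plot_bland_altman(pairs)` and
`plot_channel(scene$image)` produce the corresponding ggplot figures, and
`tidy()`/`glance()` give broom-style summaries of fitted curves. A thin
command-line front end (`inst/cli/hemochroma.R`) exposes
`simulate`, `calibrate`, `analyze` and `validate` subcommands over PNG
images and CSV tables.

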