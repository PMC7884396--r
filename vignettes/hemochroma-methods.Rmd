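---
title: "Colorimetric blood analysis from centrifuged channel images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric blood analysis from centrifuged channel images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemochroma)
```

## The measurement problem

Patients on mechanical circulatory support (ECMO, ventricular assist
devices, cardiopulmonary bypass) need frequent monitoring of plasma free
hemoglobin (PFHb) — the marker of pump-induced hemolysis — together with
hematocrit (Hct) and hemoglobin (Hb). Laboratory assays are accurate but
slow and, for Hb, involve toxic cyanide reagents. A point-of-care
alternative centrifuges ~35 µL of blood in a transparent micro-channel and
reads all three quantities from a single RGB photograph:

* **PFHb** from the *color* of the plasma band: lysed-cell hemoglobin turns
  plasma from straw-yellow toward red, and the redness is quantified as a
  CIELab chroma difference between the plasma and a black reference marker
  printed on the cartridge.
* **Hct** from the *geometry* of the packed column: the ratio of the packed
  red-cell column height `L1` to the total blood column height `L2`,
  `Hct (%) = 100 · L1 / L2`.
* **Hb** from Hct via the standard three-to-one rule `Hct = 3 · Hb`.

This package implements the full analysis chain — segmentation,
colorimetry, calibration, quantification, and the method-comparison
statistics used to validate such a device — plus a synthetic image
simulator that stands in for the hardware so every stage can be tested
against known ground truth.

## The analysis pipeline

`analyze_image()` runs, in order:

1. **Segmentation** (`segment_regions()`). Each pixel inside the channel is
   classified by two simple color statistics: Rec. 709 luminance
   `Y = 0.2126 R + 0.7152 G + 0.0722 B` and red dominance
   `d = R − (G+B)/2`. A row belongs to the black marker when its mean
   luminance is below 35; a pixel is packed red cells when `d ≥ 40` *and*
   `Y < 90`; bright, red-neutral pixels (`Y > 150`, `d < 8`) are white
   backing; everything else in the channel is plasma. Row-wise majority
   vote followed by the longest contiguous run per label yields the three
   bands — a centrifuged column is contiguous, so runs, not isolated rows,
   carry the signal.

   The luminance ceiling for packed cells deserves a note: at high PFHb the
   *plasma* is more red-dominant (d ≈ 130 at 100 mg/dL) than the dark
   packed-cell column (d ≈ 92), so red dominance alone cannot separate
   them. Luminance can: packed cells sit near Y ≈ 41–50 across a ±10%
   illumination band while plasma stays above ~130, and the default
   ceiling of 90 sits in the middle of that gap.

2. **Second ROI** (`select_second_roi()`). A fixed 20 × 100 px rectangle
   (20 across the channel, 100 along it), centered in the plasma band by
   floor-division offsets. Centering keeps the readout away from both the
   marker boundary and the packed-cell interface.

3. **Colorimetry** (`rgb_to_lab()`, `roi_mean_lab()`,
   `chroma_difference()`, `corrected_chroma()`). Pixels are converted from
   8-bit sRGB (IEC gamma, D65 white, 2° observer) to CIELab; L*, a*, b*
   are averaged over the ROI; and the chroma difference between marker (m)
   and plasma (s) is

   ΔC = √((a_m − a_s)² + (b_m − b_s)²).

   To compensate illumination drift between calibration and sample
   acquisition, the difference between the marker lightness recorded with
   the calibration images and the marker lightness of the sample image is
   *added* to ΔC (in chroma units, exactly as the device defines it — no
   rescaling), giving the corrected ΔC′. Brighter illumination inflates
   both the chroma distance and the marker's L*, so the signed L*
   difference moves predictions back toward the calibration conditions.
   sRGB/D65/2° is fixed by design and recorded in every persisted
   calibration so the two sides of the assay can never disagree about the
   color space.

4. **Calibration** (`fit_calibration()`, `pfhb_from_chroma()`). The
   ΔC′ → PFHb relationship changes regime around 20 mg/dL, so the standard
   curve is two independent OLS lines split at a breakpoint, each with its
   own R², residual SD and point count; ties at the breakpoint go to the
   low segment. Prediction clamps negatives to zero and flags values
   outside the validated 0–100 mg/dL range as extrapolated. The limit of
   detection is the blank-free regression estimate
   `LOD = 3.3 · residual SD / |slope|` on the low segment (the constant is
   configurable; 3.0 is the common alternative).

   Straight lines per segment are a deliberate choice: the published
   curves for this class of device report R² > 0.98 per side, consistent
   with local linearity, and a two-parameter line per side is the most
   that nine calibration points can robustly support. A quadratic option
   exists but is off by default.

5. **Quantification** (`hematocrit()`, `hb_from_hct()`,
   `classify_hemolysis()`, `classify_anemia()`). `L1` is the packed-band
   height; `L2` runs from the first plasma row to the last packed-cell row
   inclusive. Hemolysis stages follow the ECMO guideline thresholds —
   Normal < 30, Mild [30, 50), Moderate [50, 70), Critical ≥ 70 mg/dL.
   The printed ranges overlap at their endpoints, so a convention is
   required: each boundary goes to the higher stage. Anemia is flagged when
   Hct < 30% *and* Hb < 12 g/dL, boundaries excluded. (A looser "mild
   hemolysis" range of 15–60 mg/dL circulates in the clinical literature;
   the four-stage rule above is the one implemented.) Results are emitted
   unrounded; display rounding is left to the caller.

## The synthetic cartridge simulator

`render_channel()` draws the scene the camera would capture: white acrylic
backing; inside the channel columns, top to bottom, a black marker band
(RGB 15,15,15), a plasma band, and a packed-cell band (dark red 120,25,30)
occupying `round(Hct/100 × blood_rows)` rows at the bottom (round half away
from zero — Hct therefore carries a one-pixel quantization floor of
`100/blood_rows`, ≈ 0.1% at the default 1,000-row column). Plasma color is
a per-channel Beer–Lambert attenuation of a straw-yellow base:

intensity_c = base_c · exp(−ε_c · PFHb),  base = (250, 235, 220),
ε = (0.0005, 0.006, 0.009) per mg/dL.

Hemoglobin absorbs red least, so ε_R < ε_G ≤ ε_B keeps the red channel
dominant while green and blue fall — the qualitative behavior the real
plasma shows. Global illumination multiplies all channels; i.i.d. Gaussian
noise (default SD 2, 8-bit units) is added per pixel and channel; values
are clipped to [0, 255] and quantized. Rendering is bit-deterministic in
the scene specification, including its seed.

Defaults and why:

* **Geometry**: 1120 × 60 px, channel columns [15, 45), marker rows
  [0, 120), blood rows [120, 1120). The spans tile the image height, as in
  a filled channel; 1,000 blood rows make the Hct quantization floor 0.1%.
  The camera's pixel pitch is not asserted — all spans are free parameters.
* **Illumination scale 0.9**: a camera exposed with ~10% headroom. The
  plasma base color is nearly white, and a unit default would saturate the
  red channel under +10% illumination drift — a properly exposed sensor
  does not clip its brightest scene element, and without headroom the
  offset-correction behavior could not even be exercised.
* **Noise SD 2**: small sensor noise, configurable for detection-limit
  experiments.

What the simulator deliberately does *not* model: optics (lens distortion,
vignetting, spectral response), incomplete centrifugation (buffy coat),
rotation/misalignment (the physical holder fixes alignment), and any
physical radiometry — the Beer–Lambert model is a monotone stand-in chosen
to reproduce the qualitative channel ordering, not a spectral simulation.
Passing recovery tests therefore demonstrate that the *pipeline* inverts
the simulator's forward model through real segmentation and colorimetry;
they do not certify accuracy on real cartridge photographs.

## The breakpoint coordinate

The physical device's published standard curves split at ΔC′ = −3, a value
in *its* corrected-chroma coordinate, which the device documentation ties
to PFHb ≈ 20 mg/dL. In this package's pipeline ΔC is a Euclidean norm
(non-negative) and the brightness offset averages zero when calibration and
sample images share illumination, so corrected values here are
non-negative: the synthetic device has its own coordinate, in which the
20 mg/dL regime change falls near ΔC′ ≈ 18.3. `synthetic_breakpoint()`
computes that value at run time by rendering a noise-free 20 mg/dL scene
and measuring it; `calibrate_synthetic()` uses it as the split.
`fit_calibration()` keeps −3 as its default for tables recorded in the
physical device's coordinate. The negative published axis is readable as an
offset-corrected scale relative to a brighter factory reference; we record
this interpretation without asserting it.

## Numerical choices and degenerate inputs

* Quantization throughout is round-half-away-from-zero; 8-bit clipping is
  applied after illumination and noise.
* Each calibration segment requires ≥ 3 points and nonzero chroma
  variance; violations raise classed errors
  (`hemochroma_insufficient_calibration`, `hemochroma_degenerate_calibration`)
  rather than silently fitting.
* Missing bands raise `hemochroma_no_packed_cells` / `hemochroma_no_plasma`
  / `hemochroma_no_marker`, each marking an unusable capture;
  `analyze_image()` re-signals them with the failing stage attached.
* Band-run ties break toward the top for marker/plasma and toward the
  bottom for packed cells, matching the physical layout.
* Lab values are averaged arithmetically (no trimming by default).
* Pearson correlation and OLS use the standard closed forms via `cor()`
  and `lm()`; Bland–Altman limits use the sample (n−1) SD — conventional
  for the three-replicate precision tables such devices report — and are
  implemented as limits of agreement, bias ± 1.96 SD, the standard reading
  of the bands on such plots.

## Known limitations

* **Recovery accuracy floor.** The PFHb ↔ ΔC′ response of the Beer–Lambert
  → CIELab chain is smooth but convex, and two straight segments leave an
  interpolation/extrapolation error of roughly 1 mg/dL on a noise-free
  5-point grid over 15–80 mg/dL (largest where the high segment
  extrapolates below its lowest calibration level at 33 mg/dL); 8-bit
  quantization contributes a further ~0.3 mg/dL. Default-noise recovery is
  comfortably within 2 mg/dL MAE, but noise-free recovery does not reach
  0.1 mg/dL — the curve family, not the noise, is the binding constraint.
* Hct accuracy is floored by the one-pixel quantization of the packed
  column; at 1,000 blood rows this is 0.1%.
* The simulator's study sizes are deliberately desk-scale: a 9-level
  calibration (a 1,000 mg/dL stock diluted 1:10 … 1:100, plus a blank),
  5-point PFHb recovery grids, 4-point Hct grids, and 5 × 2 illumination
  robustness grids.
* Published device-vs-laboratory statistics (regression R, Bland–Altman
  bias, LOD, precision means) depend on the physical instrument and raw
  images that are not public; the package reproduces the *statistics* on
  printed tables and validates the *pipeline* on synthetic ground truth,
  which is the strongest check available without hardware.
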