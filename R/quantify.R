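#' Hematocrit from packed-column geometry
#'
#' The centrifuged channel packs red cells into a column of height `L1`
#' inside a total blood column of height `L2`; hematocrit is their ratio:
#' `Hct (%) = 100 * L1 / L2`.
#'
#' @param L1 Packed-cell column height in pixels (or a one-row data frame
#'   with columns `L1` and `L2`, as returned by
#'   [measure_column_lengths()]).
#' @param L2 Total blood column height in pixels; `L2 > 0`, `0 <= L1 <= L2`.
#' @return Hematocrit in percent.
#' @examples
#' hematocrit(300, 1000) # 30
#' @export
hematocrit <- function(L1, L2 = NULL) {
  if (is.data.frame(L1)) {
    L2 <- L1$L2
    L1 <- L1$L1
  }
  if (any(L2 <= 0)) stop_hemochroma("L2 must be positive", "domain")
  if (any(L1 < 0) || any(L1 > L2)) {
    stop_hemochroma("L1 must satisfy 0 <= L1 <= L2", "domain")
  }
  100 * L1 / L2
}

#' Hemoglobin estimated from hematocrit
#'
#' Uses the standard three-to-one rule `Hct (%) = 3 * Hb (g/dL)`, i.e.
#' `Hb = Hct / 3`.
#'
#' @param hct Hematocrit in percent, >= 0.
#' @return Hemoglobin in g/dL.
#' @examples
#' hb_from_hct(30) # 10
#' @export
hb_from_hct <- function(hct) {
  if (any(hct < 0)) stop_hemochroma("hct must be non-negative", "domain")
  hct / 3
}

#' Hemolysis stage from plasma free hemoglobin
#'
#' Four-stage rule used for ECMO patients: Normal below 30 mg/dL, Mild in
#' \[30, 50), Moderate in \[50, 70), Critical at 70 and above. Each printed
#' boundary is assigned to the higher stage.
#'
#' @param pfhb PFHb in mg/dL, >= 0.
#' @return Factor with levels Normal, Mild, Moderate, Critical.
#' @examples
#' classify_hemolysis(c(25, 53, 70))
#' @export
classify_hemolysis <- function(pfhb) {
  if (any(pfhb < 0)) stop_hemochroma("pfhb must be non-negative", "domain")
  cut(pfhb,
    breaks = c(-Inf, 30, 50, 70, Inf),
    labels = c("Normal", "Mild", "Moderate", "Critical"),
    right = FALSE
  )
}

#' Anemia flag from hematocrit and hemoglobin
#'
#' Flags anemia when both hematocrit is below 30% and hemoglobin is below
#' 12 g/dL (boundaries excluded).
#'
#' @param hct Hematocrit in percent.
#' @param hb Hemoglobin in g/dL.
#' @return Logical vector.
#' @examples
#' classify_anemia(29, 9.7) # TRUE
#' classify_anemia(30, 10)  # FALSE: boundary excluded
#' @export
classify_anemia <- function(hct, hb) {
  if (any(hct < 0) || any(hb < 0)) {
    stop_hemochroma("hct and hb must be non-negative", "domain")
  }
  hct < 30 & hb < 12
}

#' Analyze one channel image end to end
#'
#' Runs the full pipeline on a captured (or simulated) image: segmentation
#' into marker/plasma/packed-cell bands, colorimetry of the second ROI with
#' brightness-offset correction against the model's reference marker
#' lightness, PFHb from the standard curve, hematocrit from the column
#' lengths, hemoglobin from hematocrit, and the hemolysis stage and anemia
#' flag. Deterministic given its inputs. Segmentation failures surface as
#' classed errors carrying the failing stage.
#'
#' @param image A [channel_image()].
#' @param model A fitted [fit_calibration()] model.
#' @param config Segmentation thresholds, see [seg_config()].
#' @return A one-row tibble: `pfhb`, `hct`, `hb`, `hemolysis_stage`,
#'   `anemia`, `clamped`, `extrapolated`, `delta_c_raw`,
#'   `delta_c_corrected`, `L1`, `L2`, `source_id`. `hb` equals `hct / 3`
#'   exactly; values are unrounded (display rounding is the caller's
#'   choice).
#' @export
analyze_image <- function(image, model, config = seg_config()) {
  if (!inherits(model, "pfhb_calibration")) {
    stop_hemochroma("model must be a fitted pfhb_calibration", "state")
  }
  labels <- withCallingHandlers(
    segment_regions(image, config),
    hemochroma_error = function(e) {
      e$stage <- "segmentation"
      stop(e)
    }
  )
  chroma <- measure_chroma(image, labels,
    L_ref_marker = if (is.na(model$L_ref_marker)) NULL else model$L_ref_marker,
    config = config
  )
  pred <- pfhb_from_chroma(model, chroma$delta_c_corrected)
  lengths <- measure_column_lengths(labels)
  hct <- hematocrit(lengths)
  hb <- hb_from_hct(hct)
  tibble::tibble(
    pfhb = pred$pfhb,
    hct = hct,
    hb = hb,
    hemolysis_stage = classify_hemolysis(pred$pfhb),
    anemia = classify_anemia(hct, hb),
    clamped = pred$clamped,
    extrapolated = pred$extrapolated,
    delta_c_raw = chroma$delta_c_raw,
    delta_c_corrected = chroma$delta_c_corrected,
    L1 = lengths$L1,
    L2 = lengths$L2,
    source_id = if (inherits(image, "channel_image")) image$source_id else "array"
  )
}

#' Analyze a batch of channel images
#'
#' @param images A list of [channel_image()] objects (or paths readable by
#'   [read_channel_image()]).
#' @param model A fitted [fit_calibration()] model.
#' @param config Segmentation thresholds.
#' @return A tibble with one row per image, as in [analyze_image()].
#' @export
analyze_batch <- function(images, model, config = seg_config()) {
  purrr::map_dfr(images, function(img) {
    if (is.character(img)) img <- read_channel_image(img)
    analyze_image(img, model, config)
  })
}
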