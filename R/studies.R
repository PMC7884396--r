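#' Chroma breakpoint of the synthetic device
#'
#' The standard curve changes regime at the chroma difference produced by a
#' 20 mg/dL sample. For the physical device that value is -3 in its own
#' corrected-chroma coordinate; the simulator has its own coordinate, so
#' synthetic studies compute the breakpoint by rendering a noise-free
#' 20 mg/dL scene under the given conditions and measuring its raw chroma
#' difference (the brightness offset is zero against its own marker).
#' Deterministic.
#'
#' @param pfhb PFHb level defining the regime change, mg/dL.
#' @param hct Hematocrit of the rendered scene, percent.
#' @param illumination_scale Illumination of the rendered scene.
#' @param config Segmentation thresholds.
#' @return Chroma difference (chroma units) at the regime change.
#' @export
synthetic_breakpoint <- function(pfhb = 20, hct = 40, illumination_scale = 0.9,
                                 config = seg_config()) {
  scene <- render_channel(scene_spec(
    true_pfhb = pfhb, true_hct = hct,
    illumination_scale = illumination_scale, noise_sd = 0
  ))
  measure_chroma(scene$image, config = config)$delta_c_raw
}

#' Simulate a dilution-series calibration run
#'
#' Renders one synthetic cartridge image per calibration level (a stock
#' dilution series plus a blank by default), runs segmentation and
#' colorimetry on each, and assembles the calibration table: per-image raw
#' chroma difference and marker lightness, offset-corrected against the mean
#' marker lightness of the run.
#'
#' @param levels PFHb levels to image, mg/dL. Default: 1,000 mg/dL stock
#'   diluted 1:10, 1:15, 1:20, 1:30, 1:50, 1:65, 1:85, 1:100, plus a blank
#'   at 0.
#' @param hct Hematocrit of the rendered scenes (calibration plasma is
#'   imaged in a channel loaded like a normal sample).
#' @param noise_sd,illumination_scale Acquisition conditions passed to
#'   [scene_spec()].
#' @param seed Integer; per-image seeds are derived from it.
#' @param config Segmentation thresholds.
#' @return A tibble with one row per level: `reference_pfhb`,
#'   `delta_c_raw`, `marker_L`, `delta_c_corrected`; the run's mean marker
#'   lightness is attached as attribute `L_ref_marker`.
#' @export
simulate_calibration_run <- function(levels = c(0, dilution_series(1000)$pfhb),
                                     hct = 40, noise_sd = 2,
                                     illumination_scale = 0.9,
                                     seed = 1L, config = seg_config()) {
  rows <- purrr::imap_dfr(levels, function(pfhb, i) {
    scene <- render_channel(scene_spec(
      true_pfhb = pfhb, true_hct = hct,
      illumination_scale = illumination_scale, noise_sd = noise_sd,
      rng_seed = seed + i
    ))
    m <- measure_chroma(scene$image, config = config)
    tibble::tibble(
      reference_pfhb = pfhb,
      delta_c_raw = m$delta_c_raw,
      marker_L = m$marker_L
    )
  })
  L_ref <- mean(rows$marker_L)
  rows$delta_c_corrected <- rows$delta_c_raw + (L_ref - rows$marker_L)
  attr(rows, "L_ref_marker") <- L_ref
  rows
}

#' Calibrate the synthetic device
#'
#' Convenience wrapper: [simulate_calibration_run()] followed by
#' [fit_calibration()] at the synthetic breakpoint.
#'
#' @inheritParams simulate_calibration_run
#' @param breakpoint Chroma split; defaults to [synthetic_breakpoint()]
#'   under the same illumination.
#' @return A `pfhb_calibration` with the calibration table attached as
#'   attribute `points`.
#' @export
calibrate_synthetic <- function(levels = c(0, dilution_series(1000)$pfhb),
                                hct = 40, noise_sd = 2,
                                illumination_scale = 0.9, seed = 1L,
                                breakpoint = NULL, config = seg_config()) {
  if (is.null(breakpoint)) {
    breakpoint <- synthetic_breakpoint(
      illumination_scale = illumination_scale, config = config
    )
  }
  pts <- simulate_calibration_run(
    levels = levels, hct = hct, noise_sd = noise_sd,
    illumination_scale = illumination_scale, seed = seed, config = config
  )
  model <- fit_calibration(
    data.frame(
      delta_c_corrected = pts$delta_c_corrected,
      reference_pfhb = pts$reference_pfhb
    ),
    breakpoint = breakpoint,
    L_ref_marker = attr(pts, "L_ref_marker")
  )
  attr(model, "points") <- pts
  model
}

#' Parameter-recovery experiment on fresh synthetic samples
#'
#' Renders fresh images at the requested true PFHb/Hct values, analyzes
#' them with a fitted model, and tabulates recovered against true values --
#' the simulator's ground truth acting as the reference method.
#'
#' @param model A fitted `pfhb_calibration`.
#' @param pfhb,hct Vectors of true values; recycled to a common length.
#' @param noise_sd,illumination_scale Acquisition conditions.
#' @param seed Integer; per-image seeds are derived from it.
#' @param config Segmentation thresholds.
#' @return A tibble: `true_pfhb`, `true_hct`, `pfhb`, `hct`, `hb`,
#'   `pfhb_error`, `hct_error`.
#' @export
recover_samples <- function(model, pfhb, hct = 40, noise_sd = 2,
                            illumination_scale = 0.9, seed = 100L,
                            config = seg_config()) {
  n <- max(length(pfhb), length(hct))
  pfhb <- rep_len(pfhb, n)
  hct <- rep_len(hct, n)
  purrr::map_dfr(seq_len(n), function(i) {
    scene <- render_channel(scene_spec(
      true_pfhb = pfhb[i], true_hct = hct[i],
      illumination_scale = illumination_scale, noise_sd = noise_sd,
      rng_seed = seed + i
    ))
    res <- analyze_image(scene$image, model, config)
    tibble::tibble(
      true_pfhb = pfhb[i], true_hct = hct[i],
      pfhb = res$pfhb, hct = res$hct, hb = res$hb,
      pfhb_error = res$pfhb - true_pfhb,
      hct_error = res$hct - true_hct
    )
  })
}
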