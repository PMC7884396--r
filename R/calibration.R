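#' Fit the two-segment standard curve mapping chroma to PFHb
#'
#' The colorimetric response of plasma changes regime around a PFHb of
#' ~20 mg/dL, so the standard curve is fitted as two independent ordinary
#' least-squares lines of reference PFHb on corrected chroma difference:
#' points with `delta_c_corrected <= breakpoint` form the low segment,
#' points above it the high segment (ties go to the low segment). Each
#' segment stores its slope, intercept, R squared, residual SD and point
#' count; the limit of detection is computed from the low segment with
#' [compute_lod()].
#'
#' @param points Data frame with columns `delta_c_corrected` (chroma units)
#'   and `reference_pfhb` (mg/dL, non-negative), one row per calibration
#'   image.
#' @param breakpoint Chroma value splitting the two segments. The physical
#'   device's published coordinate places it at -3; synthetic studies use
#'   the chroma of a 20 mg/dL scene, see [synthetic_breakpoint()].
#' @param L_ref_marker Mean marker L* over the calibration images; stored so
#'   that later sample analyses are offset-corrected onto the calibration's
#'   illumination. May be `NA` for curves fitted on pre-corrected tables.
#' @param lod_k Multiplier for the limit of detection (3.3 for LOD; 3.0 is
#'   the common alternative).
#' @param validated_range PFHb interval over which the assay was validated;
#'   predictions outside it are flagged as extrapolated.
#' @return An object of class `pfhb_calibration` with elements `breakpoint`,
#'   `low_segment`, `high_segment` (each slope/intercept/r_squared/
#'   residual_sd/n_points), `L_ref_marker`, `conversion_standard`, `lod`,
#'   `lod_k`, `validated_range`.
#' @section Errors: `hemochroma_insufficient_calibration` with fewer than 3
#'   points on either side; `hemochroma_degenerate_calibration` when a side
#'   has no chroma variance.
#' @examples
#' pts <- data.frame(
#'   delta_c_corrected = c(-8, -6, -4, -2, 0, 2),
#'   reference_pfhb = c(2, 6, 10, 26, 38, 50)
#' )
#' fit_calibration(pts, breakpoint = -3)
#' @export
fit_calibration <- function(points, breakpoint = -3, L_ref_marker = NA_real_,
                            lod_k = 3.3, validated_range = c(0, 100)) {
  if (!is.data.frame(points) ||
      !all(c("delta_c_corrected", "reference_pfhb") %in% names(points))) {
    stop_hemochroma(
      "points must have columns delta_c_corrected and reference_pfhb",
      "domain"
    )
  }
  if (any(points$reference_pfhb < 0)) {
    stop_hemochroma("reference PFHb values must be non-negative", "domain")
  }
  low <- points[points$delta_c_corrected <= breakpoint, , drop = FALSE]
  high <- points[points$delta_c_corrected > breakpoint, , drop = FALSE]
  model <- structure(
    list(
      breakpoint = breakpoint,
      low_segment = fit_segment(low, "low"),
      high_segment = fit_segment(high, "high"),
      L_ref_marker = L_ref_marker,
      conversion_standard = "sRGB/D65/2deg",
      lod_k = lod_k,
      validated_range = validated_range
    ),
    class = "pfhb_calibration"
  )
  model$lod <- compute_lod(model$low_segment, k = lod_k)
  model
}

fit_segment <- function(pts, side) {
  if (nrow(pts) < 3) {
    stop_hemochroma(
      sprintf("need at least 3 calibration points on the %s side of the breakpoint (got %d)",
              side, nrow(pts)),
      "insufficient_calibration"
    )
  }
  if (stats::var(pts$delta_c_corrected) == 0) {
    stop_hemochroma(
      sprintf("zero chroma variance on the %s side", side),
      "degenerate_calibration"
    )
  }
  fit <- stats::lm(reference_pfhb ~ delta_c_corrected, data = pts)
  # summary() warns on exact fits; noiseless calibrations are legitimate here
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    n_points = nrow(pts)
  )
}

#' Limit of detection from a calibration segment
#'
#' Blank-free estimate from the regression: `LOD = k * residual_sd /
#' |slope|`, with `k = 3.3` by convention.
#'
#' @param segment A fitted segment (list with `slope` and `residual_sd`), or
#'   a `pfhb_calibration` (its low segment is used).
#' @param k LOD multiplier.
#' @return LOD in mg/dL.
#' @examples
#' compute_lod(list(slope = 2, residual_sd = 0.5)) # 0.825
#' @export
compute_lod <- function(segment, k = 3.3) {
  if (inherits(segment, "pfhb_calibration")) segment <- segment$low_segment
  if (!is_number(segment$slope) || segment$slope == 0) {
    stop_hemochroma("cannot compute LOD from a zero-slope segment", "degenerate_calibration")
  }
  k * segment$residual_sd / abs(segment$slope)
}

#' Predict PFHb from corrected chroma differences
#'
#' Picks the segment by comparing each chroma value to the breakpoint
#' (values at or below it use the low segment), evaluates the segment's
#' line, clamps negative predictions to zero, and flags predictions outside
#' the validated PFHb range as extrapolated.
#'
#' @param model A [fit_calibration()] result.
#' @param delta_c_corrected Numeric vector of corrected chroma differences.
#' @return A tibble with columns `delta_c_corrected`, `pfhb`, `segment`
#'   ("low"/"high"), `clamped`, `extrapolated`.
#' @export
pfhb_from_chroma <- function(model, delta_c_corrected) {
  if (!inherits(model, "pfhb_calibration")) {
    stop_hemochroma("model must be a fitted pfhb_calibration", "state")
  }
  low <- delta_c_corrected <= model$breakpoint
  raw <- ifelse(low,
    model$low_segment$intercept + model$low_segment$slope * delta_c_corrected,
    model$high_segment$intercept + model$high_segment$slope * delta_c_corrected
  )
  clamped <- raw < 0
  pfhb <- pmax(0, raw)
  tibble::tibble(
    delta_c_corrected = delta_c_corrected,
    pfhb = pfhb,
    segment = ifelse(low, "low", "high"),
    clamped = clamped,
    extrapolated = pfhb < model$validated_range[1] | pfhb > model$validated_range[2]
  )
}

#' @export
print.pfhb_calibration <- function(x, ...) {
  cat("<pfhb_calibration> two-segment standard curve\n")
  cat(sprintf("  breakpoint: %.4g chroma units (ties -> low segment)\n", x$breakpoint))
  seg <- function(s, name) {
    cat(sprintf(
      "  %s segment: pfhb = %.4g + %.4g * dC'  (R2 %.4f, resid SD %.3g, n %d)\n",
      name, s$intercept, s$slope, s$r_squared, s$residual_sd, s$n_points
    ))
  }
  seg(x$low_segment, "low ")
  seg(x$high_segment, "high")
  cat(sprintf("  LOD: %.3g mg/dL (k = %.2g); L_ref_marker: %.4g; %s\n",
              x$lod, x$lod_k, x$L_ref_marker, x$conversion_standard))
  invisible(x)
}

#' Tidy a fitted standard curve
#'
#' `tidy()` returns one row per segment and term (broom convention);
#' `glance()` returns a one-row model summary.
#'
#' @param x A `pfhb_calibration`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pfhb_calibration <- function(x, ...) {
  seg_rows <- function(s, name) {
    tibble::tibble(
      segment = name,
      term = c("(Intercept)", "delta_c_corrected"),
      estimate = c(s$intercept, s$slope)
    )
  }
  dplyr::bind_rows(seg_rows(x$low_segment, "low"), seg_rows(x$high_segment, "high"))
}

#' @rdname tidy.pfhb_calibration
#' @export
glance.pfhb_calibration <- function(x, ...) {
  tibble::tibble(
    breakpoint = x$breakpoint,
    r_squared_low = x$low_segment$r_squared,
    r_squared_high = x$high_segment$r_squared,
    residual_sd_low = x$low_segment$residual_sd,
    residual_sd_high = x$high_segment$residual_sd,
    lod = x$lod,
    n_low = x$low_segment$n_points,
    n_high = x$high_segment$n_points,
    L_ref_marker = x$L_ref_marker
  )
}

#' Persist and restore calibration models
#'
#' The model is stored as a small JSON document (segments, breakpoint,
#' reference marker lightness, conversion standard, creation time) and
#' restores to a `pfhb_calibration` with identical predictions.
#'
#' @param model A `pfhb_calibration`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the model.
#' @export
write_calibration <- function(model, path) {
  if (!inherits(model, "pfhb_calibration")) {
    stop_hemochroma("model must be a pfhb_calibration", "state")
  }
  doc <- list(
    format = "hemochroma_calibration",
    version = 1L,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    breakpoint = model$breakpoint,
    low_segment = model$low_segment,
    high_segment = model$high_segment,
    L_ref_marker = model$L_ref_marker,
    conversion_standard = model$conversion_standard,
    lod = model$lod,
    lod_k = model$lod_k,
    validated_range = model$validated_range
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "hemochroma_calibration")) {
    stop_hemochroma("not a hemochroma calibration file", "io")
  }
  structure(
    list(
      breakpoint = doc$breakpoint,
      low_segment = as.list(doc$low_segment),
      high_segment = as.list(doc$high_segment),
      L_ref_marker = doc$L_ref_marker,
      conversion_standard = doc$conversion_standard,
      lod = doc$lod,
      lod_k = doc$lod_k,
      validated_range = as.numeric(doc$validated_range)
    ),
    class = "pfhb_calibration"
  )
}
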