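#' Convert 8-bit sRGB colors to CIELab
#'
#' Applies the IEC 61966-2-1 sRGB decoding gamma, the sRGB linear-RGB to
#' CIE XYZ matrix, and the XYZ to CIELab transform with the D65 white point
#' and the 2 degree standard observer. All constants are fixed; the
#' conversion standard is recorded in fitted calibration models so that
#' calibration and analysis always agree.
#'
#' @param rgb A length-3 numeric vector, or an n x 3 matrix / data frame of
#'   8-bit components in \[0, 255\] (columns R, G, B).
#' @return A tibble with one row per input color and columns `L`, `a`, `b`
#'   (CIE L*, a*, b*).
#' @examples
#' rgb_to_lab(c(255, 255, 255)) # L* = 100, a* = b* = 0
#' rgb_to_lab(rbind(c(0, 0, 0), c(255, 0, 0)))
#' @export
rgb_to_lab <- function(rgb) {
  if (is.data.frame(rgb)) rgb <- as.matrix(rgb)
  if (is.null(dim(rgb))) rgb <- matrix(rgb, nrow = 1)
  if (ncol(rgb) != 3) {
    stop_hemochroma("rgb must have three components (R, G, B)", "domain")
  }
  if (anyNA(rgb) || any(rgb < 0) || any(rgb > 255)) {
    stop_hemochroma("rgb components must lie in [0, 255]", "domain")
  }
  lab <- srgb_to_lab_matrix(rgb)
  tibble::tibble(
    L = as.numeric(lab[, 1]),
    a = as.numeric(lab[, 2]),
    b = as.numeric(lab[, 3])
  )
}

# vectorized core; `rgb` is an n x 3 matrix of 8-bit values
srgb_to_lab_matrix <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  # sRGB (D65) linear RGB -> XYZ, 6 significant digits
  m <- matrix(c(
    0.412456, 0.357576, 0.180438,
    0.212673, 0.715152, 0.072175,
    0.019334, 0.119192, 0.950304
  ), nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  white <- c(0.950470, 1.000000, 1.088830) # D65, 2 degree observer
  t3 <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

#' Mean CIELab color of a rectangular region of interest
#'
#' Converts every pixel of the ROI to CIELab and returns the arithmetic mean
#' of L*, a*, b*. Conversion happens before averaging, so the result is the
#' mean color in Lab space, not the Lab of the mean RGB.
#'
#' @param image A [channel_image()] (H x W x 3 array of 8-bit values).
#' @param roi A list with `row_span` and `col_span`, each a 0-based half-open
#'   interval, e.g. as returned by [select_second_roi()].
#' @return A one-row tibble with columns `L`, `a`, `b` and `n_pixels`.
#' @export
roi_mean_lab <- function(image, roi) {
  px <- as_pixel_array(image)
  dims <- dim(px)
  rs <- check_span(roi$row_span, dims[1], "roi$row_span")
  cs <- check_span(roi$col_span, dims[2], "roi$col_span")
  rows <- span_seq(rs)
  cols <- span_seq(cs)
  if (length(rows) == 0 || length(cols) == 0) {
    stop_hemochroma("roi is empty", "domain")
  }
  block <- px[rows, cols, , drop = FALSE]
  flat <- cbind(as.vector(block[, , 1]), as.vector(block[, , 2]), as.vector(block[, , 3]))
  lab <- srgb_to_lab_matrix(flat)
  tibble::tibble(
    L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]),
    n_pixels = nrow(flat)
  )
}

#' Chroma difference between two CIELab colors
#'
#' Euclidean distance in the (a*, b*) chromaticity plane, ignoring
#' lightness: `sqrt((a_m - a_s)^2 + (b_m - b_s)^2)`. In the assay this is
#' computed between the black reference marker and the plasma band; plasma
#' redness, and hence the chroma difference, grows with plasma free
#' hemoglobin.
#'
#' @param marker,plasma Lab colors: one-row data frames or named vectors
#'   with components `a` and `b` (an `L` component is ignored).
#' @return Non-negative numeric scalar, chroma units.
#' @examples
#' chroma_difference(c(a = 0, b = 0), c(a = 3, b = 4)) # 5
#' @export
chroma_difference <- function(marker, plasma) {
  ab <- function(x) {
    if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
    if (!all(c("a", "b") %in% names(x))) {
      stop_hemochroma("Lab color needs named components 'a' and 'b'", "domain")
    }
    as.numeric(x[c("a", "b")])
  }
  m <- ab(marker)
  s <- ab(plasma)
  sqrt((m[1] - s[1])^2 + (m[2] - s[2])^2)
}

#' Brightness-offset corrected chroma difference
#'
#' Compensates illumination drift between calibration time and sample time:
#' the difference between the marker lightness recorded with the calibration
#' images and the marker lightness in the sample image is added to the raw
#' chroma difference. The corrected value may be negative.
#'
#' @param delta_c_raw Raw chroma difference (chroma units).
#' @param L_ref_marker Mean marker L* over the calibration images.
#' @param L_sample_marker Marker L* in the sample image.
#' @return `delta_c_raw + (L_ref_marker - L_sample_marker)`.
#' @examples
#' corrected_chroma(5, 60, 68) # -3
#' @export
corrected_chroma <- function(delta_c_raw, L_ref_marker, L_sample_marker) {
  if (!all(is.finite(delta_c_raw), is.finite(L_ref_marker), is.finite(L_sample_marker))) {
    stop_hemochroma("corrected_chroma inputs must be finite", "domain")
  }
  delta_c_raw + (L_ref_marker - L_sample_marker)
}

#' Marker and plasma colorimetry of a segmented channel image
#'
#' Runs the colorimetric half of the pipeline on one image: mean Lab of the
#' black marker band, mean Lab of the second ROI inside the plasma band, the
#' raw chroma difference, and (when a reference marker lightness is given)
#' the brightness offset and corrected chroma difference.
#'
#' @param image A [channel_image()].
#' @param labels Optional [segment_regions()] result; computed from `image`
#'   when missing.
#' @param L_ref_marker Optional reference marker L*; when `NULL` the offset
#'   is `NA` and `delta_c_corrected` equals `delta_c_raw`.
#' @param config Segmentation thresholds, see [seg_config()].
#' @return One-row tibble: marker and plasma Lab means (`marker_L`,
#'   `marker_a`, `marker_b`, `plasma_L`, `plasma_a`, `plasma_b`),
#'   `delta_c_raw`, `brightness_offset`, `delta_c_corrected`.
#' @export
measure_chroma <- function(image, labels = NULL, L_ref_marker = NULL,
                           config = seg_config()) {
  if (is.null(labels)) labels <- segment_regions(image, config)
  marker_roi <- list(row_span = labels$marker_row_span, col_span = labels$channel_col_span)
  marker <- roi_mean_lab(image, marker_roi)
  plasma <- roi_mean_lab(image, select_second_roi(labels))
  dc <- chroma_difference(marker, plasma)
  offset <- if (is.null(L_ref_marker)) NA_real_ else L_ref_marker - marker$L
  tibble::tibble(
    marker_L = marker$L, marker_a = marker$a, marker_b = marker$b,
    plasma_L = plasma$L, plasma_a = plasma$a, plasma_b = plasma$b,
    delta_c_raw = dc,
    brightness_offset = offset,
    delta_c_corrected = if (is.null(L_ref_marker)) dc else dc + offset
  )
}
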