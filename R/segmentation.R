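#' Segmentation thresholds
#'
#' Thresholds used by [segment_regions()] to split the channel into bands,
#' all in 8-bit intensity units. A pixel row belongs to the black marker
#' when its mean luminance (Rec. 709 weights `0.2126 R + 0.7152 G +
#' 0.0722 B`) falls below `marker_lum_threshold`. A pixel is packed red
#' cells when its red dominance `R - (G + B)/2` reaches `rbc_red_threshold`
#' while its luminance stays below `rbc_lum_ceiling`; the ceiling is what
#' separates the dark packed-cell column from bright reddish plasma, which
#' at high PFHb is *more* red-dominant than the cells but far brighter.
#'
#' A pixel is white backing (background) when it is bright
#' (`luminance > backing_lum_floor`) yet nearly achromatic in red
#' (`red dominance < backing_red_ceiling`); plasma, even hemoglobin-free,
#' keeps a red dominance of ~20 from its straw-yellow tint. Backing pixels
#' are excluded from the row vote, which lets segmentation run on a full
#' frame when the holder geometry (the channel's columns) is unknown.
#'
#' @param rbc_red_threshold Minimum red dominance for packed cells.
#' @param rbc_lum_ceiling Maximum luminance for packed cells. Packed cells
#'   render near luminance 41-50 over a +/-10% illumination band while
#'   plasma stays above ~130 even at 100 mg/dL PFHb, so the default of 90
#'   sits in the middle of the gap.
#' @param marker_lum_threshold Maximum row-mean luminance for the marker
#'   (mean over the row's non-background pixels).
#' @param backing_lum_floor Minimum luminance for white backing.
#' @param backing_red_ceiling Maximum red dominance for white backing.
#' @return A list of thresholds for [segment_regions()].
#' @export
seg_config <- function(rbc_red_threshold = 40,
                       rbc_lum_ceiling = 90,
                       marker_lum_threshold = 35,
                       backing_lum_floor = 150,
                       backing_red_ceiling = 8) {
  list(
    rbc_red_threshold = rbc_red_threshold,
    rbc_lum_ceiling = rbc_lum_ceiling,
    marker_lum_threshold = marker_lum_threshold,
    backing_lum_floor = backing_lum_floor,
    backing_red_ceiling = backing_red_ceiling
  )
}

#' Segment a channel image into marker, plasma and packed-cell bands
#'
#' Classifies every in-channel pixel as marker, rbc (packed red cells) or
#' plasma using the thresholds in [seg_config()], then converts pixel labels
#' to three contiguous row bands by per-row majority vote followed by the
#' longest contiguous run per label (a centrifuged column is contiguous).
#' Run ties break toward the top of the image for the marker and plasma
#' bands and toward the bottom for the packed-cell band, matching the
#' physical layout. Pixels outside the channel columns are background.
#'
#' @param image A [channel_image()]; its `channel_col_span` is used when
#'   present, otherwise the full frame is treated as channel.
#' @param config Thresholds from [seg_config()].
#' @return An object of class `region_labels`: `label_mask` (per-pixel
#'   labels), `marker_row_span`, `plasma_row_span`, `rbc_row_span`,
#'   `channel_col_span` (all 0-based half-open).
#' @section Errors: signals classed errors `hemochroma_no_marker`,
#'   `hemochroma_no_plasma` or `hemochroma_no_packed_cells` when a band is
#'   missing -- each indicates an unusable capture.
#' @export
segment_regions <- function(image, config = seg_config()) {
  px <- as_pixel_array(image)
  h <- dim(px)[1]
  w <- dim(px)[2]
  if (h < 120 || w < 20) {
    stop_hemochroma("image must be at least 120 x 20 pixels", "domain")
  }
  col_span <- if (inherits(image, "channel_image") && !is.null(image$channel_col_span)) {
    image$channel_col_span
  } else {
    c(0L, w)
  }
  cols <- span_seq(col_span)

  r <- px[, cols, 1, drop = TRUE]
  g <- px[, cols, 2, drop = TRUE]
  b <- px[, cols, 3, drop = TRUE]
  lum <- 0.2126 * r + 0.7152 * g + 0.0722 * b
  red_dom <- r - (g + b) / 2

  backing <- lum > config$backing_lum_floor & red_dom < config$backing_red_ceiling
  # marker test uses the row-mean luminance of non-backing pixels
  n_tissue <- rowSums(!backing)
  row_lum <- ifelse(n_tissue > 0, rowSums(lum * !backing) / pmax(n_tissue, 1), Inf)

  lab <- matrix("plasma", h, length(cols))
  lab[red_dom >= config$rbc_red_threshold & lum < config$rbc_lum_ceiling] <- "rbc"
  lab[matrix(row_lum < config$marker_lum_threshold, h, length(cols))] <- "marker"
  lab[backing] <- "background"

  # per-row majority vote among non-backing pixels
  counts <- sapply(c("marker", "plasma", "rbc"), function(l) rowSums(lab == l))
  row_label <- ifelse(
    n_tissue == 0,
    "background",
    c("marker", "plasma", "rbc")[max.col(counts, ties.method = "first")]
  )

  marker_span <- longest_run(row_label == "marker", prefer = "first")
  rbc_span <- longest_run(row_label == "rbc", prefer = "last")
  plasma_span <- longest_run(row_label == "plasma", prefer = "first")
  if (is.null(rbc_span)) {
    stop_hemochroma("no packed-cell band found", "no_packed_cells")
  }
  if (is.null(plasma_span)) {
    stop_hemochroma("no plasma band found", "no_plasma")
  }
  if (is.null(marker_span)) {
    stop_hemochroma("no black marker band found", "no_marker")
  }
  if (plasma_span[1] >= rbc_span[1]) {
    stop_hemochroma("plasma band must lie above the packed-cell band", "no_plasma")
  }

  mask <- matrix("background", h, w)
  mask[, cols] <- lab
  structure(
    list(
      label_mask = mask,
      marker_row_span = marker_span,
      plasma_row_span = plasma_span,
      rbc_row_span = rbc_span,
      channel_col_span = as.integer(col_span)
    ),
    class = "region_labels"
  )
}

# longest contiguous run of TRUE; 0-based half-open span or NULL.
# prefer = "first"/"last" decides ties between equal-length runs.
longest_run <- function(flag, prefer = "first") {
  if (!any(flag)) return(NULL)
  rl <- rle(flag)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  idx <- which(rl$values)
  len <- rl$lengths[idx]
  best <- idx[if (prefer == "last") max(which(len == max(len))) else which.max(len)]
  c(starts[best] - 1L, ends[best])
}

#' Select the second ROI inside the plasma band
#'
#' The colorimetric readout uses a fixed 20 x 100 pixel rectangle (20
#' across the channel, 100 along its axis) centered in the segmented plasma
#' band, both in rows and in columns (offsets by floor division).
#'
#' @param labels A [segment_regions()] result.
#' @param roi_width,roi_height ROI size in pixels (columns x rows).
#' @return A list with `row_span` and `col_span` (0-based half-open).
#' @section Errors: `hemochroma_insufficient_plasma` when the plasma band is
#'   smaller than the ROI.
#' @export
select_second_roi <- function(labels, roi_width = 20L, roi_height = 100L) {
  pr <- labels$plasma_row_span
  cc <- labels$channel_col_span
  if (span_len(pr) < roi_height || span_len(cc) < roi_width) {
    stop_hemochroma(
      sprintf("plasma band (%d rows x %d cols) cannot hold a %d x %d ROI",
              span_len(pr), span_len(cc), roi_height, roi_width),
      "insufficient_plasma"
    )
  }
  r0 <- pr[1] + (span_len(pr) - roi_height) %/% 2
  c0 <- cc[1] + (span_len(cc) - roi_width) %/% 2
  list(
    row_span = c(r0, r0 + roi_height),
    col_span = c(c0, c0 + roi_width)
  )
}

#' Measure packed-cell and total column lengths
#'
#' `L1` is the height of the packed red-cell band; `L2` spans from the first
#' plasma row to the last packed-cell row inclusive -- the total blood
#' column. Their ratio gives hematocrit, see [hematocrit()].
#'
#' @param labels A [segment_regions()] result.
#' @return A one-row tibble with columns `L1` and `L2` (pixels).
#' @export
measure_column_lengths <- function(labels) {
  rbc <- labels$rbc_row_span
  plasma <- labels$plasma_row_span
  if (is.null(rbc) || is.null(plasma)) {
    stop_hemochroma("labels must contain plasma and packed-cell bands", "no_packed_cells")
  }
  tibble::tibble(
    L1 = span_len(rbc),
    L2 = (rbc[2] - 1L) - plasma[1] + 1L
  )
}
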