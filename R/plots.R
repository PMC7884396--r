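#' Plot a fitted standard curve
#'
#' Calibration points (when attached to the model or supplied) with the two
#' fitted segments drawn over their own chroma ranges and the breakpoint as
#' a dashed vertical line.
#'
#' @param object A `pfhb_calibration`.
#' @param points Optional calibration table with `delta_c_corrected` and
#'   `reference_pfhb`; defaults to the table attached by
#'   [calibrate_synthetic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pfhb_calibration <- function(object, points = NULL, ...) {
  if (is.null(points)) points <- attr(object, "points")
  if (!is.null(points) && !"delta_c_corrected" %in% names(points)) points <- NULL
  seg_line <- function(s, lo, hi, name) {
    tibble::tibble(
      delta_c_corrected = c(lo, hi),
      pfhb = s$intercept + s$slope * c(lo, hi),
      segment = name
    )
  }
  if (!is.null(points)) {
    low <- points$delta_c_corrected <= object$breakpoint
    rng_low <- range(points$delta_c_corrected[low])
    rng_high <- range(points$delta_c_corrected[!low])
  } else {
    rng_low <- c(object$breakpoint - 10, object$breakpoint)
    rng_high <- c(object$breakpoint, object$breakpoint + 30)
  }
  lines <- dplyr::bind_rows(
    seg_line(object$low_segment, rng_low[1], rng_low[2], "low"),
    seg_line(object$high_segment, rng_high[1], rng_high[2], "high")
  )
  p <- ggplot2::ggplot(lines,
         ggplot2::aes(x = .data$delta_c_corrected, y = .data$pfhb)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$segment,
                                    color = .data$segment)) +
    ggplot2::geom_vline(xintercept = object$breakpoint, linetype = "dashed") +
    ggplot2::labs(
      x = "corrected chroma difference dC'",
      y = "PFHb (mg/dL)",
      color = "segment",
      title = "Two-segment standard curve"
    )
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(
        delta_c_corrected = points$delta_c_corrected,
        pfhb = points$reference_pfhb
      )
    )
  }
  p
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias and 95% limits of
#' agreement drawn as horizontal lines.
#'
#' @inheritParams regression_and_r
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(data, reference = "reference", device = "device") {
  ba <- bland_altman(data, reference, device)
  d <- tibble::tibble(
    avg = (data[[reference]] + data[[device]]) / 2,
    diff = data[[device]] - data[[reference]]
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$bias, color = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(
      x = "mean of methods", y = "device - reference",
      title = sprintf("Bland-Altman: bias %.3g, LoA (%.3g, %.3g)",
                      ba$bias, ba$loa_low, ba$loa_high)
    )
}

#' Display a channel image
#'
#' Renders the RGB raster, optionally overlaying segmented band boundaries.
#'
#' @param image A [channel_image()].
#' @param labels Optional [segment_regions()] result; band boundaries are
#'   drawn when given.
#' @return A ggplot object.
#' @export
plot_channel <- function(image, labels = NULL) {
  px <- as_pixel_array(image)
  h <- dim(px)[1]
  w <- dim(px)[2]
  d <- expand.grid(row = seq_len(h), col = seq_len(w))
  d$fill <- grDevices::rgb(px[, , 1], px[, , 2], px[, , 3], maxColorValue = 255)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = "row")
  if (!is.null(labels)) {
    edges <- c(labels$marker_row_span, labels$plasma_row_span, labels$rbc_row_span)
    p <- p + ggplot2::geom_hline(yintercept = unique(edges) + 0.5,
                                 color = "cyan", linewidth = 0.3)
  }
  p
}
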