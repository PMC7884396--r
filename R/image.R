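#' Channel image container
#'
#' A thin wrapper around an H x W x 3 array of 8-bit RGB intensities with
#' acquisition metadata: a free-text `source_id` and, when known from the
#' holder geometry, the columns occupied by the channel.
#'
#' @param pixels H x W x 3 numeric/integer array with values in \[0, 255\].
#' @param source_id Identifier carried into results for provenance.
#' @param channel_col_span Optional 0-based half-open column interval of the
#'   channel; `NULL` means full frame.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, source_id = "unknown", channel_col_span = NULL) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop_hemochroma("pixels must be an H x W x 3 array", "domain")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop_hemochroma("pixel intensities must lie in [0, 255]", "domain")
  }
  if (!is.null(channel_col_span)) {
    channel_col_span <- check_span(channel_col_span, dim(pixels)[2], "channel_col_span")
  }
  structure(
    list(
      pixels = pixels,
      source_id = source_id,
      channel_col_span = channel_col_span
    ),
    class = "channel_image"
  )
}

as_pixel_array <- function(image) {
  if (inherits(image, "channel_image")) return(image$pixels)
  if (length(dim(image)) == 3 && dim(image)[3] == 3) return(image)
  stop_hemochroma("expected a channel_image or an H x W x 3 array", "domain")
}

#' @export
print.channel_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<channel_image> %d x %d px, source: %s\n", d[1], d[2], x$source_id))
  if (!is.null(x$channel_col_span)) {
    cat(sprintf("  channel columns [%d, %d)\n",
                x$channel_col_span[1], x$channel_col_span[2]))
  }
  invisible(x)
}

#' Read and write channel images
#'
#' `read_channel_image()` loads an 8-bit RGB PNG or TIFF as a
#' [channel_image()]; `write_channel_png()` writes one as PNG. TIFF support
#' requires the optional tiff package. Grayscale input is replicated to
#' three channels; an alpha channel, if present, is dropped.
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param channel_col_span Optional known channel column interval.
#' @param image A [channel_image()].
#' @return `read_channel_image()` returns a [channel_image()];
#'   `write_channel_png()` returns `path` invisibly.
#' @export
read_channel_image <- function(path, channel_col_span = NULL) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop_hemochroma("reading TIFF requires the 'tiff' package", "io")
      }
      tiff::readTIFF(path)
    },
    stop_hemochroma(sprintf("unsupported image format '%s'", ext), "io")
  )
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  px <- round_half_up(arr * 255)
  storage.mode(px) <- "integer"
  channel_image(px, source_id = basename(path), channel_col_span = channel_col_span)
}

#' @rdname read_channel_image
#' @export
write_channel_png <- function(image, path) {
  px <- as_pixel_array(image)
  png::writePNG(px / 255, target = path)
  invisible(path)
}
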