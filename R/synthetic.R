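#' Scene specification for a synthetic cartridge image
#'
#' Describes one centrifuged-channel scene: the ground-truth analyte levels,
#' the channel geometry in pixels, and the acquisition conditions. The
#' channel is rendered vertically with the black marker band at the top and
#' the packed red-cell column at the bottom (the direction of centrifugal
#' force); row indices increase downward and all spans are 0-based,
#' half-open intervals.
#'
#' The default geometry tiles the image height completely: marker rows
#' `[0, 120)` and blood rows `[120, 1120)`, so every in-channel pixel belongs
#' to the marker, plasma or packed-cell band. The default
#' `illumination_scale` of 0.9 models a camera exposed with headroom so the
#' white backing and near-white plasma never saturate, keeping a +/-10%
#' illumination drift in gamut.
#'
#' @param true_pfhb Plasma free hemoglobin, mg/dL, >= 0.
#' @param true_hct Hematocrit, percent in \[0, 100\].
#' @param image_height,image_width Image size in pixels.
#' @param channel_col_span Columns occupied by the channel (0-based,
#'   half-open).
#' @param marker_row_span Rows of the black marker band.
#' @param blood_row_span Rows available to blood (the total-column region).
#' @param illumination_scale Global multiplicative illumination factor > 0.
#' @param noise_sd Per-pixel, per-channel Gaussian noise SD in 8-bit units.
#' @param rng_seed Integer seed; identical specs render identical images.
#' @return An object of class `scene_spec`.
#' @seealso [render_channel()]
#' @export
scene_spec <- function(true_pfhb, true_hct,
                       image_height = 1120, image_width = 60,
                       channel_col_span = c(15, 45),
                       marker_row_span = c(0, 120),
                       blood_row_span = c(120, 1120),
                       illumination_scale = 0.9,
                       noise_sd = 2,
                       rng_seed = 1L) {
  spec <- structure(
    list(
      true_pfhb = true_pfhb, true_hct = true_hct,
      image_height = as.integer(image_height),
      image_width = as.integer(image_width),
      channel_col_span = as.integer(channel_col_span),
      marker_row_span = as.integer(marker_row_span),
      blood_row_span = as.integer(blood_row_span),
      illumination_scale = illumination_scale,
      noise_sd = noise_sd,
      rng_seed = as.integer(rng_seed)
    ),
    class = "scene_spec"
  )
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (!is_number(spec$true_pfhb) || spec$true_pfhb < 0) {
    stop_hemochroma("true_pfhb must be a single non-negative number", "invalid_spec")
  }
  if (!is_number(spec$true_hct) || spec$true_hct < 0 || spec$true_hct > 100) {
    stop_hemochroma("true_hct must lie in [0, 100]", "invalid_spec")
  }
  if (!is_number(spec$illumination_scale) || spec$illumination_scale <= 0) {
    stop_hemochroma("illumination_scale must be > 0", "invalid_spec")
  }
  if (!is_number(spec$noise_sd) || spec$noise_sd < 0) {
    stop_hemochroma("noise_sd must be >= 0", "invalid_spec")
  }
  check_span(spec$channel_col_span, spec$image_width, "channel_col_span")
  check_span(spec$marker_row_span, spec$image_height, "marker_row_span")
  check_span(spec$blood_row_span, spec$image_height, "blood_row_span")
  # marker and blood bands must not overlap
  if (max(spec$marker_row_span[1], spec$blood_row_span[1]) <
      min(spec$marker_row_span[2], spec$blood_row_span[2])) {
    stop_hemochroma("marker_row_span and blood_row_span must be disjoint", "invalid_spec")
  }
  invisible(spec)
}

#' Beer-Lambert plasma color as a function of plasma free hemoglobin
#'
#' Models the plasma band color as per-channel attenuation of a straw-yellow
#' base: channel intensity `base_c * exp(-epsilon_c * pfhb)`, quantized to
#' 8 bits. Hemoglobin absorbs red light least, so `epsilon_R < epsilon_G <=
#' epsilon_B`: the red channel stays highest while green and blue fall with
#' PFHb, which is what drives the chroma difference used for quantification.
#'
#' @param pfhb Vector of PFHb levels, mg/dL, >= 0.
#' @param base 8-bit base color at PFHb 0 (straw-yellow plasma).
#' @param epsilon Per-channel absorbance coefficients, 1/(mg/dL).
#' @return A tibble with columns `pfhb`, `r`, `g`, `b` (8-bit integers).
#' @examples
#' plasma_rgb(c(0, 100))
#' @export
plasma_rgb <- function(pfhb, base = c(250, 235, 220),
                       epsilon = c(0.0005, 0.006, 0.009)) {
  if (any(!is.finite(pfhb)) || any(pfhb < 0)) {
    stop_hemochroma("pfhb must be non-negative", "domain")
  }
  if (!(epsilon[1] < epsilon[2] && epsilon[2] <= epsilon[3])) {
    stop_hemochroma("absorbance coefficients must satisfy eps_R < eps_G <= eps_B", "domain")
  }
  raw <- outer(pfhb, epsilon, function(p, e) exp(-e * p))
  rgb <- sweep(raw, 2, base, "*")
  rgb <- pmin(pmax(round_half_up(rgb), 0), 255)
  tibble::tibble(
    pfhb = pfhb,
    r = as.integer(rgb[, 1]), g = as.integer(rgb[, 2]), b = as.integer(rgb[, 3])
  )
}

#' Dilution series of a hemolysate stock
#'
#' PFHb levels produced by diluting a stock at the given ratios (a ratio of
#' 10 means 1:10). Defaults to the eight-ratio series used to span the
#' clinically relevant 10-100 mg/dL range from a 1,000 mg/dL stock.
#'
#' @param original_pfhb Stock PFHb, mg/dL, > 0.
#' @param ratios Dilution factors, all >= 1.
#' @return A tibble with columns `ratio` and `pfhb` (`original_pfhb / ratio`),
#'   in the order given.
#' @examples
#' dilution_series(1000)
#' @export
dilution_series <- function(original_pfhb,
                            ratios = c(10, 15, 20, 30, 50, 65, 85, 100)) {
  if (!is_number(original_pfhb) || original_pfhb <= 0) {
    stop_hemochroma("original_pfhb must be a single positive number", "domain")
  }
  if (any(!is.finite(ratios)) || any(ratios < 1)) {
    stop_hemochroma("dilution ratios must all be >= 1", "domain")
  }
  tibble::tibble(ratio = as.numeric(ratios), pfhb = original_pfhb / ratios)
}

# fixed scene palette (8-bit, before illumination)
scene_palette <- function() {
  list(
    background = c(255, 255, 255), # white acrylic backing
    marker = c(15, 15, 15),        # black cap marker
    rbc = c(120, 25, 30)           # packed red cells, dark red
  )
}

#' Render a synthetic centrifuged-channel image with ground truth
#'
#' Draws the scene described by a [scene_spec()]: white backing outside the
#' channel columns; inside them, top to bottom, the black marker band, the
#' plasma band (color from [plasma_rgb()] at `true_pfhb`), and a packed
#' red-cell band occupying `round(true_hct/100 * blood_rows)` rows at the
#' bottom of the blood region (round half away from zero, so Hct has a
#' one-pixel quantization floor of `100/blood_rows`). All channels are
#' multiplied by `illumination_scale`, then i.i.d. Gaussian noise of SD
#' `noise_sd` is added per pixel and channel, and values are clipped to
#' \[0, 255\] and quantized to 8 bits. Rendering is deterministic in the
#' spec (including `rng_seed`).
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (a [channel_image()]) and `truth`
#'   (class `ground_truth`: `label_mask` with levels background/marker/
#'   plasma/rbc, `rbc_rows`, `blood_rows`, `true_pfhb`, `true_hct`).
#' @export
render_channel <- function(spec) {
  if (!inherits(spec, "scene_spec")) {
    stop_hemochroma("spec must be a scene_spec", "invalid_spec")
  }
  validate_scene_spec(spec)
  h <- spec$image_height
  w <- spec$image_width
  pal <- scene_palette()

  blood_rows <- span_len(spec$blood_row_span)
  rbc_rows <- as.integer(round_half_up(spec$true_hct / 100 * blood_rows))
  plasma_rows <- blood_rows - rbc_rows

  label <- matrix("background", h, w)
  cols <- span_seq(spec$channel_col_span)
  label[span_seq(spec$marker_row_span), cols] <- "marker"
  plasma_span <- c(spec$blood_row_span[1], spec$blood_row_span[1] + plasma_rows)
  rbc_span <- c(spec$blood_row_span[1] + plasma_rows, spec$blood_row_span[2])
  if (plasma_rows > 0) label[span_seq(plasma_span), cols] <- "plasma"
  if (rbc_rows > 0) label[span_seq(rbc_span), cols] <- "rbc"

  plasma_col <- as.numeric(plasma_rgb(spec$true_pfhb)[1, c("r", "g", "b")])
  px <- array(0, dim = c(h, w, 3))
  for (k in 1:3) {
    plane <- matrix(pal$background[k], h, w)
    plane[label == "marker"] <- pal$marker[k]
    plane[label == "plasma"] <- plasma_col[k]
    plane[label == "rbc"] <- pal$rbc[k]
    px[, , k] <- plane
  }
  px <- px * spec$illumination_scale
  if (spec$noise_sd > 0) {
    px <- px + withr::with_seed(
      spec$rng_seed,
      array(stats::rnorm(length(px), sd = spec$noise_sd), dim = dim(px))
    )
  }
  px <- pmin(pmax(round_half_up(px), 0), 255)
  storage.mode(px) <- "integer"

  image <- channel_image(px,
    source_id = sprintf("synthetic pfhb=%g hct=%g seed=%d",
                        spec$true_pfhb, spec$true_hct, spec$rng_seed),
    channel_col_span = spec$channel_col_span
  )
  truth <- structure(
    list(
      label_mask = label,
      rbc_rows = rbc_rows,
      blood_rows = blood_rows,
      true_pfhb = spec$true_pfhb,
      true_hct = spec$true_hct,
      plasma_row_span = plasma_span,
      rbc_row_span = rbc_span,
      marker_row_span = spec$marker_row_span
    ),
    class = "ground_truth"
  )
  list(image = image, truth = truth)
}
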