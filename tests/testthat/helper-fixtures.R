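# shared fixtures built in code

# a small, fast scene: 300-row blood column, same palette and thresholds
small_spec <- function(pfhb = 20, hct = 40, noise_sd = 0, seed = 1L,
                       illumination = 0.9, shift = 0L) {
  scene_spec(
    true_pfhb = pfhb, true_hct = hct,
    image_height = 420L + shift, image_width = 40L,
    channel_col_span = c(8, 32),
    marker_row_span = c(0L + shift, 60L + shift),
    blood_row_span = c(60L + shift, 420L + shift),
    illumination_scale = illumination, noise_sd = noise_sd, rng_seed = seed
  )
}

# hand-built region labels (0-based half-open spans)
make_labels <- function(marker = c(0, 60), plasma = c(60, 300),
                        rbc = c(300, 420), cols = c(8, 32)) {
  structure(
    list(
      label_mask = NULL,
      marker_row_span = marker,
      plasma_row_span = plasma,
      rbc_row_span = rbc,
      channel_col_span = cols
    ),
    class = "region_labels"
  )
}

# uniform-color image builder
flat_image <- function(h, w, rgb, channel_col_span = NULL) {
  px <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) px[, , k] <- rgb[k]
  channel_image(px, source_id = "fixture", channel_col_span = channel_col_span)
}

# R row indices of a 0-based half-open span
rows_of <- function(span) seq.int(span[1] + 1, span[2])

# the 12 published hemoglobin pairs (lab reference vs device), g/dL
table1_hb_pairs <- function() {
  data.frame(
    reference = c(9.6, 10.1, 12, 11.2, 10.7, 10.1, 10.8, 8, 9.5, 9.1, 9.2, 9.6),
    device = c(9.2, 9.2, 11.8, 11.6, 11.8, 9.9, 9.9, 9.2, 10.4, 10, 9.1, 10.3)
  )
}
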