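test_that("noise-free synthetic images segment exactly to ground truth", {
  for (hct in c(25, 42)) {
    out <- render_channel(small_spec(pfhb = 30, hct = hct, noise_sd = 0))
    labels <- segment_regions(out$image)
    # pixel labels agree with the simulator mask on >= 99% of channel pixels
    cols <- rows_of(labels$channel_col_span)
    agree <- mean(labels$label_mask[, cols] == out$truth$label_mask[, cols])
    expect_gte(agree, 0.99)
    # column lengths equal ground truth exactly
    len <- measure_column_lengths(labels)
    expect_equal(len$L1, out$truth$rbc_rows)
    expect_equal(len$L2, out$truth$blood_rows)
  }
})

test_that("segmentation still recovers lengths under default noise", {
  out <- render_channel(small_spec(pfhb = 40, hct = 42, noise_sd = 2, seed = 5))
  len <- measure_column_lengths(segment_regions(out$image))
  expect_lte(abs(len$L1 - out$truth$rbc_rows), 2)
  expect_lte(abs(len$L2 - out$truth$blood_rows), 2)
})

test_that("missing bands raise classed errors", {
  expect_error(
    segment_regions(flat_image(200, 30, c(255, 255, 255))),
    class = "hemochroma_no_packed_cells"
  )
  # marker + rbc but no plasma band above the cells
  px <- flat_image(200, 30, c(120, 25, 30))$pixels
  for (k in 1:3) px[1:60, , k] <- 15
  expect_error(
    segment_regions(channel_image(px)),
    class = "hemochroma_no_plasma"
  )
  # plasma + rbc but no marker
  px2 <- flat_image(200, 30, c(250, 235, 220))$pixels
  for (k in 1:3) px2[150:200, , k] <- c(120, 25, 30)[k]
  expect_error(
    segment_regions(channel_image(px2)),
    class = "hemochroma_no_marker"
  )
  # undersized images are rejected outright
  expect_error(
    segment_regions(flat_image(50, 10, c(0, 0, 0))),
    class = "hemochroma_domain"
  )
})

test_that("a sharp band boundary is located exactly", {
  # marker rows [0,60), plasma [60,140), rbc [140,200)
  px <- flat_image(200, 30, c(250, 235, 220))$pixels
  for (k in 1:3) {
    px[1:60, , k] <- 15
    px[141:200, , k] <- c(120, 25, 30)[k]
  }
  labels <- segment_regions(channel_image(px))
  expect_equal(labels$marker_row_span, c(0, 60))
  expect_equal(labels$plasma_row_span, c(60, 140))
  expect_equal(labels$rbc_row_span, c(140, 200))
  len <- measure_column_lengths(labels)
  expect_equal(len$L1, 60)
  expect_equal(len$L2, 140)
})

test_that("every channel pixel receives exactly one label", {
  out <- render_channel(small_spec(noise_sd = 2, seed = 3))
  labels <- segment_regions(out$image)
  cols <- rows_of(labels$channel_col_span)
  inside <- labels$label_mask[, cols]
  expect_true(all(inside %in% c("marker", "plasma", "rbc")))
  outside <- labels$label_mask[, -cols]
  expect_true(all(outside == "background"))
})

test_that("shifting the scene down shifts every reported span equally", {
  base <- segment_regions(render_channel(small_spec(noise_sd = 0))$image)
  k <- 7L
  shifted <- segment_regions(render_channel(small_spec(noise_sd = 0, shift = k))$image)
  expect_equal(shifted$marker_row_span, base$marker_row_span + k)
  expect_equal(shifted$plasma_row_span, base$plasma_row_span + k)
  expect_equal(shifted$rbc_row_span, base$rbc_row_span + k)
})

test_that("second ROI is a centered 20 x 100 rectangle inside plasma", {
  labels <- make_labels(plasma = c(100, 300), cols = c(40, 80))
  roi <- select_second_roi(labels)
  expect_equal(roi$row_span, c(150, 250))
  expect_equal(roi$col_span, c(50, 70))

  # a plasma band of exactly 100 rows is used whole
  exact <- select_second_roi(make_labels(plasma = c(60, 160), cols = c(0, 20)))
  expect_equal(exact$row_span, c(60, 160))
  expect_equal(exact$col_span, c(0, 20))

  # 99 rows are not enough
  expect_error(
    select_second_roi(make_labels(plasma = c(60, 159))),
    class = "hemochroma_insufficient_plasma"
  )

  # the ROI lies fully inside plasma-labeled pixels on a rendered scene
  out <- render_channel(small_spec(noise_sd = 0))
  lab <- segment_regions(out$image)
  roi2 <- select_second_roi(lab)
  block <- lab$label_mask[rows_of(roi2$row_span), rows_of(roi2$col_span)]
  expect_true(all(block == "plasma"))
})

test_that("column lengths follow the span arithmetic", {
  labels <- make_labels(plasma = c(0, 700), rbc = c(700, 1000))
  len <- measure_column_lengths(labels)
  expect_equal(len$L1, 300)
  expect_equal(len$L2, 1000)
})
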