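test_that("a noiseless two-segment line is recovered exactly", {
  bp <- 0
  low_x <- c(-10, -7, -5, -2, 0)
  high_x <- c(2, 5, 8, 12)
  pts <- data.frame(
    delta_c_corrected = c(low_x, high_x),
    reference_pfhb = c(60 + 2 * low_x, 55 + 3.5 * high_x)
  )
  model <- fit_calibration(pts, breakpoint = bp)
  expect_equal(model$low_segment$slope, 2, tolerance = 1e-9)
  expect_equal(model$low_segment$intercept, 60, tolerance = 1e-9)
  expect_equal(model$high_segment$slope, 3.5, tolerance = 1e-9)
  expect_equal(model$high_segment$intercept, 55, tolerance = 1e-9)
  expect_equal(model$low_segment$r_squared, 1)
  expect_equal(model$high_segment$r_squared, 1)

  # round trip: every calibration point predicts its own reference
  pred <- pfhb_from_chroma(model, pts$delta_c_corrected)
  expect_equal(pred$pfhb, pts$reference_pfhb, tolerance = 1e-9)
})

test_that("random noiseless curves are recovered exactly in every trial", {
  set.seed(7)
  for (trial in 1:100) {
    bp <- 0
    s_low <- runif(1, 1, 5)
    s_high <- runif(1, 1, 5)
    i_low <- runif(1, 55, 90)
    i_high <- runif(1, 55, 90)
    lx <- sort(runif(5, -10, 0))
    hx <- sort(runif(4, 1e-6, 15))
    pts <- data.frame(
      delta_c_corrected = c(lx, hx),
      reference_pfhb = c(i_low + s_low * lx, i_high + s_high * hx)
    )
    m <- fit_calibration(pts, breakpoint = bp)
    expect_equal(m$low_segment$slope, s_low, tolerance = 1e-8)
    expect_equal(m$high_segment$slope, s_high, tolerance = 1e-8)
    expect_equal(m$low_segment$intercept, i_low, tolerance = 1e-7)
    expect_equal(m$high_segment$intercept, i_high, tolerance = 1e-7)
  }
})

test_that("segment assignment, ties, clamping and extrapolation flags", {
  pts <- data.frame(
    delta_c_corrected = c(-8, -6, -4, 2, 4, 6),
    reference_pfhb = c(4, 8, 12, 40, 60, 80)
  )
  model <- fit_calibration(pts, breakpoint = -3)
  # exactly at the breakpoint -> low segment (documented tie rule)
  at_bp <- pfhb_from_chroma(model, -3)
  expect_equal(at_bp$segment, "low")
  expect_equal(at_bp$pfhb, model$low_segment$intercept + model$low_segment$slope * -3)
  just_above <- pfhb_from_chroma(model, -3 + 1e-9)
  expect_equal(just_above$segment, "high")

  # a chroma implying negative pfhb clamps to 0 and flags it
  low_end <- pfhb_from_chroma(model, -20)
  expect_equal(low_end$pfhb, 0)
  expect_true(low_end$clamped)

  # beyond the validated range flags extrapolation
  high_end <- pfhb_from_chroma(model, 10)
  expect_gt(high_end$pfhb, 100)
  expect_true(high_end$extrapolated)

  expect_error(pfhb_from_chroma(list(), 0), class = "hemochroma_state")
})

test_that("underdetermined or degenerate calibrations are rejected", {
  pts <- data.frame(delta_c_corrected = c(-5, -4, 1, 2, 3), reference_pfhb = 1:5)
  expect_error(fit_calibration(pts, breakpoint = 0),
               class = "hemochroma_insufficient_calibration")
  flat <- data.frame(
    delta_c_corrected = c(-5, -5, -5, 1, 2, 3),
    reference_pfhb = 1:6
  )
  expect_error(fit_calibration(flat, breakpoint = 0),
               class = "hemochroma_degenerate_calibration")
  neg <- data.frame(delta_c_corrected = 1:6 - 3.5, reference_pfhb = c(-1, 2:6))
  expect_error(fit_calibration(neg, breakpoint = 0), class = "hemochroma_domain")
})

test_that("limit of detection follows k * residual SD / |slope|", {
  expect_equal(compute_lod(list(slope = 2, residual_sd = 0.5)), 0.825)
  expect_equal(compute_lod(list(slope = 1, residual_sd = 1)), 3.3)
  expect_equal(compute_lod(list(slope = -2, residual_sd = 0.5)), 0.825)
  expect_equal(compute_lod(list(slope = 3, residual_sd = 0)), 0)
  expect_equal(compute_lod(list(slope = 2, residual_sd = 0.5), k = 3), 0.75)
  expect_error(compute_lod(list(slope = 0, residual_sd = 1)),
               class = "hemochroma_degenerate_calibration")

  # five-point fixture: OLS computed longhand as the oracle
  x <- c(1, 2, 3, 4, 5)
  e <- c(0.5, -0.25, -0.5, -0.25, 0.5)
  y <- 2 * x + e
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_hand <- mean(y) - slope_hand * mean(x)
  resid_hand <- y - intercept_hand - slope_hand * x
  sd_hand <- sqrt(sum(resid_hand^2) / (length(x) - 2))
  pts <- data.frame(
    delta_c_corrected = c(x, 11, 12, 13),
    reference_pfhb = c(y, 3 * c(11, 12, 13) - 5)
  )
  model <- fit_calibration(pts, breakpoint = 10)
  expect_equal(model$low_segment$slope, slope_hand, tolerance = 1e-12)
  expect_equal(model$low_segment$intercept, intercept_hand, tolerance = 1e-12)
  expect_equal(model$low_segment$residual_sd, sd_hand, tolerance = 1e-12)
  expect_equal(model$lod, 3.3 * sd_hand / abs(slope_hand), tolerance = 1e-12)
})

test_that("fitted models serialize to JSON and round-trip losslessly", {
  model <- calibrate_synthetic(seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(model, path)
  back <- read_calibration(path)
  probe <- seq(5, 50, by = 2.5)
  expect_equal(pfhb_from_chroma(back, probe), pfhb_from_chroma(model, probe))
  expect_equal(back$L_ref_marker, model$L_ref_marker)
  expect_equal(back$lod, model$lod)
  expect_equal(back$conversion_standard, model$conversion_standard)
})

test_that("tidy and glance summarize the fitted curve", {
  model <- calibrate_synthetic(seed = 3)
  td <- tidy(model)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  expect_setequal(unique(td$segment), c("low", "high"))
  gl <- glance(model)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("r_squared_low", "r_squared_high", "lod") %in% names(gl)))
  expect_true(gl$r_squared_low >= 0 && gl$r_squared_low <= 1)
})

test_that("prediction is monotone within each fitted segment", {
  model <- calibrate_synthetic(seed = 5)
  lo <- seq(model$breakpoint - 8, model$breakpoint, length.out = 20)
  hi <- seq(model$breakpoint + 1e-6, model$breakpoint + 30, length.out = 20)
  p_lo <- pfhb_from_chroma(model, lo)$pfhb
  p_hi <- pfhb_from_chroma(model, hi)$pfhb
  expect_true(all(diff(p_lo) >= 0) || all(diff(p_lo) <= 0))
  expect_true(all(diff(p_hi) >= 0) || all(diff(p_hi) <= 0))
})
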