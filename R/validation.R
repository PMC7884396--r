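#' Ordinary least-squares agreement regression with Pearson correlation
#'
#' Regresses device measurements on the reference method (OLS of device on
#' reference) and reports the Pearson correlation of the two series -- the
#' slope/intercept/R summary used in method-comparison scatter plots.
#'
#' @param data Data frame of paired measurements.
#' @param reference,device Column names (strings) holding the reference and
#'   device values; defaults `"reference"` and `"device"`.
#' @return One-row tibble: `slope`, `intercept`, `pearson_r`, `n`.
#' @examples
#' d <- data.frame(reference = 1:5, device = 2 * (1:5) + 5)
#' regression_and_r(d) # slope 2, intercept 5, r 1
#' @export
regression_and_r <- function(data, reference = "reference", device = "device") {
  p <- paired_values(data, reference, device)
  if (stats::var(p$reference) == 0) {
    stop_hemochroma("reference values have zero variance", "degenerate_data")
  }
  fit <- stats::lm(p$device ~ p$reference)
  tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    pearson_r = stats::cor(p$reference, p$device),
    n = nrow(p)
  )
}

#' Bland-Altman agreement analysis
#'
#' Computes the paired differences `device - reference`, their mean (the
#' bias) and the 95% limits of agreement `bias +/- 1.96 * SD` using the
#' sample (n-1) standard deviation. These are limits of agreement in the
#' Bland-Altman sense, the standard reading of the bands drawn on such
#' plots.
#'
#' @inheritParams regression_and_r
#' @return One-row tibble: `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @examples
#' d <- data.frame(reference = c(1, 2, 3), device = c(3, 4, 5))
#' bland_altman(d) # bias 2, limits (2, 2)
#' @export
bland_altman <- function(data, reference = "reference", device = "device") {
  p <- paired_values(data, reference, device)
  d <- p$device - p$reference
  bias <- mean(d)
  s <- stats::sd(d)
  tibble::tibble(
    bias = bias,
    loa_low = bias - 1.96 * s,
    loa_high = bias + 1.96 * s,
    sd_diff = s,
    n = length(d)
  )
}

paired_values <- function(data, reference, device) {
  if (!is.data.frame(data) || !all(c(reference, device) %in% names(data))) {
    stop_hemochroma(
      sprintf("data must contain columns '%s' and '%s'", reference, device),
      "domain"
    )
  }
  p <- tibble::tibble(
    reference = as.numeric(data[[reference]]),
    device = as.numeric(data[[device]])
  )
  p <- p[stats::complete.cases(p), , drop = FALSE]
  if (nrow(p) < 3) {
    stop_hemochroma("need at least 3 complete measurement pairs", "domain")
  }
  p
}

#' Replicate precision summary
#'
#' Mean, sample (n-1) standard deviation, and coefficient of variation
#' `CV% = 100 * SD / mean` of replicate measurements of one sample.
#'
#' @param replicates Numeric vector of replicate measurements, n >= 2.
#' @return One-row tibble: `mean`, `sd`, `cv_percent`, `n`.
#' @examples
#' precision_summary(c(52.1, 53.5, 53.6))
#' @export
precision_summary <- function(replicates) {
  replicates <- replicates[!is.na(replicates)]
  if (length(replicates) < 2) {
    stop_hemochroma("need at least 2 replicates", "domain")
  }
  m <- mean(replicates)
  s <- stats::sd(replicates)
  tibble::tibble(
    mean = m,
    sd = s,
    cv_percent = cv_percent(m, s),
    n = length(replicates)
  )
}

#' Coefficient of variation from a mean and SD
#'
#' `CV% = 100 * SD / mean`; used both internally by [precision_summary()]
#' and directly when reproducing published precision tables from their
#' printed mean/SD values.
#'
#' @param mean Mean of the replicates, > 0.
#' @param sd Standard deviation of the replicates.
#' @return CV in percent.
#' @examples
#' cv_percent(53.08, 1.36) # 2.56 at 2-decimal rounding
#' @export
cv_percent <- function(mean, sd) {
  if (any(mean <= 0)) {
    stop_hemochroma("CV is undefined for non-positive means", "domain")
  }
  100 * sd / mean
}
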