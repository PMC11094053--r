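# Observer/model reproducibility statistics: Bland-Altman, two-way
# mixed-effects absolute-agreement ICC, coefficient of variability,
# Pearson correlation, paired t-tests with Bonferroni correction and a
# Shapiro-Wilk normality gate.

#' Paired series of a cardiac-function parameter from two raters
#'
#' @param parameter Parameter name (e.g., `"EF"`, `"SV"`, `"LV mass"`,
#'   `"EDV"`, `"ESV"`).
#' @param values_a,values_b Equal-length numeric vectors aligned by scan.
#' @param ids Optional scan identifiers.
#' @return A `paired_series` list.
#' @export
paired_series <- function(parameter, values_a, values_b, ids = NULL) {
  if (length(values_a) != length(values_b))
    stop("`values_a` and `values_b` must have equal length", call. = FALSE)
  if (length(values_a) < 2)
    stop("a paired series needs at least 2 scans", call. = FALSE)
  structure(list(parameter = parameter,
                 values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b),
                 ids = ids),
            class = "paired_series")
}

as_paired <- function(s, a = NULL, b = NULL) {
  if (inherits(s, "paired_series")) return(s)
  paired_series("value", s, a)
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean of the paired differences `a - b`; the limits of
#' agreement are `bias +/- 1.96` sample standard deviations of the
#' differences, so roughly 95% of differences fall inside them under
#' normality.
#'
#' @param s A [paired_series()], or a numeric vector (then `b` supplies
#'   the second rater).
#' @param b Second rater's values when `s` is a plain vector.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(s, b = NULL) {
  s <- as_paired(s, b)
  d <- s$values_a - s$values_b
  bias <- mean(d)
  sdd <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * sdd,
       loa_high = bias + 1.96 * sdd, sd_diff = sdd, n = length(d))
}

#' Two-way mixed-effects, absolute-agreement ICC (single measure)
#'
#' ICC(A,1) from the two-way ANOVA mean squares, for n subjects rated by
#' k = 2 raters:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + (k / n) (MSC - MSE))`,
#' where MSR, MSC and MSE are the subject, rater and residual mean
#' squares. Interpretation bands: below 0.5 poor, 0.5-0.75 moderate,
#' 0.75-0.9 good, above 0.9 excellent. A table with zero total variance
#' (identical constant series) has an undefined ICC and returns `NA`.
#'
#' @inheritParams bland_altman
#' @return Numeric ICC (at most 1), with attribute `interpretation`;
#'   `NA` when undefined.
#' @export
icc_absolute_agreement <- function(s, b = NULL) {
  s <- as_paired(s, b)
  x <- cbind(s$values_a, s$values_b)
  n <- nrow(x); k <- ncol(x)
  if (n < 3) stop("ICC requires at least 3 subjects", call. = FALSE)
  grand <- mean(x)
  sst <- sum((x - grand)^2)
  if (sst == 0) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  row_m <- rowMeans(x); col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  interp <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
            else if (icc <= 0.9) "good" else "excellent"
  structure(icc, interpretation = interp)
}

#' Coefficient of variability between two raters, in percent
#'
#' `100 * SD(a - b) / mean`, where the denominator is by default the
#' grand mean over all values of both series (this reading reproduces a
#' CoV of exactly 0% for identical series); `"pairwise_mean"` divides by
#' the mean of the per-pair means instead (identical here for equal-length
#' series, but kept explicit as the convention is stated ambiguously in
#' the field).
#'
#' @inheritParams bland_altman
#' @param denominator `"grand_mean"` (default) or `"pairwise_mean"`.
#' @return CoV in percent (non-negative).
#' @export
cov_percent <- function(s, b = NULL,
                        denominator = c("grand_mean", "pairwise_mean")) {
  denominator <- match.arg(denominator)
  s <- as_paired(s, b)
  denom <- switch(denominator,
                  grand_mean = mean(c(s$values_a, s$values_b)),
                  pairwise_mean = mean((s$values_a + s$values_b) / 2))
  if (denom == 0) stop("mean of the series is 0: CoV undefined",
                       call. = FALSE)
  100 * stats::sd(s$values_a - s$values_b) / denom
}

#' Pearson correlation between two raters
#'
#' @inheritParams bland_altman
#' @return Sample correlation in `[-1, 1]`; `NA` (with a warning) for a
#'   constant series.
#' @export
pearson_r <- function(s, b = NULL) {
  s <- as_paired(s, b)
  if (length(s$values_a) < 3)
    stop("Pearson correlation requires n >= 3", call. = FALSE)
  if (stats::sd(s$values_a) == 0 || stats::sd(s$values_b) == 0) {
    warning("constant series: Pearson correlation undefined")
    return(NA_real_)
  }
  stats::cor(s$values_a, s$values_b)
}

#' Paired t-tests with a Bonferroni-adjusted threshold
#'
#' For each series, both raters' values are checked for normality with a
#' Shapiro-Wilk test (logged; a failed check warns but does not block the
#' t-test) and a two-sided paired Student's t-test is run. The
#' significance threshold is `overall_alpha / m`; with the default
#' `overall_alpha = 0.05` and `m = 4` hypotheses per parameter this gives
#' 0.0125. Zero-variance differences leave the p-value undefined
#' (flagged).
#'
#' @param series A [paired_series()] or list of them.
#' @param overall_alpha Family-wise error rate (default 0.05).
#' @param m Number of hypotheses per parameter (default 4).
#' @return Data frame with one row per series: parameter, n, bias,
#'   Shapiro-Wilk p-values, t-test p-value, the adjusted threshold and a
#'   significance flag.
#' @export
paired_tests <- function(series, overall_alpha = 0.05, m = 4) {
  if (inherits(series, "paired_series")) series <- list(series)
  threshold <- overall_alpha / m
  rows <- lapply(series, function(s) {
    d <- s$values_a - s$values_b
    sw <- function(v) {
      if (length(v) < 3 || stats::sd(v) == 0) return(NA_real_)
      stats::shapiro.test(v)$p.value
    }
    sw_a <- sw(s$values_a); sw_b <- sw(s$values_b)
    if ((!is.na(sw_a) && sw_a < 0.05) || (!is.na(sw_b) && sw_b < 0.05))
      warning(sprintf(
        "%s: Shapiro-Wilk rejects normality; paired t-test run regardless",
        s$parameter))
    degenerate <- stats::sd(d) == 0
    p <- if (degenerate) {
      warning(sprintf("%s: zero-variance differences, p-value undefined",
                      s$parameter))
      NA_real_
    } else stats::t.test(s$values_a, s$values_b, paired = TRUE)$p.value
    data.frame(parameter = s$parameter, n = length(d), bias = mean(d),
               shapiro_p_a = sw_a, shapiro_p_b = sw_b,
               t_p_value = p, threshold = threshold,
               significant = !is.na(p) & p < threshold,
               degenerate = degenerate)
  })
  do.call(rbind, rows)
}

#' Relative deviation of a bias from a reference mean, in percent
#'
#' `100 * |bias| / reference_mean`; e.g., a 2.35 ml bias at a mean of
#' 43.4 ml is a 5.4% deviation.
#'
#' @param bias Systematic difference between two methods.
#' @param reference_mean Mean value of the quantity (non-zero).
#' @return Percent deviation.
#' @export
relative_deviation <- function(bias, reference_mean) {
  if (reference_mean == 0)
    stop("reference mean is 0: relative deviation undefined", call. = FALSE)
  100 * abs(bias) / reference_mean
}

#' Full agreement statistics for one paired series
#'
#' Bundles Bland-Altman bias and limits, ICC, CoV, Pearson r, the paired
#' t-test (with Shapiro-Wilk gate) and n into one row.
#'
#' @inheritParams paired_tests
#' @param s A [paired_series()].
#' @return One-row data frame.
#' @export
agreement_stats <- function(s, overall_alpha = 0.05, m = 4) {
  ba <- bland_altman(s)
  tt <- suppressWarnings(paired_tests(s, overall_alpha, m))
  icc <- tryCatch(suppressWarnings(icc_absolute_agreement(s)),
                  error = function(e) NA_real_)
  cv <- cov_percent(s)
  r <- tryCatch(suppressWarnings(pearson_r(s)),
                error = function(e) NA_real_)
  data.frame(parameter = s$parameter, n = ba$n, bias = ba$bias,
             loa_low = ba$loa_low, loa_high = ba$loa_high,
             icc = as.numeric(icc), cov_percent = cv, pearson_r = r,
             t_p_value = tt$t_p_value, threshold = tt$threshold,
             significant = tt$significant)
}
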