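#' Bland-Altman limits of agreement
#'
#' Computes the mean difference, the sample SD of the paired differences
#' and the 95 percent limits of agreement `mean +/- 1.96 * SD`.  The
#' fixed 1.96 multiplier (no small-sample t correction) follows the
#' standard presentation of the method.
#'
#' @param values_a,values_b Paired measurements (same units, same order).
#' @param label_a,label_b Method names, carried into the report.
#' @return An object of class `bland_altman`: a list with `mean_diff`,
#'   `sd_diff`, `loa_halfwidth` (1.96 x SD), `loa_lower`, `loa_upper`,
#'   `n`, and per-pair `means` / `diffs` for plotting.
#' @examples
#' bland_altman(c(25, 30, 20), c(24, 33, 21))
#' @export
bland_altman <- function(values_a, values_b,
                         label_a = "method A", label_b = "method B") {
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) == length(values_b))
  if (length(values_a) < 2) {
    stop("Bland-Altman needs at least 2 pairs", call. = FALSE)
  }
  if (anyNA(values_a) || anyNA(values_b)) {
    stop("paired values must be complete", call. = FALSE)
  }
  d <- values_a - values_b
  m <- mean(d)
  s <- stats::sd(d)
  hw <- 1.96 * s
  structure(list(mean_diff = m, sd_diff = s, loa_halfwidth = hw,
                 loa_lower = m - hw, loa_upper = m + hw,
                 n = length(d), means = (values_a + values_b) / 2,
                 diffs = d, label_a = label_a, label_b = label_b),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> %s - %s: mean %.2f, LoA half-width %.2f [%.2f, %.2f], n = %d\n",
    x$label_a, x$label_b, x$mean_diff, x$loa_halfwidth,
    x$loa_lower, x$loa_upper, x$n))
  invisible(x)
}

#' Intraclass correlation coefficient
#'
#' ANOVA-based ICC for a complete subjects-by-measurements matrix.  The
#' default is the two-way random-effects, absolute-agreement,
#' single-measure coefficient ICC(2,1) — appropriate when raters or
#' occasions are a random sample and systematic offsets between them
#' should count against agreement, as in inter-observer and test-retest
#' reliability of a clinical measurement.  Consistency and one-way
#' variants, and average-measure units, are available.  Confidence
#' intervals are F-based (with a Satterthwaite approximation for the
#' agreement variants).
#'
#' @param ratings Numeric matrix: rows = subjects, columns =
#'   raters/occasions.  Must be complete (no `NA`).
#' @param model `"twoway"` (default) or `"oneway"`.
#' @param type `"agreement"` (default) or `"consistency"`; ignored for
#'   the one-way model.
#' @param unit `"single"` (default) or `"average"`.
#' @param conf_level Confidence level for the interval.
#' @return An object of class `icc_result`: a list with `icc`, `ci_low`,
#'   `ci_high`, `model`, `type`, `unit`, `n`, `k`, and the mean squares.
#' @examples
#' m <- cbind(c(9, 6, 8, 7, 10, 6), c(2, 1, 4, 1, 5, 2))
#' icc(m)
#' @export
icc <- function(ratings, model = c("twoway", "oneway"),
                type = c("agreement", "consistency"),
                unit = c("single", "average"),
                conf_level = 0.95) {
  model <- match.arg(model); type <- match.arg(type)
  unit <- match.arg(unit)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 columns", call. = FALSE)
  alpha <- 1 - conf_level

  grand <- mean(ratings)
  row_means <- rowMeans(ratings)
  col_means <- colMeans(ratings)
  ss_total <- sum((ratings - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ms_rows <- ss_rows / (n - 1)                       # between subjects
  ms_cols <- ss_cols / (k - 1)                       # between columns
  ms_err <- (ss_total - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  ms_within <- (ss_total - ss_rows) / (n * (k - 1))  # one-way residual

  if (model == "oneway") {
    r1 <- (ms_rows - ms_within) / (ms_rows + (k - 1) * ms_within)
    f_obs <- ms_rows / ms_within
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo1 <- (fl - 1) / (fl + k - 1)
    hi1 <- (fu - 1) / (fu + k - 1)
    est <- if (unit == "single") r1 else spearman_brown(r1, k)
    lo <- if (unit == "single") lo1 else spearman_brown(lo1, k)
    hi <- if (unit == "single") hi1 else spearman_brown(hi1, k)
  } else if (type == "consistency") {
    r1 <- (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
    f_obs <- ms_rows / ms_err
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo1 <- (fl - 1) / (fl + k - 1)
    hi1 <- (fu - 1) / (fu + k - 1)
    est <- if (unit == "single") r1 else spearman_brown(r1, k)
    lo <- if (unit == "single") lo1 else spearman_brown(lo1, k)
    hi <- if (unit == "single") hi1 else spearman_brown(hi1, k)
  } else {
    # two-way random effects, absolute agreement
    r1 <- (ms_rows - ms_err) /
      (ms_rows + (k - 1) * ms_err + (k / n) * (ms_cols - ms_err))
    a <- (k * r1) / (n * (1 - r1))
    b <- 1 + (k * r1 * (n - 1)) / (n * (1 - r1))
    v <- (a * ms_cols + b * ms_err)^2 /
      ((a * ms_cols)^2 / (k - 1) + (b * ms_err)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo1 <- n * (ms_rows - f_l * ms_err) /
      (f_l * (k * ms_cols + (k * n - k - n) * ms_err) + n * ms_rows)
    hi1 <- n * (f_u * ms_rows - ms_err) /
      (k * ms_cols + (k * n - k - n) * ms_err + n * f_u * ms_rows)
    if (unit == "single") {
      est <- r1; lo <- lo1; hi <- hi1
    } else {
      est <- (ms_rows - ms_err) / (ms_rows + (ms_cols - ms_err) / n)
      lo <- spearman_brown(lo1, k)
      hi <- spearman_brown(hi1, k)
    }
  }
  structure(list(icc = est, ci_low = lo, ci_high = hi,
                 model = model, type = type, unit = unit,
                 n = n, k = k,
                 ms = c(rows = ms_rows, cols = ms_cols, error = ms_err,
                        within = ms_within)),
            class = "icc_result")
}

spearman_brown <- function(r, k) k * r / (1 + (k - 1) * r)

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "<icc_result> ICC(%s %s, %s) = %.3f [%.3f, %.3f], n = %d, k = %d\n",
    x$model, x$type, x$unit, x$icc, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Pearson correlation of two measurement series
#'
#' Thin wrapper over the product-moment correlation with the input
#' checks the agreement battery needs.
#'
#' @param values_a,values_b Paired numeric vectors.
#' @return The correlation coefficient.
#' @export
pearson <- function(values_a, values_b) {
  stopifnot(is.numeric(values_a), is.numeric(values_b),
            length(values_a) == length(values_b), length(values_a) >= 2)
  if (anyNA(values_a) || anyNA(values_b)) {
    stop("paired values must be complete", call. = FALSE)
  }
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    stop("both series need nonzero variance", call. = FALSE)
  }
  stats::cor(values_a, values_b)
}

# round half away from zero (printed clinical tables round 0.05 up,
# unlike the IEC 754 banker's rounding of base round())
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Categorize between-method differences into clinical bins
#'
#' Bins absolute differences (prism diopters) into below `bounds[1]`,
#' between the bounds (closed on both ends), and above `bounds[2]`, and
#' reports counts with percentages.  Percentages are computed by
#' differencing half-up-rounded cumulative percentages, so the printed
#' values always sum to exactly 100.0 and cumulative fractions round
#' consistently.
#'
#' @param diffs_pd Differences between two methods, prism diopters (the
#'   sign is ignored).
#' @param bounds Two increasing bin boundaries, default `c(3, 5)`.
#' @return An object of class `diff_categories`: a data frame with
#'   `category`, `count`, `percent`, plus attributes `n` and
#'   `cum_percent` (cumulative percentages per bin).
#' @examples
#' categorize_differences(c(0.5, 2, -1, 4, 7))
#' @export
categorize_differences <- function(diffs_pd, bounds = c(3, 5)) {
  stopifnot(is.numeric(diffs_pd), all(is.finite(diffs_pd)),
            length(bounds) == 2, bounds[1] < bounds[2])
  a <- abs(diffs_pd)
  counts <- c(sum(a < bounds[1]),
              sum(a >= bounds[1] & a <= bounds[2]),
              sum(a > bounds[2]))
  category <- c(sprintf("< %g", bounds[1]),
                sprintf("%g-%g", bounds[1], bounds[2]),
                sprintf("> %g", bounds[2]))
  build_categories(counts, category)
}

#' @rdname categorize_differences
#' @param counts Pre-tabulated bin counts (ordered low to high), for
#'   reproducing a published table without the raw differences.
#' @param category Optional bin labels.
#' @export
bin_percentages <- function(counts, category = NULL) {
  stopifnot(is.numeric(counts), all(counts >= 0), sum(counts) > 0)
  if (is.null(category)) category <- paste0("bin", seq_along(counts))
  build_categories(counts, category)
}

build_categories <- function(counts, category) {
  n <- sum(counts)
  cum <- round_half_up(100 * cumsum(counts) / n, 1)
  percent <- diff(c(0, cum))
  out <- data.frame(category = category, count = as.integer(counts),
                    percent = percent)
  structure(out, n = n, cum_percent = cum,
            class = c("diff_categories", "data.frame"))
}

#' @export
print.diff_categories <- function(x, ...) {
  cat(sprintf("<diff_categories> n = %d\n", attr(x, "n")))
  df <- data.frame(category = x$category,
                   `n (%)` = sprintf("%d (%.1f)", x$count, x$percent),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Full agreement report between two methods
#'
#' Bundles the validation battery for a paired comparison: Bland-Altman
#' limits of agreement, ICC(2,1), Pearson correlation, and the
#' categorized-difference table.
#'
#' @param values_a,values_b Paired measurements (prism diopters).
#' @param label_a,label_b Method names.
#' @param bounds Category bounds for [categorize_differences()].
#' @return An object of class `agreement_report`: a list with elements
#'   `bland_altman`, `icc`, `pearson_r`, `categories`, `n`.
#' @export
agreement_report <- function(values_a, values_b,
                             label_a = "method A", label_b = "method B",
                             bounds = c(3, 5)) {
  ba <- bland_altman(values_a, values_b, label_a, label_b)
  structure(list(
    bland_altman = ba,
    icc = icc(cbind(values_a, values_b)),
    pearson_r = pearson(values_a, values_b),
    categories = categorize_differences(values_a - values_b, bounds),
    n = ba$n
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$bland_altman)
  print(x$icc)
  cat(sprintf("Pearson r = %.3f\n", x$pearson_r))
  print(x$categories)
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of pair differences against pair means with the mean
#' difference and the 95 percent limits of agreement as dashed lines.
#' Requires ggplot2.
#'
#' @param ba A [bland_altman()] result.
#' @param units Axis unit label.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba, units = "PD") {
  stopifnot(inherits(ba, "bland_altman"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- data.frame(mean = ba$means, diff = ba$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff, linetype = "solid") +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Mean of %s and %s (%s)", ba$label_a, ba$label_b, units),
      y = sprintf("%s - %s (%s)", ba$label_a, ba$label_b, units)) +
    ggplot2::theme_minimal()
}
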