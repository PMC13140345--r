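#' Summary of loading errors against a target
#'
#' Differences between measured percent-bodyweight loading and the target
#' level (e.g. 16.5 %BW for simulated lunar gravity), summarised over all
#' non-missing values.
#'
#' @param data A data frame of loading measurements.
#' @param loading Column of measured loading (%BW); tidy-selected.
#' @param target_pct Target loading, %BW (scalar), or a column in `data`
#'   selected with [dplyr::vars()]-style bare name via `target_col`.
#' @param target_col Optional bare column name holding per-row targets;
#'   overrides `target_pct`.
#' @return A one-row tibble: `n`, `mean_error`, `sd_error`, `min_error`,
#'   `max_error` (all %BW).
#' @examples
#' d <- tibble::tibble(loading = c(19.0, 17.1, 22.7))
#' error_summary(d, loading, target_pct = 16.5)
#' @export
error_summary <- function(data, loading, target_pct = NULL, target_col = NULL) {
  loading_vals <- dplyr::pull(data, {{ loading }})
  target_quo <- rlang::enquo(target_col)
  target_vals <- if (!rlang::quo_is_null(target_quo)) {
    dplyr::pull(data, !!target_quo)
  } else if (!is.null(target_pct)) {
    target_pct
  } else {
    abort("supply `target_pct` or `target_col`")
  }
  err <- loading_vals - target_vals
  err <- err[!is.na(err)]
  if (length(err) == 0) abort("no non-missing loading values")
  tibble::tibble(
    n = length(err),
    mean_error = mean(err),
    sd_error = if (length(err) > 1) sd(err) else 0,
    min_error = min(err),
    max_error = max(err)
  )
}

#' Bland-Altman agreement between two measurement occasions
#'
#' Classical agreement analysis for paired measurements: bias (mean
#' difference x - y), limits of agreement (LOA) at bias +/- 1.96 sd of the
#' differences (sample sd, n - 1), a t-based confidence interval for the
#' bias, and normal-theory confidence intervals for each LOA using
#' `se(LOA) = sd * sqrt(3 / n)` with a t(n - 1) quantile. Incomplete pairs
#' are dropped.
#'
#' @param data A data frame containing the two measurement columns.
#' @param x,y Columns to compare (tidy-selected); differences are `x - y`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `bland_altman`; see [tidy.bland_altman()],
#'   [glance.bland_altman()] and [autoplot.bland_altman()].
#' @examples
#' d <- tibble::tibble(v1 = c(17.6, 20.8, 19.3, 22.8), v2 = c(18.7, 19.1, 26.0, 17.6))
#' ba <- bland_altman(d, v1, v2)
#' tidy(ba)
#' @export
bland_altman <- function(data, x, y, conf = 0.95) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  n <- length(xv)
  if (n < 3) abort("need at least 3 complete pairs")
  d <- xv - yv
  bias <- mean(d)
  sd_d <- sd(d)
  if (sd_d == 0) warn("zero variance of differences: limits of agreement collapse onto the bias")
  z <- 1.96
  loa_upper <- bias + z * sd_d
  loa_lower <- bias - z * sd_d
  tq <- qt(1 - (1 - conf) / 2, df = n - 1)
  se_bias <- sd_d / sqrt(n)
  se_loa <- sd_d * sqrt(3 / n)
  structure(
    list(
      n = n, conf = conf, bias = bias, sd_diff = sd_d,
      loa_lower = loa_lower, loa_upper = loa_upper,
      ci_bias = bias + c(-1, 1) * tq * se_bias,
      ci_loa_lower = loa_lower + c(-1, 1) * tq * se_loa,
      ci_loa_upper = loa_upper + c(-1, 1) * tq * se_loa,
      pairs = tibble::tibble(mean = (xv + yv) / 2, diff = d)
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d complete pairs)\n", x$n))
  cat(sprintf("  bias %.2f [%.2f, %.2f]\n", x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LOA  %.2f [%.2f, %.2f] to %.2f [%.2f, %.2f]\n",
              x$loa_lower, x$ci_loa_lower[1], x$ci_loa_lower[2],
              x$loa_upper, x$ci_loa_upper[1], x$ci_loa_upper[2]))
  invisible(x)
}

#' Tidy a Bland-Altman analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return A tibble with one row per estimate (`bias`, `loa_lower`,
#'   `loa_upper`) and columns `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("bias", "loa_lower", "loa_upper"),
    estimate = c(x$bias, x$loa_lower, x$loa_upper),
    conf.low = c(x$ci_bias[1], x$ci_loa_lower[1], x$ci_loa_upper[1]),
    conf.high = c(x$ci_bias[2], x$ci_loa_lower[2], x$ci_loa_upper[2])
  )
}

#' @rdname tidy.bland_altman
#' @return `glance()`: a one-row tibble with `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `conf`.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 conf = x$conf)
}

icc_label <- function(icc) {
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' Two-way absolute-agreement intraclass correlation, single measures
#'
#' Reliability of repeated measurements (e.g. loading on separate visits)
#' via the two-way model with absolute agreement, single measures - ICC(A,1)
#' in the McGraw-Wong taxonomy. From the two-way ANOVA mean squares (rows =
#' subjects, columns = occasions):
#'
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#'
#' The confidence interval uses the standard F-based method with a
#' Satterthwaite degrees-of-freedom approximation, and the p-value tests
#' ICC = 0 via `F = MS_R / MS_E` on (n - 1, (n - 1)(k - 1)) df. Absolute
#' agreement penalises systematic occasion offsets: adding a constant to one
#' occasion only lowers the ICC, while adding it to every cell leaves the
#' ICC unchanged.
#'
#' @param data Long-format data frame: one measurement per row.
#' @param subject,rater,value Columns identifying the subject, the occasion
#'   (visit/rater) and the measurement (tidy-selected).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `icc_agreement` with fields `icc`, `ci`
#'   (length 2), `p_value`, `f_value`, `df1`, `df2`, `n`, `k`, `label`
#'   (qualitative: < 0.50 poor, 0.50-0.74 moderate, 0.75-0.90 good,
#'   >= 0.90 excellent) and `model_label`.
#' @examples
#' d <- sim_loading_table(n_participants = 12, seed = 1)
#' icc_agreement(d, participant, visit, loading_pct)
#' @export
icc_agreement <- function(data, subject, rater, value, conf = 0.95) {
  df <- dplyr::select(tibble::as_tibble(data),
                      subject = {{ subject }}, rater = {{ rater }},
                      value = {{ value }})
  if (any(is.na(df$value))) {
    abort("measurements contain missing values: extract complete cases first (tidyr::drop_na on a wide table)")
  }
  df$subject <- factor(df$subject)
  df$rater <- factor(df$rater)
  n <- nlevels(df$subject)
  k <- nlevels(df$rater)
  if (k < 2) abort("need at least 2 occasions/raters")
  if (n < 3) abort("need at least 3 subjects")
  if (nrow(df) != n * k) {
    abort("table must be complete: exactly one measurement per subject x occasion")
  }
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]

  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))

  alpha <- 1 - conf
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)

  f_value <- msr / mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(f_value, df1, df2, lower.tail = FALSE)

  structure(
    list(icc = icc, ci = c(lower, upper), conf = conf,
         p_value = p, f_value = f_value, df1 = df1, df2 = df2,
         n = n, k = k, label = icc_label(icc),
         model_label = "two-way mixed, absolute agreement, single measures",
         mean_squares = c(msr = msr, msc = msc, mse = mse)),
    class = "icc_agreement"
  )
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("ICC (%s)\n", x$model_label))
  cat(sprintf("  ICC = %.3f (%s), %d%% CI [%.3f, %.3f]\n",
              x$icc, x$label, round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("  F(%d, %d) = %.2f, p = %.2g  (n = %d subjects, k = %d occasions)\n",
              x$df1, x$df2, x$f_value, x$p_value, x$n, x$k))
  invisible(x)
}

#' Tidy an intraclass-correlation result
#'
#' @param x An `icc_agreement` object.
#' @param ... Unused.
#' @return `tidy()`: one row with `estimate`, `conf.low`, `conf.high`,
#'   `statistic`, `p.value`. `glance()`: one row adding `n`, `k`, `label`,
#'   `model`.
#' @export
tidy.icc_agreement <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci[1], conf.high = x$ci[2],
                 statistic = x$f_value, p.value = x$p_value)
}

#' @rdname tidy.icc_agreement
#' @export
glance.icc_agreement <- function(x, ...) {
  tibble::tibble(icc = x$icc, conf.low = x$ci[1], conf.high = x$ci[2],
                 p.value = x$p_value, n = x$n, k = x$k,
                 label = x$label, model = x$model_label)
}
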