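#' Bland-Altman agreement analysis
#'
#' For paired measurements, differences are taken as test minus reference
#' (`d = y - x`). Reports the bias (mean difference), the SD of the
#' differences, the 95% limits of agreement `bias +/- 1.96 * SD`, normal
#' approximation CIs (bias: `SE = SD / sqrt(n)`; each LOA:
#' `SE = SD * sqrt(3 / n)`), and the minimum detectable change
#' `MDC = 1.96 * SD`.
#'
#' @param x numeric vector of reference values.
#' @param y numeric vector of test values, same length.
#' @return A list with `n`, `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `ci_bias`, `ci_loa_low`, `ci_loa_high` (each length-2), `mdc`.
#' @export
bland_altman <- function(x, y) {
  d <- .paired_diff(x, y)
  n <- length(d)
  if (n < 2) stop("need at least 2 paired values", call. = FALSE)
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  se_loa <- s * sqrt(3 / n)
  list(n = n, bias = bias, sd_diff = s,
       loa_low = loa[1], loa_high = loa[2],
       ci_bias = bias + c(-1, 1) * 1.96 * s / sqrt(n),
       ci_loa_low = loa[1] + c(-1, 1) * 1.96 * se_loa,
       ci_loa_high = loa[2] + c(-1, 1) * 1.96 * se_loa,
       mdc = 1.96 * s)
}

.paired_diff <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must be the same length",
                                   call. = FALSE)
  y - x
}

#' Symmetric mean absolute percentage error (SMAPE)
#'
#' `SMAPE = (100 / n) * sum(|x - y| / (|x| + |y|))`, the bounded variant
#' ranging from 0% (identity) to 100% (maximal disagreement). Pairs with
#' `x = y = 0` contribute zero.
#'
#' @param x reference values (non-negative measures).
#' @param y test values.
#' @return Percentage in \[0, 100\].
#' @export
smape <- function(x, y) {
  .paired_diff(x, y)
  den <- abs(x) + abs(y)
  term <- ifelse(den == 0, 0, abs(x - y) / den)
  100 * mean(term)
}

#' Standardized absolute difference (SAD)
#'
#' `SAD = mean(|x - y|) / sqrt((s2_x + s2_y) / 2)`, the mean absolute
#' difference scaled by the root mean of the two sample variances. SAD is
#' unitless, direction-free, invariant to common positive rescaling, and
#' symmetric in x and y, enabling cross-measure comparison of dispersion.
#'
#' @inheritParams bland_altman
#' @return Non-negative scalar.
#' @export
sad <- function(x, y) {
  .paired_diff(x, y)
  if (length(x) < 2) stop("need at least 2 paired values", call. = FALSE)
  pooled <- (stats::var(x) + stats::var(y)) / 2
  if (pooled <= 0) stop("zero pooled variance: SAD undefined", call. = FALSE)
  mean(abs(x - y)) / sqrt(pooled)
}

#' Pearson correlation of paired measures
#'
#' @inheritParams bland_altman
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  .paired_diff(x, y)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Consistency intraclass correlation, two-way model, single measure
#'
#' ICC(C,1) for k = 2 raters (reference and test device) under a two-way
#' random-effects model: `(MS_rows - MS_error) / (MS_rows + MS_error)`
#' with participants as rows and devices as columns. Consistency ICC
#' ignores a fixed offset between devices; negative values are reported
#' as-is.
#'
#' @inheritParams bland_altman
#' @return ICC estimate (may be negative).
#' @export
icc_consistency <- function(x, y) {
  .paired_diff(x, y)
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  ms_rows <- ss_rows / (n - 1)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  if (ss_total == 0) stop("zero total variance: ICC undefined", call. = FALSE)
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err)
}

#' Cohen's d for paired differences
#'
#' Standardized difference `d = mean(y - x) / sd(y - x)`; the sign
#' follows the sign of the bias.
#'
#' @inheritParams bland_altman
#' @return Standardized effect size.
#' @export
cohen_d_paired <- function(x, y) {
  d <- .paired_diff(x, y)
  if (length(d) < 2) stop("need at least 2 pairs", call. = FALSE)
  s <- stats::sd(d)
  if (s == 0) stop("zero SD of differences: d undefined", call. = FALSE)
  mean(d) / s
}

#' Cohen's d for two independent groups
#'
#' `d = (mean(a) - mean(b)) / s_pooled` with the pooled SD
#' `s_pooled = sqrt(((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2))`.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return Standardized effect size.
#' @export
cohen_d_two_sample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values",
                                           call. = FALSE)
  cohen_d_from_stats(length(a), mean(a), stats::sd(a),
                     length(b), mean(b), stats::sd(b))
}

#' Cohen's d from printed group summaries
#'
#' Computes the two-sample pooled-SD effect size directly from reported
#' (n, mean, SD) triplets, as needed to check published tables.
#'
#' @param n1,m1,s1 size, mean and SD of group 1.
#' @param n2,m2,s2 size, mean and SD of group 2.
#' @return Standardized effect size.
#' @export
cohen_d_from_stats <- function(n1, m1, s1, n2, m2, s2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD: d undefined", call. = FALSE)
  (m1 - m2) / sp
}

#' Shapiro-Wilk normality check on paired differences
#'
#' Report-only check: the downstream agreement statistics are computed
#' either way (no correction is applied), but the flag records whether
#' the differences deviate from normality at the 5% level.
#'
#' @inheritParams bland_altman
#' @return List with `statistic` (W), `p_value`, `non_normal` flag.
#' @export
normality_check <- function(x, y) {
  d <- .paired_diff(x, y)
  if (length(d) < 3 || length(d) > 5000) {
    stop("Shapiro-Wilk supports 3 <= n <= 5000", call. = FALSE)
  }
  sw <- stats::shapiro.test(d)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       non_normal = sw$p.value < 0.05)
}

#' Classify the magnitude of a standardized difference
#'
#' Applied to Cohen's d or SAD on the absolute value:
#' `< 0.1` negligible, `[0.1, 0.3)` small, `[0.3, 0.5)` moderate,
#' `>= 0.5` large.
#'
#' @param v standardized (dimensionless) value, finite.
#' @return One of `"negligible"`, `"small"`, `"moderate"`, `"large"`.
#' @export
classify_magnitude <- function(v) {
  stopifnot(is.finite(v))
  a <- abs(v)
  if (a < 0.1) "negligible"
  else if (a < 0.3) "small"
  else if (a < 0.5) "moderate"
  else "large"
}

# interscorer-reliability thresholds for satisfactory summary agreement
.summary_icc_thresholds <- c(WASO = 0.84, REM = 0.75, NREM = 0.65,
                             LS = 0.67, DS = 0.63)

#' Satisfactory-agreement flag for a sleep summary measure
#'
#' Compares a consistency ICC to the interscorer-reliability threshold
#' for that measure (WASO 0.84, REM 0.75, NREM 0.65, LS 0.67, DS 0.63);
#' agreement is satisfactory when the ICC strictly exceeds the threshold.
#'
#' @param measure_name one of `"WASO"`, `"REM"`, `"NREM"`, `"LS"`, `"DS"`.
#' @param icc consistency ICC of device vs reference.
#' @return Logical.
#' @export
is_satisfactory_summary <- function(measure_name, icc) {
  if (!measure_name %in% names(.summary_icc_thresholds)) {
    stop("no satisfactory-agreement threshold for measure ", measure_name,
         call. = FALSE)
  }
  icc > .summary_icc_thresholds[[measure_name]]
}

#' Full agreement report for one paired measure
#'
#' Bundles the Bland-Altman family with the standardized metrics and the
#' satisfactory flag (where a threshold exists) into one row.
#'
#' @inheritParams bland_altman
#' @param measure_name measure tag (TST, SOL, WASO, SEFF, AP, REM, NREM,
#'   LS, DS, ...).
#' @return A one-row [tibble::tibble].
#' @export
agreement_report <- function(x, y, measure_name = NA_character_) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  ba <- bland_altman(x, y)
  icc <- tryCatch(icc_consistency(x, y), error = function(e) NA_real_)
  rho <- tryCatch(pearson(x, y), error = function(e) NA_real_)
  dd <- tryCatch(cohen_d_paired(x, y), error = function(e) NA_real_)
  nrm <- tryCatch(normality_check(x, y),
                  error = function(e) list(p_value = NA_real_,
                                           non_normal = NA))
  sat <- if (!is.na(measure_name) &&
             measure_name %in% names(.summary_icc_thresholds) && !is.na(icc)) {
    is_satisfactory_summary(measure_name, icc)
  } else NA
  tibble::tibble(
    measure = measure_name, n = ba$n, bias = ba$bias, sd_diff = ba$sd_diff,
    loa_low = ba$loa_low, loa_high = ba$loa_high,
    ci_bias_low = ba$ci_bias[1], ci_bias_high = ba$ci_bias[2],
    mdc = ba$mdc, rho = rho, icc = icc, cohen_d = dd,
    smape = smape(x, y), sad = sad(x, y),
    normality_p = nrm$p_value, non_normal = nrm$non_normal,
    satisfactory = sat)
}
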