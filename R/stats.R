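# Reliability and discrimination statistics used to validate the thrust
# index: Cohen's d (pooled SD), unpaired t-tests from raw samples or printed
# summary statistics, ICC(1,1), Pearson correlation, empirical ROC with the
# Youden cutoff, closed-form binormal AUC, and standardized-beta OLS.

#' Cohen's d from group summary statistics (pooled SD)
#'
#' `|m1 - m2| / sp` with the classic pooled standard deviation
#' `sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`. Reported unsigned,
#' and symmetric in group order.
#'
#' @param m1,s1,n1 Mean, sample SD (n-1 denominator) and size of group 1.
#' @param m2,s2,n2 Likewise for group 2.
#' @return Cohen's d (non-negative scalar).
#' @export
cohen_d_pooled <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group", call. = FALSE)
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative", call. = FALSE)
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("pooled SD is zero: effect size undefined", call. = FALSE)
  abs(m1 - m2) / sqrt(sp2)
}

.group_comparison <- function(m1, s1, n1, m2, s2, n2,
                              labels = c("group1", "group2")) {
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance: t-test undefined", call. = FALSE)
  df <- n1 + n2 - 2
  t_stat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(
    labels = labels, n1 = n1, n2 = n2, m1 = m1, m2 = m2, s1 = s1, s2 = s2,
    t_stat = t_stat, df = df,
    p_value = 2 * stats::pt(-abs(t_stat), df),
    cohen_d = abs(m1 - m2) / sqrt(sp2)
  ), class = "group_comparison")
}

#' Unpaired Student's t-test with effect size
#'
#' Pooled-variance (Student) two-sided t-test between two independent
#' samples, with the pooled-SD Cohen's d. `unpaired_t_from_summary()` is
#' the same test computed from printed means, SDs and group sizes, which is
#' algebraically identical to the raw-sample version evaluated at the
#' sample's own summaries.
#'
#' @param sample1,sample2 Numeric vectors, each of length at least 2.
#' @param labels Group labels (length 2).
#' @return An object of class `group_comparison` with elements `n1`, `n2`,
#'   `m1`, `m2`, `s1`, `s2`, `t_stat`, `df`, `p_value` and `cohen_d`.
#' @export
unpaired_t <- function(sample1, sample2, labels = c("group1", "group2")) {
  if (length(sample1) < 2L || length(sample2) < 2L) {
    stop("need at least 2 observations per group", call. = FALSE)
  }
  .group_comparison(mean(sample1), stats::sd(sample1), length(sample1),
                    mean(sample2), stats::sd(sample2), length(sample2),
                    labels = labels)
}

#' @rdname unpaired_t
#' @inheritParams cohen_d_pooled
#' @export
unpaired_t_from_summary <- function(m1, s1, n1, m2, s2, n2,
                                    labels = c("group1", "group2")) {
  if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group", call. = FALSE)
  .group_comparison(m1, s1, n1, m2, s2, n2, labels = labels)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Unpaired t-test: %s (n=%d, %.4g +/- %.4g) vs %s (n=%d, %.4g +/- %.4g)\n",
              x$labels[1L], x$n1, x$m1, x$s1, x$labels[2L], x$n2, x$m2, x$s2))
  cat(sprintf("  t = %.3f, df = %d, p = %.4g, Cohen's d = %.3f\n",
              x$t_stat, x$df, x$p_value, x$cohen_d))
  invisible(x)
}

#' Intraclass correlation ICC(1,1)
#'
#' One-way random-effects, single-measurement intraclass correlation for
#' test-retest reliability across two sessions:
#' `(BMS - WMS) / (BMS + (k - 1) WMS)` with k = 2, where BMS and WMS are
#' the between- and within-subject mean squares of the one-way ANOVA on the
#' n x 2 table. Negative estimates are reported as-is, not truncated.
#'
#' @param day1,day2 Paired measurements, one value per subject.
#' @return An object of class `icc_result` with elements `icc`, `bms`,
#'   `wms`, `n_subjects`, `k`.
#' @export
icc_1_1 <- function(day1, day2) {
  if (length(day1) != length(day2)) stop("sessions must have equal length", call. = FALSE)
  n <- length(day1)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (any(!is.finite(day1)) || any(!is.finite(day2))) {
    stop("non-finite values in ICC input", call. = FALSE)
  }
  k <- 2L
  x <- cbind(day1, day2)
  rowm <- rowMeans(x)
  gm <- mean(x)
  bms <- k * sum((rowm - gm)^2) / (n - 1)
  wms <- sum((x - rowm)^2) / (n * (k - 1))
  structure(list(icc = (bms - wms) / (bms + (k - 1) * wms),
                 bms = bms, wms = wms, n_subjects = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f  (n = %d subjects, k = %d sessions)\n",
              x$icc, x$n_subjects, x$k))
  if (x$icc < 0) cat("  note: negative estimate reported as-is (not truncated)\n")
  invisible(x)
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation; the p-value comes from the t transform with
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return A list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Empirical ROC curve with the Youden cutoff
#'
#' Thresholds are the midpoints between consecutive distinct pooled values
#' plus -Inf/+Inf sentinels; a case is called positive when its value is at
#' or above the threshold (orientation: larger value, more likely
#' positive). The AUC is the trapezoid over the empirical curve, which
#' equals the Mann-Whitney statistic U/(n1*n2) with ties counted 0.5. The
#' Youden cutoff maximizes J = sensitivity + specificity - 1; ties are
#' broken toward larger specificity, then toward the smaller threshold.
#'
#' @param values_positive Index values of the positive class.
#' @param values_negative Index values of the negative class.
#' @return An object of class `roc_result`: `thresholds` (decreasing),
#'   `sensitivity`, `specificity`, `auc`, `youden_cutoff`, `youden_j`,
#'   `sens_at_cutoff`, `spec_at_cutoff`, `degenerate`.
#' @export
roc_with_youden <- function(values_positive, values_negative) {
  if (!length(values_positive) || !length(values_negative)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  pos <- as.numeric(values_positive)
  neg <- as.numeric(values_negative)
  v <- sort(unique(c(pos, neg)))
  mids <- if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2 else numeric()
  thresholds <- c(Inf, rev(mids), -Inf)            # decreasing
  sens <- vapply(thresholds, function(th) mean(pos >= th), numeric(1L))
  spec <- vapply(thresholds, function(th) mean(neg < th), numeric(1L))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1L) + utils::tail(sens, -1L)) / 2)
  j <- sens + spec - 1
  finite <- is.finite(thresholds)
  degenerate <- !any(finite)
  if (degenerate) {
    cutoff <- NA_real_; jmax <- 0; s_at <- NA_real_; sp_at <- NA_real_
  } else {
    jmax <- max(j[finite])
    cand <- which(finite & j == jmax)
    cand <- cand[spec[cand] == max(spec[cand])]
    pick <- cand[which.min(thresholds[cand])]
    cutoff <- thresholds[pick]
    s_at <- sens[pick]
    sp_at <- spec[pick]
  }
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, auc = auc, youden_cutoff = cutoff,
                 youden_j = jmax, sens_at_cutoff = s_at,
                 spec_at_cutoff = sp_at, degenerate = degenerate,
                 n_positive = length(pos), n_negative = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f  (n+ = %d, n- = %d)\n",
              x$auc, x$n_positive, x$n_negative))
  if (x$degenerate) {
    cat("  degenerate: all values identical, cutoff undefined\n")
  } else {
    cat(sprintf("  Youden cutoff = %.4g (J = %.3f): sensitivity %.1f%%, specificity %.1f%%\n",
                x$youden_cutoff, x$youden_j, 100 * x$sens_at_cutoff,
                100 * x$spec_at_cutoff))
  }
  invisible(x)
}

#' Closed-form binormal AUC
#'
#' Under normal within-group distributions the AUC of a threshold
#' classifier is `pnorm(|m1 - m2| / sqrt(s1^2 + s2^2))`. Used as a
#' consistency check between printed group summaries and printed empirical
#' AUCs.
#'
#' @param m1,s1 Mean and SD of one group.
#' @param m2,s2 Mean and SD of the other group.
#' @return AUC in `[0.5, 1]`.
#' @export
binormal_auc <- function(m1, s1, m2, s2) {
  if (s1^2 + s2^2 <= 0) stop("need s1^2 + s2^2 > 0", call. = FALSE)
  stats::pnorm(abs(m1 - m2) / sqrt(s1^2 + s2^2))
}

#' Standardized-beta ordinary least squares
#'
#' Z-scores the outcome and every predictor (binary group indicators should
#' be coded 0/1 beforehand), fits OLS, and reports per-predictor
#' standardized coefficients with two-sided p-values from the t
#' distribution with n - p - 1 degrees of freedom.
#'
#' @param outcome Numeric response.
#' @param predictors Data frame of numeric predictor columns.
#' @return A list with `coefficients` (data frame: `predictor`, `beta`,
#'   `t`, `p_value`), `r_squared`, `df_residual`.
#' @export
ols_standardized_beta <- function(outcome, predictors) {
  predictors <- as.data.frame(predictors)
  n <- length(outcome)
  p <- ncol(predictors)
  if (n <= p + 1L) stop("need more observations than predictors + 1", call. = FALSE)
  zs <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("constant column: rank deficient", call. = FALSE)
    (v - mean(v)) / s
  }
  dat <- data.frame(.y = zs(outcome), lapply(predictors, zs))
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients[-1L, , drop = FALSE]
  list(coefficients = data.frame(predictor = rownames(co),
                                 beta = unname(co[, 1L]),
                                 t = unname(co[, 3L]),
                                 p_value = unname(co[, 4L]),
                                 stringsAsFactors = FALSE),
       r_squared = sm$r.squared,
       df_residual = fit$df.residual)
}
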