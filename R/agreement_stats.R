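#' Intraclass correlation coefficient (single rater)
#'
#' Single-rater ICC from the ANOVA mean squares of an n-subjects-by-k-raters
#' table, for the three classical models:
#' * `oneway_random`: ICC(1,1), one-way random effects;
#' * `twoway_random`: ICC(2,1), two-way random effects, absolute agreement;
#' * `twoway_mixed_consistency`: ICC(3,1), two-way mixed effects,
#'   consistency of agreement (insensitive to a fixed rater offset).
#'
#' @param x numeric matrix (subjects x raters) or first rater's vector.
#' @param y second rater's vector when `x` is a vector.
#' @param model ICC model (see above); default is the consistency model.
#' @return Object of class `icc`: list with `value`, `model`, `label`,
#'   `n`, `k`, and `low_variance` (TRUE when between-subject variance is
#'   not above residual variance, in which case the value is <= 0).
#' @examples
#' a <- c(10, 12, 14, 16, 18)
#' icc(a, a + 3, model = "twoway_mixed_consistency")$value  # exactly 1
#' @export
icc <- function(x, y = NULL,
                model = c("twoway_mixed_consistency", "oneway_random",
                          "twoway_random")) {
  model <- match.arg(model)
  m <- if (is.null(y)) as.matrix(x) else cbind(as.matrix(x), y)
  if (!is.numeric(m) || any(!is.finite(m))) stopf("ratings must be finite numeric")
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stopf("need >= 3 paired observations, got %d", n)
  if (k < 2L) stopf("need >= 2 raters, got %d", k)
  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ss_total <- sum((m - gm)^2)
  ss_rows <- k * sum((rowm - gm)^2)
  ss_cols <- n * sum((colm - gm)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  bms <- ss_rows / (n - 1)                      # between subjects
  jms <- ss_cols / (k - 1)                      # between raters
  ems <- ss_err / ((n - 1) * (k - 1))           # residual
  wms <- (ss_total - ss_rows) / (n * (k - 1))   # within subjects
  value <- switch(model,
    oneway_random = (bms - wms) / (bms + (k - 1) * wms),
    twoway_random = (bms - ems) /
      (bms + (k - 1) * ems + k * (jms - ems) / n),
    twoway_mixed_consistency = (bms - ems) / (bms + (k - 1) * ems))
  label <- switch(model,
    oneway_random = "ICC(1,1) one-way random",
    twoway_random = "ICC(2,1) two-way random, absolute agreement",
    twoway_mixed_consistency = "ICC(3,1) two-way mixed, consistency")
  low <- !is.nan(value) && value <= 0
  if (low) warning("between-subject variance does not exceed error variance; ICC <= 0")
  structure(list(value = value, model = model, label = label,
                 n = n, k = k, low_variance = low), class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("%s = %.4f  (n = %d subjects, k = %d raters)\n",
              x$label, x$value, x$n, x$k))
  invisible(x)
}

#' Bland-Altman analysis
#'
#' Paired-difference bias with limits of agreement
#' `bias +/- multiplier * SD` (default multiplier 1.96, the 95% limits).
#'
#' @param a,b equal-length paired measurement vectors (`a - b` is the
#'   difference analysed).
#' @param multiplier LOA multiplier (default 1.96).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, `multiplier`, plus the per-pair `means` and `diffs`.
#' @export
bland_altman <- function(a, b, multiplier = 1.96) {
  if (length(a) != length(b))
    stopf("paired vectors differ in length: %d vs %d", length(a), length(b))
  if (length(a) < 2L) stopf("need >= 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - multiplier * s,
                 loa_high = bias + multiplier * s,
                 n = length(a), multiplier = multiplier,
                 means = (a + b) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, SD %.4g, LOA [%.4g, %.4g]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ..., xlab = "Mean of methods",
                              ylab = "Difference") {
  graphics::plot(x$means, x$diffs, xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = "firebrick")
  invisible(x)
}

#' Ordinary least-squares fit of paired measurements
#'
#' Least-squares slope and intercept of `y ~ x` with the Pearson
#' correlation coefficient.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list with `slope`, `intercept`, `pearson_r`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3L) stopf("need >= 3 pairs")
  if (stats::sd(x) == 0) stopf("zero variance in x",
                               class = "pvloopr_degenerate_input")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(x, y), n = length(x))
}

#' Paired two-sample comparison
#'
#' Thin wrapper over [stats::t.test()] (paired) and [stats::wilcox.test()]
#' (paired, signed rank) for pipeline completeness. Degenerate inputs
#' (all differences equal) are flagged rather than raised.
#'
#' @param a,b paired numeric vectors, n >= 3.
#' @param kind `"t"` or `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `kind`, `degenerate`.
#' @export
paired_compare <- function(a, b, kind = c("t", "wilcoxon")) {
  kind <- match.arg(kind)
  if (length(a) != length(b)) stopf("paired vectors differ in length")
  if (length(a) < 3L) stopf("need >= 3 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(statistic = if (all(d == 0)) 0 else sign(mean(d)) * Inf,
                p_value = NA_real_, kind = kind, degenerate = TRUE))
  }
  res <- if (kind == "t") stats::t.test(a, b, paired = TRUE)
         else suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       kind = kind, degenerate = FALSE)
}

#' Full method-agreement report for one metric
#'
#' The comparison battery applied to paired measurements of one quantity
#' by two methods (or raters): Pearson r, ICC, OLS slope/intercept, and
#' Bland-Altman bias with limits of agreement.
#'
#' @param est,ref paired vectors: estimated (new method) and reference.
#' @param icc_model ICC model passed to [icc()].
#' @param multiplier LOA multiplier passed to [bland_altman()].
#' @return Object of class `agreement_report` (named list; see fields of
#'   the printed output).
#' @export
agreement <- function(est, ref, icc_model = "twoway_mixed_consistency",
                      multiplier = 1.96) {
  o <- ols_fit(ref, est)
  ic <- icc(cbind(est, ref), model = icc_model)
  ba <- bland_altman(est, ref, multiplier = multiplier)
  structure(list(n = length(est), pearson_r = o$pearson_r,
                 icc = ic$value, icc_model = ic$label,
                 ols_slope = o$slope, ols_intercept = o$intercept,
                 bias = ba$bias, sd_diff = ba$sd_diff,
                 loa_low = ba$loa_low, loa_high = ba$loa_high),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("Agreement (n = %d): r = %.3f, ICC = %.3f [%s]\n",
                     "  y = %.3f x + %.4g; bias %.4g, SD %.4g, LOA [%.4g, %.4g]\n"),
              x$n, x$pearson_r, x$icc, x$icc_model, x$ols_slope,
              x$ols_intercept, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Agreement table across several metrics
#'
#' One [agreement()] row per shared numeric column of two data frames of
#' paired per-beat (or per-patient) metrics.
#'
#' @param est_df,ref_df data frames with identical row order (one row per
#'   beat/patient) and shared metric columns.
#' @param metrics columns to compare; default all shared numeric columns.
#' @inheritParams agreement
#' @return data.frame, one row per metric, columns per agreement report.
#' @export
agreement_table <- function(est_df, ref_df, metrics = NULL,
                            icc_model = "twoway_mixed_consistency",
                            multiplier = 1.96) {
  metrics <- metrics %||% intersect(names(est_df), names(ref_df))
  metrics <- metrics[vapply(metrics, function(m)
    is.numeric(est_df[[m]]) && is.numeric(ref_df[[m]]), logical(1))]
  if (!length(metrics)) stopf("no shared numeric metric columns")
  rows <- lapply(metrics, function(m) {
    r <- agreement(est_df[[m]], ref_df[[m]], icc_model = icc_model,
                   multiplier = multiplier)
    data.frame(metric = m, as.data.frame(unclass(r)[setdiff(names(r), "icc_model")]))
  })
  do.call(rbind, rows)
}
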