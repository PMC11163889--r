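# Cohort-level statistics: stratification, LOESS growth curves, trend
# regression, sex comparison, percent change, and intra/inter-operator ICC.

#' Stratify per-disk records into a cohort table
#'
#' Joins per-disk morphometry records with scan-level age and sex, and
#' assigns each row its spinal level group (upper/mid/low-thoracic, lumbar)
#' and SRS age group (infantile 0--3, juvenile 4--10, adolescent 11--18,
#' applied to whole years).
#'
#' @param records Data frame of per-disk measurements with `scan_id` and
#'   `level_index` columns (see [measure_disc()]).
#' @param manifest Cohort manifest with `scan_id`, `age_years`, `sex`.
#' @param n_levels Disk levels per scan (for the level-group mapping).
#' @return A `cohort_table` data frame: records plus `age_years`, `sex`,
#'   `level_group`, `age_group`.
#' @export
stratify <- function(records, manifest, n_levels = 17) {
  stopifnot(all(c("scan_id", "level_index") %in% names(records)),
            all(c("scan_id", "age_years", "sex") %in% names(manifest)))
  if (any(manifest$age_years < 0 | manifest$age_years > 18))
    stop("age_years must lie in [0, 18]")
  keep <- c("scan_id", "age_years", "sex")
  tab <- merge(records, manifest[, keep], by = "scan_id", sort = FALSE)
  tab$level_group <- level_group_of(tab$level_index, n_levels)
  tab$age_group <- age_group_of(tab$age_years)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' LOESS growth-curve fit
#'
#' Locally estimated scatterplot smoothing: a tricube-weighted local
#' polynomial of the given degree, fitted with the `span` fraction of
#' nearest neighbours (Cleveland's LOESS via [stats::loess()], with direct
#' surface evaluation so predictions at arbitrary query points are exact
#' local fits, not interpolations).
#'
#' @param x,y Predictor and response vectors.
#' @param span Neighbourhood fraction in (0, 1].
#' @param degree Local polynomial degree (1 or 2).
#' @param query Points at which to evaluate the fit (default `x`).
#' @return A `loess_fit` object: list with `model`, `x`, `y`, `span`,
#'   `degree`, `query`, `fitted` (values at `query`).
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1, query = x) {
  stopifnot(length(x) == length(y), span > 0, span <= 1, degree %in% 1:2)
  if (length(x) < degree + 2)
    stop("need at least degree + 2 points for a local fit")
  df <- data.frame(x = x, y = y)
  model <- stats::loess(y ~ x, data = df, span = span, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
  fitted <- as.numeric(stats::predict(model, newdata = data.frame(x = query)))
  if (any(!is.finite(fitted))) stop("LOESS produced non-finite fitted values")
  structure(list(model = model, x = x, y = y, span = span, degree = degree,
                 query = query, fitted = fitted),
            class = "loess_fit")
}

#' @rdname loess_fit
#' @param fit A `loess_fit`.
#' @param at Points at which to predict.
#' @export
predict_loess <- function(fit, at) {
  as.numeric(stats::predict(fit$model, newdata = data.frame(x = at)))
}

#' Percent change along a fitted growth curve
#'
#' Reports the fitted value at `age1` as a percentage of the fitted value at
#' `age0` (so a curve growing from 100 to 460 mm^2 yields 460%: "the increase
#' was 460%" means the final value is 4.6 times the initial one, not +460
#' percentage points).
#'
#' @param fit A [loess_fit()].
#' @param age0,age1 Ages bounding the change (defaults 0 and 18).
#' @return Percentage (100 * fit(age1) / fit(age0)).
#' @export
percent_change <- function(fit, age0 = 0, age1 = 18) {
  v0 <- predict_loess(fit, age0)
  v1 <- predict_loess(fit, age1)
  if (!is.finite(v0) || v0 <= 0) stop("fitted value at age0 must be positive")
  100 * v1 / v0
}

#' Two-way random-effects ICC (absolute agreement, single measure)
#'
#' Intraclass correlation from the two-way ANOVA mean-squares decomposition
#' (items crossed with raters, both random), quantifying absolute agreement
#' of single measurements -- the standard model for intra- and inter-operator
#' segmentation reliability. The 95% confidence interval uses the
#' F-distribution bounds of McGraw & Wong's ICC(A,1).
#'
#' @param m Numeric matrix, items in rows, raters/sessions in columns.
#' @param conf_level Confidence level (default 0.95).
#' @return An `icc_result`: list with `estimate`, `lower`, `upper`, `model`.
#' @export
icc_two_way <- function(m, conf_level = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 items and 2 raters")
  if (anyNA(m)) stop("missing cells are not supported")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST <= .Machine$double.eps) stop("zero total variance; ICC is undefined")
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- max(SSE / ((n - 1) * (k - 1)), 0)
  est <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  if (MSE <= .Machine$double.eps && MSC <= .Machine$double.eps) {
    lower <- upper <- est  # perfect agreement: no error variance to bound
  } else {
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    Fl <- stats::qf(1 - alpha / 2, n - 1, v)
    lower <- n * (MSR - Fl * MSE) /
      (Fl * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    Fu <- stats::qf(1 - alpha / 2, v, n - 1)
    upper <- n * (Fu * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fu * MSR)
  }
  structure(list(estimate = est, lower = min(lower, est), upper = max(upper, est),
                 model = "two-way random, absolute agreement, single measure",
                 conf_level = conf_level),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f (%.0f%% CI %.3f-%.3f), %s\n", x$estimate,
              100 * x$conf_level, x$lower, x$upper, x$model))
  invisible(x)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with two-sided p-value; used for the post hoc
#' comparison of mid-thoracic disk slenderness between boys and girls aged
#' 9 to 13.
#'
#' @param a,b Numeric samples (each of length >= 2).
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Age-trend regression
#'
#' Ordinary least-squares regression of a morphometric outcome on age,
#' optionally adjusted for sex (sex enters as an indicator; its coefficient
#' tests the male-female difference at fixed age).
#'
#' @param table A `cohort_table` (or any data frame with `age_years`, `sex`
#'   and the outcome).
#' @param outcome Name of the outcome column.
#' @param adjust_for_sex Add a sex term?
#' @return A `trend_result`: list with `slope`, `intercept`, `se`, `p`
#'   (age coefficient), and `sex_coef`, `sex_p` when adjusted.
#' @export
trend_fit <- function(table, outcome, adjust_for_sex = FALSE) {
  stopifnot(outcome %in% names(table))
  if (length(unique(table$age_years)) < 2) stop("age is constant; no trend to fit")
  fm <- if (adjust_for_sex) stats::as.formula(paste(outcome, "~ age_years + sex"))
        else stats::as.formula(paste(outcome, "~ age_years"))
  fit <- stats::lm(fm, data = table)
  sm <- summary(fit)$coefficients
  out <- list(slope = sm["age_years", 1], intercept = sm["(Intercept)", 1],
              se = sm["age_years", 2], p = sm["age_years", 4])
  if (adjust_for_sex) {
    sexrow <- grep("^sex", rownames(sm))
    out$sex_coef <- sm[sexrow, 1]
    out$sex_p <- sm[sexrow, 4]
  }
  structure(out, class = "trend_result")
}
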