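#' Cronbach's alpha for a participants-by-items score matrix
#'
#' Internal consistency of the six activity items:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(item sums))`. Alpha can
#' be negative when items covary negatively.
#'
#' @param items Numeric matrix or data frame, one column per item, one row
#'   per participant (weekly-minute scores here, but any metric works).
#' @return A one-row tibble: `alpha`, `k` (items), `n` (participants).
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1.2, 1.9, 3.1, 4.1))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(items) {
  m <- as.matrix(items)
  if (!is.numeric(m)) abort("`items` must be numeric.")
  m <- m[complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  n <- nrow(m)
  if (k < 2) abort("Cronbach's alpha needs at least 2 items.")
  if (n < 3) abort("Cronbach's alpha needs at least 3 participants.")
  total_var <- var(rowSums(m))
  if (total_var <= .Machine$double.eps) {
    abort("Total score variance is zero; alpha is undefined.")
  }
  alpha <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / total_var)
  tibble(alpha = alpha, k = k, n = n)
}

#' Intraclass correlation coefficient (single measures)
#'
#' Variance-components ICC from the two-way mean squares of an n subjects by
#' k ratings table. `"consistency"` is the two-way mixed-effects,
#' consistency-of-single-measures coefficient; `"agreement"` the two-way
#' random-effects absolute-agreement coefficient (which also charges rating
#' mean differences to disagreement). Confidence intervals use the standard
#' F-distribution constructions.
#'
#' @param ratings Numeric matrix/data frame, subjects x ratings (k >= 2).
#' @param model `"consistency"` (default) or `"agreement"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `icc`, `lower`, `upper`, `model`, `n`, `k`.
#' @examples
#' set.seed(1)
#' a <- rnorm(50); icc(cbind(a, a + rnorm(50, sd = 0.5)))
#' @export
icc <- function(ratings, model = c("consistency", "agreement"),
                conf_level = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(ratings)
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  if (k < 2) abort("ICC needs at least 2 ratings per subject.")
  if (n < 3) abort("ICC needs at least 3 subjects.")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps && mse <= .Machine$double.eps) {
    abort("Degenerate ratings: no between- or within-subject variance.")
  }
  alpha <- 1 - conf_level
  if (model == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- fobs / qf(1 - alpha / 2, df1, df2)
    fu <- fobs * qf(1 - alpha / 2, df2, df1)
    lower <- (fl - 1) / (fl + k - 1)
    upper <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    # Satterthwaite df for the rating-variance component (McGraw & Wong)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  }
  tibble(icc = est, lower = lower, upper = upper, model = model, n = n, k = k)
}

#' Qualitative labels for correlation and kappa coefficients
#'
#' Five-level classification scales used throughout the validity reporting.
#' For correlations: weak (<= 0.20), fair (0.21-0.40), moderate (0.41-0.60),
#' good (0.61-0.80), very good (> 0.80). For kappa: slight, fair, moderate,
#' substantial, almost perfect over the same boundaries.
#'
#' @param r,kappa Coefficient value(s).
#' @param boundaries Upper bounds of the first four classes.
#' @return Character vector of labels.
#' @examples
#' correlation_label(c(0.31, 0.60, 0.61))
#' kappa_label(0.50)
#' @export
correlation_label <- function(r, boundaries = c(0.20, 0.40, 0.60, 0.80)) {
  labs <- c("weak", "fair", "moderate", "good", "very good")
  labs[findInterval(r, boundaries, left.open = TRUE) + 1L]
}

#' @rdname correlation_label
#' @export
kappa_label <- function(kappa, boundaries = c(0.20, 0.40, 0.60, 0.80)) {
  labs <- c("slight", "fair", "moderate", "substantial", "almost perfect")
  labs[findInterval(kappa, boundaries, left.open = TRUE) + 1L]
}

#' Correlation between test and criterion, with qualitative label
#'
#' @param test,criterion Paired numeric vectors (questionnaire and
#'   accelerometer MVPA, typically).
#' @param method `"pearson"` or `"spearman"`.
#' @param conf_level Confidence level for the Pearson CI (Fisher z); the
#'   Spearman CI uses the same construction on the rank correlation.
#' @return One-row tibble: `estimate`, `lower`, `upper`, `method`, `label`,
#'   `n`.
#' @export
validity_correlation <- function(test, criterion,
                                 method = c("pearson", "spearman"),
                                 conf_level = 0.95) {
  method <- match.arg(method)
  ok <- complete.cases(test, criterion)
  x <- test[ok]
  y <- criterion[ok]
  n <- length(x)
  if (n < 3) abort("Correlation needs at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Constant input: correlation is undefined.")
  }
  r <- if (method == "pearson") cor(x, y) else cor(rank(x), rank(y))
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  se <- 1 / sqrt(n - 3)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  tibble(estimate = r, lower = tanh(z - crit * se),
         upper = tanh(z + crit * se), method = method,
         label = correlation_label(r), n = n)
}

#' Weighted kappa for a square cross-classification table
#'
#' Chance-corrected agreement with linear (default) or quadratic weights;
#' with `k` categories the agreement weight for cells `(i, j)` is
#' `1 - (|i - j| / (k - 1))^p`, `p = 1` or `2`.
#'
#' @param counts Square contingency matrix (rows: method 1, cols: method 2).
#' @param weights `"linear"` or `"quadratic"`.
#' @return Weighted kappa (scalar).
#' @export
weighted_kappa <- function(counts, weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  m <- as.matrix(counts)
  if (nrow(m) != ncol(m)) abort("`counts` must be square.")
  k <- nrow(m)
  n <- sum(m)
  if (n == 0) abort("`counts` is empty.")
  p <- m / n
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- 1 - if (weights == "linear") d else d^2
  pe <- outer(rowSums(p), colSums(p))
  po_w <- sum(w * p)
  pe_w <- sum(w * pe)
  if (abs(1 - pe_w) < .Machine$double.eps) {
    abort("Expected weighted agreement is 1; kappa undefined.")
  }
  (po_w - pe_w) / (1 - pe_w)
}

# Empirical tercile membership. Boundaries are the 1/3 and 2/3 quantiles with
# midpoint interpolation (quantile type 5), so membership depends only on the
# order statistics and is invariant under strictly monotone transforms.
tercile_assign <- function(x) {
  q <- quantile(x, c(1 / 3, 2 / 3), type = 5, names = FALSE)
  g <- 1L + (x > q[1]) + (x > q[2])
  if (length(unique(g)) < 3) {
    ties <- names(which(table(x) > 1))
    abort(paste0("Cannot split into 3 non-empty terciles; heavy ties at ",
                 "value(s) ", paste(head(ties, 5), collapse = ", "), "."))
  }
  g
}

#' Tercile cross-classification concordance
#'
#' Assigns each method's values to empirical terciles of its own
#' distribution, cross-classifies the pairs, and reports absolute agreement
#' (fraction on the diagonal), gross misclassification (opposite corners:
#' bottom tercile by one method, top by the other), and the weighted kappa
#' with its qualitative label.
#'
#' @inheritParams validity_correlation
#' @param weights Kappa weights, `"linear"` (default) or `"quadratic"`.
#' @return A list of class `"tercile_concordance"`: `counts` (3x3 matrix,
#'   rows = test terciles), `absolute_agreement` and
#'   `gross_misclassification` (percent), `kappa`, `kappa_label`, `weights`,
#'   `n`. Has a [tidy()] method.
#' @examples
#' set.seed(1)
#' x <- rnorm(90); tercile_concordance(x, x + rnorm(90))
#' @export
tercile_concordance <- function(test, criterion,
                                weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  ok <- complete.cases(test, criterion)
  x <- test[ok]
  y <- criterion[ok]
  n <- length(x)
  if (n < 3) abort("Tercile concordance needs at least 3 complete pairs.")
  gx <- tercile_assign(x)
  gy <- tercile_assign(y)
  counts <- table(factor(gx, 1:3), factor(gy, 1:3))
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(test = c("T1", "T2", "T3"),
                                   criterion = c("T1", "T2", "T3")))
  kap <- weighted_kappa(counts, weights)
  structure(
    list(counts = counts,
         absolute_agreement = 100 * sum(diag(counts)) / n,
         gross_misclassification = 100 * (counts[1, 3] + counts[3, 1]) / n,
         kappa = kap, kappa_label = kappa_label(kap), weights = weights,
         n = n),
    class = "tercile_concordance"
  )
}

#' @export
print.tercile_concordance <- function(x, ...) {
  cat("<tercile_concordance> n =", x$n, "\n")
  print(x$counts)
  cat(sprintf("absolute agreement %.1f%% | gross misclassification %.1f%% | %s weighted kappa %.3f (%s)\n",
              x$absolute_agreement, x$gross_misclassification, x$weights,
              x$kappa, x$kappa_label))
  invisible(x)
}

#' @export
#' @method tidy tercile_concordance
tidy.tercile_concordance <- function(x, ...) {
  tibble(absolute_agreement = x$absolute_agreement,
         gross_misclassification = x$gross_misclassification,
         kappa = x$kappa, kappa_label = x$kappa_label,
         weights = x$weights, n = x$n)
}

#' Bland-Altman agreement analysis (classic and Ludbrook variants)
#'
#' Differences are always test minus criterion. The classic variant reports
#' the mean difference with its t-based CI and the mean +/- 1.96 SD limits of
#' agreement. Both variants regress the difference on the per-participant
#' mean of the two methods to quantify proportional bias; the Ludbrook
#' variant additionally models the bias as a function of that mean and
#' replaces the constant limits with t-based 95% prediction bands around the
#' fitted regression line.
#'
#' @inheritParams validity_correlation
#' @param variant `"classic"` (default) or `"ludbrook"`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `"bland_altman"` with the mean difference and CI,
#'   limits of agreement, the proportional-bias regression (slope, CI,
#'   p-value), for the Ludbrook variant a `band` tibble (mean grid, fitted
#'   bias, lower/upper prediction limits), and the paired data. Has
#'   [tidy()] and [autoplot()] methods.
#' @examples
#' set.seed(1)
#' acc <- rnorm(80, 95, 30); q <- acc + rnorm(80, 10, 25)
#' tidy(bland_altman(q, acc))
#' @export
bland_altman <- function(test, criterion, variant = c("classic", "ludbrook"),
                         conf_level = 0.95) {
  variant <- match.arg(variant)
  ok <- complete.cases(test, criterion)
  x <- test[ok]
  y <- criterion[ok]
  n <- length(x)
  if (n < 3) abort("Bland-Altman needs at least 3 complete pairs.")
  d <- x - y
  m <- (x + y) / 2
  mean_diff <- mean(d)
  sd_diff <- sd(d)
  alpha <- 1 - conf_level
  tcrit <- qt(1 - alpha / 2, n - 1)
  ci <- mean_diff + c(-1, 1) * tcrit * sd_diff / sqrt(n)
  loa <- mean_diff + c(-1, 1) * qnorm(1 - alpha / 2) * sd_diff
  fit <- lm(d ~ m)
  sm <- summary(fit)$coefficients
  slope <- sm["m", "Estimate"]
  slope_se <- sm["m", "Std. Error"]
  tcrit2 <- qt(1 - alpha / 2, n - 2)
  band <- NULL
  if (variant == "ludbrook") {
    grid <- seq(min(m), max(m), length.out = 100)
    pr <- predict(fit, newdata = data.frame(m = grid), interval = "prediction",
                  level = conf_level)
    band <- tibble(mean = grid, bias = pr[, "fit"], lower = pr[, "lwr"],
                   upper = pr[, "upr"])
  }
  structure(
    list(variant = variant, n = n, mean_diff = mean_diff,
         ci_lower = ci[1], ci_upper = ci[2], sd_diff = sd_diff,
         loa_lower = loa[1], loa_upper = loa[2],
         slope = slope, slope_lower = slope - tcrit2 * slope_se,
         slope_upper = slope + tcrit2 * slope_se,
         slope_p = sm["m", "Pr(>|t|)"],
         intercept = sm["(Intercept)", "Estimate"], fit = fit, band = band,
         data = tibble(mean = m, difference = d), conf_level = conf_level),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("<bland_altman:", x$variant, "> n =", x$n, "\n")
  cat(sprintf("mean difference %.2f (%.0f%% CI %.2f; %.2f), LoA [%.2f; %.2f]\n",
              x$mean_diff, 100 * x$conf_level, x$ci_lower, x$ci_upper,
              x$loa_lower, x$loa_upper))
  cat(sprintf("proportional bias slope %.3f (%.3f; %.3f), p = %.3g\n",
              x$slope, x$slope_lower, x$slope_upper, x$slope_p))
  invisible(x)
}

#' @export
#' @method tidy bland_altman
tidy.bland_altman <- function(x, ...) {
  tibble(variant = x$variant, mean_difference = x$mean_diff,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         loa_lower = x$loa_lower, loa_upper = x$loa_upper,
         bias_slope = x$slope, bias_slope_lower = x$slope_lower,
         bias_slope_upper = x$slope_upper, bias_slope_p = x$slope_p,
         n = x$n)
}

#' Proportional agreement between paired measurements
#'
#' 100 times the mean of the per-participant ratios; 100% indicates complete
#' agreement on average. The default direction is test over criterion, so an
#' over-reporting questionnaire yields a value above 100%; the inverse
#' direction is selectable. The CI is a normal approximation on the mean
#' ratio.
#'
#' @inheritParams validity_correlation
#' @param definition Ratio direction (see [pau_config()]'s
#'   `agreement_ratio`).
#' @return One-row tibble: `percent`, `lower`, `upper`, `definition`, `n`.
#' @export
proportional_agreement <- function(test, criterion,
                                   definition = c("test_over_criterion",
                                                  "criterion_over_test"),
                                   conf_level = 0.95) {
  definition <- match.arg(definition)
  ok <- complete.cases(test, criterion)
  x <- test[ok]
  y <- criterion[ok]
  denom <- if (definition == "test_over_criterion") y else x
  if (any(denom == 0)) {
    abort(paste0("Zero denominator for participant position(s) ",
                 paste(head(which(denom == 0), 5), collapse = ", "),
                 "; proportional agreement is undefined."))
  }
  ratio <- if (definition == "test_over_criterion") x / y else y / x
  n <- length(ratio)
  est <- 100 * mean(ratio)
  se <- 100 * sd(ratio) / sqrt(n)
  crit <- qnorm(1 - (1 - conf_level) / 2)
  tibble(percent = est, lower = est - crit * se, upper = est + crit * se,
         definition = definition, n = n)
}
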