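test_that("Cronbach alpha matches its closed form and limiting cases", {
  x <- rnorm(100)
  ident <- cbind(x, x, x, x, x, x)
  expect_equal(cronbach_alpha(ident)$alpha, 1)

  # equicorrelated standardized items: alpha = k*r / (1 + (k-1)*r)
  set.seed(11)
  n <- 40000
  k <- 6
  r <- 0.345
  f <- rnorm(n)
  m <- sqrt(r) * matrix(f, n, k) + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
  expect_equal(cronbach_alpha(m)$alpha, k * r / (1 + (k - 1) * r),
               tolerance = 0.02)

  set.seed(12)
  indep <- matrix(rnorm(6 * 20000), ncol = 6)
  expect_lt(abs(cronbach_alpha(indep)$alpha), 0.05)

  expect_error(cronbach_alpha(matrix(1, 10, 4)), "zero")
  expect_error(cronbach_alpha(matrix(rnorm(4), 2, 2)), "participants")
})

test_that("ICC agrees with the aov mean-squares oracle on random tables", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(5:25, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, sd = sample(1:3, 1)), n, k) +
      rnorm(n)  # subject effect
    m[, 1] <- m[, 1] + runif(1, -2, 2)  # rating mean shift
    for (model in c("consistency", "agreement")) {
      expect_equal(icc(m, model)$icc, oracle_icc_aov(m, model),
                   tolerance = 1e-10)
    }
  }
})

test_that("ICC recovers known structure", {
  x <- rnorm(60)
  expect_equal(icc(cbind(x, x))$icc, 1)
  # bivariate normal, equal variances: consistency ICC -> rho
  set.seed(22)
  rho <- 0.71
  n <- 60000
  a <- rnorm(n)
  b <- rho * a + sqrt(1 - rho^2) * rnorm(n)
  res <- icc(cbind(a, b))
  expect_equal(res$icc, rho, tolerance = 0.01)
  expect_true(res$lower < rho && rho < res$upper)
  # agreement ICC penalises a constant offset, consistency does not
  off <- cbind(a, b + 1)[1:2000, ]
  expect_equal(icc(off, "consistency")$icc,
               icc(cbind(a, b)[1:2000, ], "consistency")$icc)
  expect_lt(icc(off, "agreement")$icc, icc(off, "consistency")$icc)
  expect_error(icc(matrix(1, 10, 2)), "Degenerate")
})

test_that("correlation labels partition with the published boundaries", {
  expect_equal(correlation_label(c(0.20, 0.21, 0.40, 0.41, 0.60, 0.61,
                                   0.80, 0.81)),
               c("weak", "fair", "fair", "moderate", "moderate", "good",
                 "good", "very good"))
  expect_equal(correlation_label(0.31), "fair")
  expect_equal(kappa_label(c(0.24, 0.50)), c("fair", "moderate"))
  expect_equal(kappa_label(0.61), "substantial")
})

test_that("validity correlation handles both methods and degenerate input", {
  x <- rnorm(50)
  expect_equal(validity_correlation(x, x)$estimate, 1)
  expect_equal(validity_correlation(x, x)$label, "very good")
  expect_equal(validity_correlation(x, -rank(x), "spearman")$estimate, -1)
  expect_error(validity_correlation(rep(1, 10), rnorm(10)), "Constant")
  expect_error(validity_correlation(1:2, 2:3), "at least 3")
})

test_that("weighted kappa equals the cell-by-cell oracle", {
  # exhaustive over all 3x3 tables with small totals
  for (n in c(3, 5, 7)) {
    tables <- enumerate_tables_3x3(n)
    for (tab in tables) {
      if (sum(tab) == 0) next
      marg_ok <- abs(1 - sum((rowSums(tab) / n) %o% (colSums(tab) / n) *
                               (1 - abs(outer(1:3, 1:3, "-")) / 2))) > 1e-12
      if (!marg_ok) next
      expect_equal(weighted_kappa(tab), oracle_weighted_kappa(tab),
                   tolerance = 1e-12)
    }
  }
  # random larger tables, both weight schemes
  set.seed(31)
  for (i in 1:200) {
    tab <- matrix(stats::rpois(9, 4), 3, 3)
    if (sum(tab) == 0) next
    expect_equal(weighted_kappa(tab, "linear"),
                 oracle_weighted_kappa(tab, 1), tolerance = 1e-12)
    expect_equal(weighted_kappa(tab, "quadratic"),
                 oracle_weighted_kappa(tab, 2), tolerance = 1e-12)
  }
  # frozen worked example
  tab <- matrix(c(20, 6, 1, 5, 14, 7, 2, 6, 19), 3, 3)
  expect_equal(weighted_kappa(tab), 0.5807127883, tolerance = 1e-9)
})

test_that("tercile concordance behaves at the extremes", {
  set.seed(32)
  x <- rnorm(90)
  same <- tercile_concordance(x, x)
  expect_equal(same$absolute_agreement, 100)
  expect_equal(same$kappa, 1)
  expect_equal(same$gross_misclassification, 0)

  y <- rnorm(9000)
  z <- rnorm(9000)
  indep <- tercile_concordance(y, z)
  expect_equal(indep$absolute_agreement, 100 / 3, tolerance = 0.1 * 100 / 3)
  expect_lt(abs(indep$kappa), 0.05)
})

test_that("tercile assignment is invariant under monotone transforms", {
  set.seed(33)
  x <- rexp(120)
  y <- x + rnorm(120, sd = 0.3)
  base <- tercile_concordance(x, y)
  warped <- tercile_concordance(log(x), y)
  expect_equal(base$counts, warped$counts)
  warped2 <- tercile_concordance(x, exp(y / 2))
  expect_equal(base$counts, warped2$counts)
})

test_that("heavy ties that prevent three groups raise an informative error", {
  x <- c(rep(1, 20), 2)
  expect_error(tercile_concordance(x, rnorm(21)), "ties")
})

test_that("Bland-Altman recovers fixed offsets and proportional bias", {
  x <- rnorm(100, 100, 20)
  same <- suppressWarnings(bland_altman(x, x))  # zero-variance difference
  expect_equal(same$mean_diff, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(same$loa_lower, same$loa_upper)

  off <- suppressWarnings(bland_altman(x + 10, x))  # exact offset
  expect_equal(off$mean_diff, 10)
  expect_equal(off$slope, 0, tolerance = 1e-10)

  # test = 2 * criterion: d = c, m = 1.5c, slope = 2/3
  dbl <- suppressWarnings(bland_altman(2 * x, x))  # exact proportionality
  expect_equal(dbl$slope, 2 / 3, tolerance = 1e-10)
})

test_that("classic limits of agreement cover about 95% of differences", {
  set.seed(34)
  x <- rnorm(20000, 100, 15)
  y <- x + rnorm(20000, 5, 10)
  ba <- bland_altman(y, x)
  inside <- mean(ba$data$difference >= ba$loa_lower &
                   ba$data$difference <= ba$loa_upper)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("Ludbrook bands follow the bias regression and cover the data", {
  set.seed(35)
  crit <- rnorm(2000, 95, 25)
  test <- 0.5 * crit + 60 + rnorm(2000, 0, 12)  # strong proportional bias
  lb <- bland_altman(test, crit, variant = "ludbrook")
  expect_false(is.null(lb$band))
  expect_lt(lb$slope_p, 1e-10)
  # prediction band should cover ~95% of observed differences
  f <- stats::approxfun(lb$band$mean, lb$band$lower)
  g <- stats::approxfun(lb$band$mean, lb$band$upper)
  inside <- mean(lb$data$difference >= f(lb$data$mean) &
                   lb$data$difference <= g(lb$data$mean), na.rm = TRUE)
  expect_equal(inside, 0.95, tolerance = 0.015)
})

test_that("proportional agreement reflects the ratio and its direction", {
  x <- runif(50, 50, 150)
  expect_equal(proportional_agreement(x, x)$percent, 100)
  expect_equal(proportional_agreement(2 * x, x)$percent, 200)
  expect_equal(proportional_agreement(x / 2, x)$percent, 50)
  expect_equal(proportional_agreement(2 * x, x,
                                      "criterion_over_test")$percent, 50)
  expect_error(proportional_agreement(x, c(0, x[-1])), "Zero denominator")
})

test_that("the concordance report carries the full statistics battery", {
  sim <- simulate_cohort(n = 304, seed = 5)
  rep <- concordance_report(sim)
  expect_setequal(unique(rep$stratum), c("all", "boys", "girls"))
  stats_all <- rep$statistic[rep$stratum == "all" &
                               rep$method == "noncalibrated"]
  for (s in c("n", "criterion_mean", "criterion_sd", "test_mean", "test_sd",
              "between_method_difference", "proportional_agreement",
              "cronbach_alpha", "bias_slope", "spearman", "pearson", "icc",
              "absolute_agreement", "gross_misclassification",
              "weighted_kappa")) {
    expect_true(s %in% stats_all, label = paste("statistic", s))
  }
  expect_true("calibrated" %in% rep$method)
  expect_true("test_retest" %in% rep$method)
  cal_diff <- rep$estimate[rep$stratum == "all" & rep$method == "calibrated" &
                             rep$statistic == "between_method_difference"]
  expect_equal(cal_diff, 0, tolerance = 1e-10)
  # report writers round-trip
  jf <- withr::local_tempfile(fileext = ".json")
  cf <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, json_path = jf, csv_path = cf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$schema, "pau7s-report/1")
  expect_equal(nrow(back$rows), nrow(rep))
  expect_equal(readr::read_csv(cf, show_col_types = FALSE)$estimate,
               rep$estimate)
})
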