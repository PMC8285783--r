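# Independent brute-force oracles used to cross-check the package's
# statistics. They deliberately use different computational routes
# (explicit loops, aov() decompositions, literal refits).

# weighted kappa straight from the definition, cell by cell
oracle_weighted_kappa <- function(counts, power = 1) {
  k <- nrow(counts)
  n <- sum(counts)
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      w <- 1 - (abs(i - j) / (k - 1))^power
      po <- po + w * counts[i, j] / n
      pe <- pe + w * (sum(counts[i, ]) / n) * (sum(counts[, j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

# mean squares via aov() on the long layout, then the textbook ICC formulas
oracle_icc_aov <- function(ratings, model = "consistency") {
  n <- nrow(ratings)
  k <- ncol(ratings)
  long <- data.frame(
    y = as.vector(as.matrix(ratings)),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  if (model == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  }
}

# literal n-refit leave-one-out over the calibration model
oracle_loocv <- function(cohort) {
  n <- nrow(cohort)
  vapply(seq_len(n), function(i) {
    fit <- stats::lm(mvpa_accel ~ age + sex_num + mvpa_q + weight,
                     data = transform(cohort[-i, ],
                                      sex_num = as.numeric(sex == "boy")))
    stats::predict(fit, newdata = transform(cohort[i, ],
                                            sex_num = as.numeric(sex == "boy")))
  }, numeric(1))
}

# enumerate all 3x3 contingency tables with total exactly n
enumerate_tables_3x3 <- function(n) {
  out <- list()
  cells <- 9
  rec <- function(prefix, remaining, depth) {
    if (depth == cells) {
      out[[length(out) + 1]] <<- matrix(c(prefix, remaining), 3, 3)
      return()
    }
    for (v in 0:remaining) rec(c(prefix, v), remaining - v, depth + 1)
  }
  rec(integer(0), n, 1)
  out
}

# a uniform epoch series helper for hand-built accelerometer cases
epoch_series <- function(vm, start = "2019-04-01 00:00:00",
                         epoch_length = 5, participant_id = NULL) {
  ts <- as.POSIXct(start, tz = "UTC") + (seq_along(vm) - 1) * epoch_length
  df <- tibble::tibble(timestamp = ts, vm = vm)
  if (!is.null(participant_id)) {
    df <- tibble::tibble(participant_id = participant_id, df)
  }
  df
}
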