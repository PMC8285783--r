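sex_indicator <- function(sex, config) {
  if (is.numeric(sex)) {
    if (!all(sex %in% c(0, 1))) abort("Numeric `sex` must be coded 0/1.")
    return(sex)
  }
  s <- tolower(as.character(sex))
  boy <- s %in% c("boy", "boys", "male", "m", "b", "1")
  girl <- s %in% c("girl", "girls", "female", "f", "g", "0")
  if (!all(boy | girl)) {
    abort(paste0("Unrecognised sex value(s): ",
                 paste(unique(s[!(boy | girl)]), collapse = ", "), "."))
  }
  ifelse(boy, config$sex_male, 1 - config$sex_male)
}

calibration_terms <- c("age", "sex", "mvpa_q", "weight")

prepare_calibration_frame <- function(cohort, config, require_response = TRUE) {
  need <- c(calibration_terms, if (require_response) "mvpa_accel")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", "),
                 "."))
  }
  if ("accel_valid" %in% names(cohort)) {
    dropped <- sum(!cohort$accel_valid)
    if (dropped > 0) {
      inform(paste0("Excluding ", dropped,
                    " participant(s) without valid accelerometer data (",
                    nrow(cohort) - dropped, " remain)."))
    }
    cohort <- cohort[cohort$accel_valid, , drop = FALSE]
  }
  df <- tibble(
    age = as.numeric(cohort$age),
    sex = sex_indicator(cohort$sex, config),
    mvpa_q = as.numeric(cohort$mvpa_q),
    weight = as.numeric(cohort$weight)
  )
  if (require_response) df$mvpa_accel <- as.numeric(cohort$mvpa_accel)
  keep <- complete.cases(df)
  if (sum(!keep) > 0) {
    inform(paste0("Listwise deletion of ", sum(!keep),
                  " row(s) with missing values."))
  }
  df[keep, , drop = FALSE]
}

#' Fit the linear calibration of questionnaire MVPA against the criterion
#'
#' Regresses accelerometer MVPA (criterion) on questionnaire MVPA with age,
#' sex and weight as covariables, by ordinary least squares. The fitted
#' model corrects the questionnaire's measurement error: applying it to the
#' training rows yields calibrated values whose mean equals the criterion
#' mean exactly (the OLS-with-intercept identity behind a zero calibrated
#' between-method difference). Variance inflation factors are computed as a
#' multicollinearity check and stored on the object.
#'
#' @param cohort Data frame with columns `mvpa_accel`, `mvpa_q`, `age`,
#'   `sex`, `weight`; rows with `accel_valid == FALSE` (when that column is
#'   present) are excluded.
#' @param config A [pau_config()] (sex coding, confidence level).
#' @return An object of class `"pau_calibration"`: the `lm` fit,
#'   `coefficients` (named `intercept`, `age`, `sex`, `mvpa_q`, `weight`),
#'   `sigma`, `r_squared`, `n`, `vif`, and the sex coding used. Has
#'   [tidy()], [glance()] and [predict()] methods.
#' @examples
#' cohort <- simulate_cohort(n = 304, seed = 1)$cohort
#' fit <- fit_calibration(cohort)
#' coef(fit$fit)
#' @export
fit_calibration <- function(cohort, config = pau_config()) {
  config <- as_pau_config(config)
  df <- prepare_calibration_frame(cohort, config)
  if (nrow(df) <= 10) abort("Calibration needs more than 10 complete rows.")
  constant <- calibration_terms[vapply(df[calibration_terms], function(x)
    sd(x) == 0, logical(1))]
  if (length(constant)) {
    abort(paste0("Constant column(s) in the calibration design: ",
                 paste(constant, collapse = ", "), "."))
  }
  fit <- lm(mvpa_accel ~ age + sex + mvpa_q + weight, data = df)
  if (fit$rank < 5) {
    aliased <- names(which(is.na(coef(fit))))
    abort(paste0("Singular calibration design; collinear column(s): ",
                 paste(aliased, collapse = ", "), "."))
  }
  cf <- coef(fit)
  names(cf)[1] <- "intercept"
  sm <- summary(fit)
  structure(
    list(fit = fit, coefficients = cf, sigma = sm$sigma,
         r_squared = sm$r.squared, n = nrow(df),
         vif = car::vif(fit), sex_male = config$sex_male,
         conf_level = config$conf_level),
    class = "pau_calibration"
  )
}

#' @export
print.pau_calibration <- function(x, ...) {
  cat("<pau_calibration> n =", x$n, "\n")
  eq <- sprintf("calibrated MVPA = %.3f + (%.3f * age) + (%.3f * sex) + (%.3f * MVPA_q) + (%.3f * weight)",
                x$coefficients["intercept"], x$coefficients["age"],
                x$coefficients["sex"], x$coefficients["mvpa_q"],
                x$coefficients["weight"])
  cat(" ", eq, "\n")
  cat(sprintf("  sex coding: boy = %d | R^2 = %.3f | residual SD = %.2f\n",
              x$sex_male, x$r_squared, x$sigma))
  cat("  VIF:", paste(names(x$vif), sprintf("%.2f", x$vif), sep = "=",
                      collapse = " "), "\n")
  invisible(x)
}

#' @export
#' @method tidy pau_calibration
tidy.pau_calibration <- function(x, conf.int = TRUE,
                                 conf.level = x$conf_level, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble(
    term = c("intercept", rownames(sm)[-1]),
    estimate = sm[, "Estimate"], std_error = sm[, "Std. Error"],
    statistic = sm[, "t value"], p_value = sm[, "Pr(>|t|)"]
  )
  if (conf.int) {
    tcrit <- qt(1 - (1 - conf.level) / 2, x$fit$df.residual)
    out$conf_low <- out$estimate - tcrit * out$std_error
    out$conf_high <- out$estimate + tcrit * out$std_error
  }
  out
}

#' @export
#' @method glance pau_calibration
glance.pau_calibration <- function(x, ...) {
  tibble(r_squared = x$r_squared, sigma = x$sigma, n = x$n,
         max_vif = max(x$vif))
}

#' Build a calibration model from known coefficients
#'
#' Wraps externally supplied calibration coefficients (for instance a
#' published equation) into an object usable by [apply_calibration()].
#'
#' @param intercept,age,sex,mvpa_q,weight Coefficients of the linear
#'   predictor.
#' @param sex_male Numeric code for boys in the `sex` covariate (default 1).
#' @return A `"pau_calibration"` object without fit diagnostics.
#' @examples
#' eq <- calibration_model(183.788, age = -6.374, sex = 1.437,
#'                         mvpa_q = 0.080, weight = -0.436)
#' apply_calibration(eq, data.frame(age = 12, sex = 1, mvpa_q = 100,
#'                                  weight = 47))
#' @export
calibration_model <- function(intercept, age, sex, mvpa_q, weight,
                              sex_male = 1) {
  structure(
    list(fit = NULL,
         coefficients = c(intercept = intercept, age = age, sex = sex,
                          mvpa_q = mvpa_q, weight = weight),
         sigma = NA_real_, r_squared = NA_real_, n = NA_integer_,
         vif = NULL, sex_male = sex_male, conf_level = 0.95),
    class = "pau_calibration"
  )
}

#' Apply a calibration model to participant covariates
#'
#' Evaluates the linear predictor for each row. Negative calibrated values
#' are returned as-is with a warning (no truncation).
#'
#' @param model A `"pau_calibration"` object ([fit_calibration()] or
#'   [calibration_model()]).
#' @param covariates Data frame with `age`, `sex`, `mvpa_q`, `weight`.
#' @return Numeric vector of calibrated MVPA (min/day).
#' @export
apply_calibration <- function(model, covariates) {
  stopifnot(inherits(model, "pau_calibration"))
  config <- pau_config(sex_male = model$sex_male)
  df <- prepare_calibration_frame(covariates, config, require_response = FALSE)
  if (nrow(df) < nrow(covariates)) {
    abort("Missing covariate values; calibration needs complete age, sex, mvpa_q and weight.")
  }
  cf <- model$coefficients
  pred <- cf["intercept"] + cf["age"] * df$age + cf["sex"] * df$sex +
    cf["mvpa_q"] * df$mvpa_q + cf["weight"] * df$weight
  if (any(pred < 0)) {
    warn(paste0(sum(pred < 0), " calibrated value(s) are negative; ",
                "returned untruncated."))
  }
  unname(pred)
}

#' @export
predict.pau_calibration <- function(object, newdata, ...) {
  apply_calibration(object, newdata)
}

#' Add calibrated MVPA to a cohort table
#'
#' Fits the calibration on the cohort (or uses a supplied model) and appends
#' an `mvpa_calibrated` column.
#'
#' @inheritParams fit_calibration
#' @param model Optional pre-fitted `"pau_calibration"`; fitted on `cohort`
#'   when `NULL`.
#' @return The cohort tibble with `mvpa_calibrated` appended.
#' @export
calibrate_cohort <- function(cohort, model = NULL, config = pau_config()) {
  if (is.null(model)) model <- fit_calibration(cohort, config)
  cohort <- as_tibble(cohort)
  cohort$mvpa_calibrated <- apply_calibration(model, cohort)
  cohort
}

#' Leave-one-out cross-validated predictive validity
#'
#' Predicts each participant's criterion MVPA from the calibration model
#' fitted on the remaining n - 1 participants, then compares the n held-out
#' predictions with the observed criterion by Pearson and Spearman
#' correlation and ICC. Uses the exact OLS leave-one-out identity
#' (`e_i / (1 - h_i)`), which equals refitting n times.
#'
#' @inheritParams fit_calibration
#' @return An object of class `"pau_loocv"`: `predictions` tibble (observed
#'   criterion, held-out prediction), `pearson`, `spearman`, `icc` rows (as
#'   returned by [validity_correlation()] / [icc()]), and `n`. Has a
#'   [glance()] method.
#' @examples
#' cohort <- simulate_cohort(n = 304, seed = 1)$cohort
#' glance(loocv_calibration(cohort))
#' @export
loocv_calibration <- function(cohort, config = pau_config()) {
  config <- as_pau_config(config)
  model <- fit_calibration(cohort, config)
  fit <- model$fit
  if (nrow(fit$model) <= length(coef(fit)) + 1) {
    abort("LOOCV needs n greater than the number of parameters + 1.")
  }
  h <- hatvalues(fit)
  if (any(1 - h < 1e-10)) {
    abort("A leave-one-out fit is singular (leverage 1).")
  }
  y <- fit$model$mvpa_accel
  pred <- y - residuals(fit) / (1 - h)
  pe <- validity_correlation(pred, y, "pearson", config$conf_level)
  sp <- validity_correlation(pred, y, "spearman", config$conf_level)
  ic <- icc(cbind(pred, y), config$icc_model, config$conf_level)
  structure(
    list(predictions = tibble(observed = y, predicted = unname(pred)),
         pearson = pe, spearman = sp, icc = ic, n = length(y),
         in_sample_pearson = sqrt(model$r_squared), model = model),
    class = "pau_loocv"
  )
}

#' @export
print.pau_loocv <- function(x, ...) {
  cat("<pau_loocv> n =", x$n, "\n")
  cat(sprintf("  held-out Pearson %.3f (in-sample %.3f) | Spearman %.3f | ICC %.3f\n",
              x$pearson$estimate, x$in_sample_pearson, x$spearman$estimate,
              x$icc$icc))
  invisible(x)
}

#' @export
#' @method glance pau_loocv
glance.pau_loocv <- function(x, ...) {
  tibble(pearson = x$pearson$estimate, spearman = x$spearman$estimate,
         icc = x$icc$icc, in_sample_pearson = x$in_sample_pearson, n = x$n)
}

#' Construct validity: adiposity outcome regressed on MVPA
#'
#' Fits the sex- and age-adjusted multiple linear regression of an
#' anthropometric outcome (zBMI or waist-to-height ratio) on MVPA, with the
#' exposure scaled per 100 min/day, and reports the exposure coefficient
#' with Wald CI and p-value. An inverse (negative) coefficient supports the
#' construct that more active children carry less adiposity.
#'
#' @inheritParams fit_calibration
#' @param outcome `"zbmi"` or `"whtr"` (column of `cohort`).
#' @param calibrated Use `mvpa_calibrated` as the exposure instead of
#'   `mvpa_q` (the column must exist, see [calibrate_cohort()]).
#' @return One-row tibble: `outcome`, `exposure`, `beta` (per 100 min/d),
#'   `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
construct_validity <- function(cohort, outcome = c("zbmi", "whtr"),
                               calibrated = FALSE, config = pau_config()) {
  config <- as_pau_config(config)
  outcome <- match.arg(outcome)
  exposure <- if (calibrated) "mvpa_calibrated" else "mvpa_q"
  need <- c(outcome, exposure, "age", "sex")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", "),
                 "."))
  }
  if ("accel_valid" %in% names(cohort)) {
    cohort <- cohort[cohort$accel_valid, , drop = FALSE]
  }
  df <- tibble(
    y = as.numeric(cohort[[outcome]]),
    mvpa100 = as.numeric(cohort[[exposure]]) / 100,
    age = as.numeric(cohort$age),
    sex = sex_indicator(cohort$sex, config)
  )
  df <- df[complete.cases(df), , drop = FALSE]
  fit <- lm(y ~ mvpa100 + sex + age, data = df)
  if (fit$rank < 4) abort("Singular construct-validity design.")
  sm <- summary(fit)$coefficients
  tcrit <- qt(1 - (1 - config$conf_level) / 2, fit$df.residual)
  tibble(
    outcome = outcome, exposure = exposure,
    beta = sm["mvpa100", "Estimate"],
    conf_low = sm["mvpa100", "Estimate"] - tcrit * sm["mvpa100", "Std. Error"],
    conf_high = sm["mvpa100", "Estimate"] + tcrit * sm["mvpa100", "Std. Error"],
    p_value = sm["mvpa100", "Pr(>|t|)"], n = nrow(df)
  )
}
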