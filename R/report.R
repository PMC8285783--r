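battery_rows <- function(test, criterion, items, config) {
  ba <- bland_altman(test, criterion, "classic", config$conf_level)
  pa <- proportional_agreement(test, criterion, config$agreement_ratio,
                               config$conf_level)
  sp <- validity_correlation(test, criterion, "spearman", config$conf_level)
  pe <- validity_correlation(test, criterion, "pearson", config$conf_level)
  ic <- icc(cbind(test, criterion), config$icc_model, config$conf_level)
  tc <- tercile_concordance(test, criterion, config$kappa_weights)
  alpha <- if (!is.null(items)) cronbach_alpha(items)$alpha else NA_real_
  row <- function(statistic, estimate, lower = NA_real_, upper = NA_real_,
                  label = NA_character_) {
    tibble(statistic = statistic, estimate = estimate, lower = lower,
           upper = upper, label = label)
  }
  dplyr::bind_rows(
    row("n", length(test)),
    row("criterion_mean", mean(criterion)), row("criterion_sd", sd(criterion)),
    row("test_mean", mean(test)), row("test_sd", sd(test)),
    row("between_method_difference", ba$mean_diff, ba$ci_lower, ba$ci_upper),
    row("proportional_agreement", pa$percent, pa$lower, pa$upper),
    if (!is.null(items)) row("cronbach_alpha", alpha),
    row("bias_slope", ba$slope, ba$slope_lower, ba$slope_upper),
    row("bias_slope_p", ba$slope_p),
    row("spearman", sp$estimate, sp$lower, sp$upper, sp$label),
    row("pearson", pe$estimate, pe$lower, pe$upper, pe$label),
    row("icc", ic$icc, ic$lower, ic$upper),
    row("absolute_agreement", tc$absolute_agreement),
    row("gross_misclassification", tc$gross_misclassification),
    row("weighted_kappa", tc$kappa, label = tc$kappa_label)
  )
}

#' Full between-method concordance report
#'
#' Computes the complete reliability/validity battery comparing
#' questionnaire MVPA (test) against accelerometer MVPA (criterion):
#' means/SDs, between-method difference with CI, proportional agreement,
#' Cronbach alpha (when item scores are available), the proportional-bias
#' regression slope, Spearman and Pearson correlations with qualitative
#' labels, ICC, tercile absolute agreement, gross misclassification and
#' weighted kappa - overall and, optionally, by sex, for the noncalibrated
#' and (when present or requested) calibrated questionnaire values, plus
#' the test-retest ICC when both administrations are present.
#'
#' @param data A `"pau_cohort"` from [simulate_cohort()], or a cohort data
#'   frame with at least `mvpa_q` and `mvpa_accel` (optionally `sex`,
#'   `mvpa_q1`/`mvpa_q2`, `mvpa_calibrated`, `accel_valid`).
#' @param config A [pau_config()].
#' @param by_sex Also report boys and girls strata (needs a `sex` column).
#' @param calibrate Add calibrated-questionnaire rows; fits the calibration
#'   on the fly if `mvpa_calibrated` is absent (needs the calibration
#'   covariates).
#' @return A long tibble: `stratum` (`all`/`boys`/`girls`), `method`
#'   (`noncalibrated`/`calibrated`/`test_retest`), `statistic`, `estimate`,
#'   `lower`, `upper`, `label`.
#' @examples
#' sim <- simulate_cohort(n = 304, seed = 1)
#' rep <- concordance_report(sim)
#' dplyr::filter(rep, statistic == "weighted_kappa")
#' @export
concordance_report <- function(data, config = pau_config(), by_sex = TRUE,
                               calibrate = TRUE) {
  config <- as_pau_config(config)
  items <- NULL
  if (inherits(data, "pau_cohort")) {
    s <- data$scored[data$scored$administration == config$administration, ]
    items <- s[c("walking", "recess_play", "free_play", "physical_education",
                 "team_sport", "individual_sport")]
    cohort <- data$cohort
  } else {
    cohort <- as_tibble(data)
  }
  if ("accel_valid" %in% names(cohort)) {
    keep <- cohort$accel_valid
    if (any(!keep)) {
      inform(paste0("Excluding ", sum(!keep), " participant(s) without ",
                    "valid accelerometer data (", sum(keep), " remain)."))
    }
    cohort <- cohort[keep, , drop = FALSE]
    if (!is.null(items)) items <- items[keep, , drop = FALSE]
  }
  if (!all(c("mvpa_q", "mvpa_accel") %in% names(cohort))) {
    abort("`data` needs `mvpa_q` and `mvpa_accel` columns.")
  }
  if (calibrate && !"mvpa_calibrated" %in% names(cohort) &&
      all(calibration_terms %in% names(cohort))) {
    cohort <- calibrate_cohort(cohort, config = config)
  }

  strata <- list(all = rep(TRUE, nrow(cohort)))
  if (by_sex && "sex" %in% names(cohort)) {
    ind <- sex_indicator(cohort$sex, config)
    strata$boys <- ind == config$sex_male
    strata$girls <- ind == 1 - config$sex_male
  }
  out <- purrr::imap(strata, function(sel, nm) {
    blocks <- list(
      dplyr::mutate(
        battery_rows(cohort$mvpa_q[sel], cohort$mvpa_accel[sel],
                     if (!is.null(items)) items[sel, , drop = FALSE], config),
        method = "noncalibrated")
    )
    if ("mvpa_calibrated" %in% names(cohort)) {
      blocks <- c(blocks, list(dplyr::mutate(
        battery_rows(cohort$mvpa_calibrated[sel], cohort$mvpa_accel[sel],
                     NULL, config),
        method = "calibrated")))
    }
    if (all(c("mvpa_q1", "mvpa_q2") %in% names(cohort))) {
      rt <- icc(cbind(cohort$mvpa_q1[sel], cohort$mvpa_q2[sel]),
                config$icc_model, config$conf_level)
      blocks <- c(blocks, list(tibble(
        statistic = "test_retest_icc", estimate = rt$icc, lower = rt$lower,
        upper = rt$upper, label = correlation_label(rt$icc),
        method = "test_retest")))
    }
    dplyr::mutate(dplyr::bind_rows(blocks), stratum = nm)
  })
  dplyr::relocate(dplyr::bind_rows(out), "stratum", "method")
}

#' Write a concordance report to JSON and/or CSV
#'
#' Numbers are serialised at full precision; the JSON carries a schema
#' version tag.
#'
#' @param report Tibble from [concordance_report()].
#' @param json_path,csv_path Output paths (`NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  if (!is.null(csv_path)) readr::write_csv(report, csv_path, progress = FALSE)
  if (!is.null(json_path)) {
    payload <- list(schema = "pau7s-report/1", rows = report)
    jsonlite::write_json(payload, json_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}
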