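#' Generator configuration for synthetic PAU-7S cohorts
#'
#' Bundles every generative parameter of [simulate_cohort()]. The defaults
#' describe a nationally representative validation cohort of Spanish
#' 8-16-year-olds: demographic moments, questionnaire MVPA moments, the
#' reliability/consistency targets, the criterion model built from a linear
#' calibration equation, and construct-validity slopes. Item-level latent
#' means/SDs and the latent correlation parameters are *pre-shrinkage*
#' values, tuned once (fixed-seed internal search) so that the *scored*
#' cohort - after day-by-bin discretisation and flooring at zero - hits the
#' observable targets; see the methods vignette.
#'
#' @param n Default cohort size (the validity sample size, 304).
#' @param age_mean,age_sd,age_range Age distribution (years); a truncated
#'   normal whose parent parameters are moment-matched so the *truncated*
#'   mean/SD equal the targets.
#' @param p_boy Proportion of boys (149/321).
#' @param weight_mean,weight_sd,weight_min Weight (kg) moments and
#'   plausibility floor.
#' @param age_weight_cor Age-weight correlation (growth; 0.7).
#' @param height_mean,height_age_slope,height_resid_sd,height_min Height (cm)
#'   as a linear function of age plus noise.
#' @param items Tibble `item`, `mean`, `sd`: latent minutes/day per item for
#'   administration 2.
#' @param admin1_scale Multiplier on item means for administration 1
#'   (activity reporting is higher at baseline).
#' @param latent_r Latent inter-item correlation (drives Cronbach alpha).
#' @param retest_r Latent administration-to-administration correlation
#'   (drives test-retest ICC).
#' @param age_activity_cor Correlation between the latent activity factor
#'   and age (negative: younger children report more activity); drives the
#'   marginal test-criterion correlation through the criterion's age term.
#' @param mvpa_mean,mvpa_sd Scored questionnaire MVPA targets (min/day).
#' @param criterion_mean Criterion (accelerometer) MVPA mean target.
#' @param criterion_slopes Named vector `age`, `sex`, `mvpa_q`, `weight`:
#'   the true calibration slopes generating the criterion.
#' @param multiple_r Target multiple correlation of the criterion on the
#'   four calibration covariates; the residual SD is solved from it each
#'   cohort.
#' @param zbmi_mean,zbmi_sd,zbmi_slope zBMI marginal moments and true slope
#'   per 100 min/day of questionnaire MVPA.
#' @param whtr_mean,whtr_sd,whtr_slope Same for waist-to-height ratio.
#' @param alpha_target,retest_icc_target,marginal_spearman_target Observable
#'   targets checked by [verify_moments()].
#' @param aquatic_p,sick_p Rates of the two qualitative flags.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n = 304,
                       age_mean = 12.3, age_sd = 2.21, age_range = c(8, 16),
                       p_boy = 149 / 321,
                       weight_mean = 47.6, weight_sd = 14.6, weight_min = 20,
                       age_weight_cor = 0.7,
                       height_mean = 152, height_age_slope = 5.8,
                       height_resid_sd = 5.5, height_min = 110,
                       items = NULL,
                       admin1_scale = 1.12,
                       latent_r = 0.4796,
                       retest_r = 0.7282,
                       age_activity_cor = -0.3553,
                       mvpa_mean = 106.5, mvpa_sd = 77.0,
                       criterion_mean = 95.2,
                       criterion_slopes = c(age = -6.374, sex = 1.437,
                                            mvpa_q = 0.080, weight = -0.436),
                       multiple_r = 0.62,
                       zbmi_mean = 0.57, zbmi_sd = 1.25, zbmi_slope = -0.162,
                       whtr_mean = 0.46, whtr_sd = 0.06, whtr_slope = -0.010,
                       alpha_target = 0.76,
                       retest_icc_target = 0.71,
                       marginal_spearman_target = 0.31,
                       aquatic_p = 0.3, sick_p = 0.1) {
  if (is.null(items)) {
    # latent (pre-shrinkage) minutes/day; tuned once so the scored cohort
    # hits the observable targets (see the methods vignette)
    items <- tibble(
      item = pau_items(),
      mean = c(40.470, 13.255, 35.719, 4.075, 19.398, 12.437),
      sd   = c(32.131, 14.459, 42.841, 3.856, 38.557, 32.131)
    )
  }
  stopifnot(
    n >= 2, age_sd > 0, weight_sd > 0, p_boy > 0, p_boy < 1,
    latent_r > 0, latent_r < 1, retest_r > 0, retest_r < 1,
    abs(age_activity_cor) < 1, multiple_r > 0, multiple_r < 1,
    mvpa_sd > 0, zbmi_sd > 0, whtr_sd > 0,
    identical(sort(items$item), sort(pau_items())),
    identical(names(criterion_slopes), c("age", "sex", "mvpa_q", "weight"))
  )
  structure(
    list(n = n, age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         p_boy = p_boy, weight_mean = weight_mean, weight_sd = weight_sd,
         weight_min = weight_min, age_weight_cor = age_weight_cor,
         height_mean = height_mean, height_age_slope = height_age_slope,
         height_resid_sd = height_resid_sd, height_min = height_min,
         items = items, admin1_scale = admin1_scale, latent_r = latent_r,
         retest_r = retest_r, age_activity_cor = age_activity_cor,
         mvpa_mean = mvpa_mean, mvpa_sd = mvpa_sd,
         criterion_mean = criterion_mean,
         criterion_slopes = criterion_slopes, multiple_r = multiple_r,
         zbmi_mean = zbmi_mean, zbmi_sd = zbmi_sd, zbmi_slope = zbmi_slope,
         whtr_mean = whtr_mean, whtr_sd = whtr_sd, whtr_slope = whtr_slope,
         alpha_target = alpha_target, retest_icc_target = retest_icc_target,
         marginal_spearman_target = marginal_spearman_target,
         aquatic_p = aquatic_p, sick_p = sick_p),
    class = "sim_config"
  )
}

# mean and sd of N(mu, sigma) truncated to [lo, hi]
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# parent parameters whose truncated moments equal the targets
truncnorm_match <- function(mean, sd, lo, hi) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo[1] - mean)^2 + (mo[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- truncnorm_match(mean, sd, lo, hi)
  lo_p <- stats::pnorm((lo - p[1]) / p[2])
  hi_p <- stats::pnorm((hi - p[1]) / p[2])
  p[1] + p[2] * qnorm(runif(n, lo_p, hi_p))
}

# distribute latent weekly minutes over allowed days, one bin per day,
# greedily assigning the bin nearest to what remains
discretize_item <- function(weekly, n_days, bin_values) {
  n <- length(weekly)
  bins <- sort(unname(bin_values))
  mid <- (bins[-length(bins)] + bins[-1]) / 2
  codes <- matrix(0L, n, n_days)
  remaining <- pmax(weekly, 0)
  for (d in seq_len(n_days)) {
    target <- pmin(remaining, bins[length(bins)])
    idx <- findInterval(target, mid) + 1L
    codes[, d] <- idx - 1L
    remaining <- pmax(remaining - bins[idx], 0)
  }
  codes
}

#' Simulate a synthetic validation cohort
#'
#' Generates demographics, two questionnaire administrations at item x day x
#' bin resolution, criterion accelerometer MVPA and adiposity outcomes, with
#' the structure described in [sim_config()]. Item responses come from a
#' one-factor equicorrelated latent model (shared person factor, stable
#' item-person component, administration noise sized for the retest target),
#' are discretised to day-by-bin grids and then *scored with the package's
#' own scorer*, so the recorded scored values round-trip exactly. The
#' criterion is the true linear calibration predictor plus Gaussian noise
#' whose SD solves the target multiple correlation on each cohort.
#'
#' @param n Cohort size (defaults to `config$n`).
#' @param seed Integer seed; same seed and config give a bit-identical
#'   cohort.
#' @param config A [sim_config()].
#' @param pau A [pau_config()] used for discretisation and scoring.
#' @return A list of class `"pau_cohort"`: `cohort` (one row per
#'   participant: demographics, `mvpa_q1`, `mvpa_q2`, `mvpa_q` (the
#'   administration selected in `pau`), `mvpa_accel`, `zbmi`, `whtr`,
#'   `accel_valid`), `responses` (wide questionnaire rows, two per
#'   participant), `scored` (scored activities per administration), and
#'   `truth` (latent values, the criterion linear predictor and residual SD).
#' @examples
#' sim <- simulate_cohort(n = 200, seed = 42)
#' dplyr::glimpse(sim$cohort)
#' @export
simulate_cohort <- function(n = NULL, seed = NULL, config = sim_config(),
                            pau = pau_config()) {
  stopifnot(inherits(config, "sim_config"))
  pau <- as_pau_config(pau)
  n <- n %||% config$n
  if (!is.null(seed)) set.seed(seed)

  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  z_age <- (age - config$age_mean) / config$age_sd
  sex_num <- rbinom(n, 1, config$p_boy)
  rho_w <- config$age_weight_cor
  weight <- pmax(config$weight_min,
                 config$weight_mean + config$weight_sd *
                   (rho_w * z_age + sqrt(1 - rho_w^2) * rnorm(n)))
  height <- pmax(config$height_min,
                 config$height_mean +
                   config$height_age_slope * (age - config$age_mean) +
                   rnorm(n, 0, config$height_resid_sd))

  # latent activity factor, tied (negatively) to age
  g <- config$age_activity_cor
  f <- g * z_age + sqrt(1 - g^2) * rnorm(n)

  items <- config$items
  k <- nrow(items)
  r <- config$latent_r
  rt <- config$retest_r
  stable <- sqrt(r) * matrix(f, n, k) + sqrt(1 - r) * matrix(rnorm(n * k), n, k)
  latent_admin <- function() {
    noise <- sqrt(r) * matrix(rnorm(n), n, k) +
      sqrt(1 - r) * matrix(rnorm(n * k), n, k)
    sqrt(rt) * stable + sqrt(1 - rt) * noise
  }
  t1 <- latent_admin()
  t2 <- latent_admin()

  build_admin <- function(tmat, admin, scale) {
    resp <- tibble(participant_id = sprintf("P%04d", seq_len(n)),
                   administration = as.integer(admin))
    weekly_latent <- matrix(0, n, k, dimnames = list(NULL, items$item))
    for (j in seq_len(k)) {
      item <- items$item[j]
      w <- pmax(7 * (items$mean[j] * scale + items$sd[j] * tmat[, j]), 0)
      weekly_latent[, j] <- w
      days <- item_days(item)
      if (item == "PE") {
        nd <- pmin(length(days), pmax(0, round(w / pau$pe_minutes)))
        codes <- outer(nd, seq_along(days), ">=") * 1L
      } else {
        codes <- discretize_item(w, length(days), pau$bin_minutes)
      }
      colnames(codes) <- paste(item, days, sep = "_")
      resp <- dplyr::bind_cols(resp, as_tibble(codes))
    }
    resp$aquatic <- rbinom(n, 1, config$aquatic_p)
    resp$sick <- rbinom(n, 1, config$sick_p)
    list(resp = resp, weekly_latent = weekly_latent)
  }
  a1 <- build_admin(t1, 1, config$admin1_scale)
  a2 <- build_admin(t2, 2, 1)
  responses <- dplyr::bind_rows(a1$resp, a2$resp)
  scored <- score_pau7s(responses, pau)

  s1 <- scored[scored$administration == 1, ]
  s2 <- scored[scored$administration == 2, ]
  mvpa_q1 <- s1$mvpa
  mvpa_q2 <- s2$mvpa
  mvpa_q <- if (pau$administration == 2) mvpa_q2 else mvpa_q1

  b <- config$criterion_slopes
  lp <- b[["age"]] * (age - config$age_mean) +
    b[["sex"]] * (sex_num - config$p_boy) +
    b[["mvpa_q"]] * (mvpa_q - config$mvpa_mean) +
    b[["weight"]] * (weight - config$weight_mean)
  sd_lp <- sd(lp)
  if (sd_lp <= 0) abort("Degenerate criterion linear predictor.")
  resid_sd <- sd_lp * sqrt(1 / config$multiple_r^2 - 1)
  # a child wearing the device over valid days never logs exactly zero MVPA:
  # truncate the residual below zero by rejection (affects < 1% of draws)
  mvpa_accel <- config$criterion_mean + lp + rnorm(n, 0, resid_sd)
  for (tries in 1:50) {
    bad_idx <- which(mvpa_accel <= 0)
    if (!length(bad_idx)) break
    mvpa_accel[bad_idx] <- config$criterion_mean + lp[bad_idx] +
      rnorm(length(bad_idx), 0, resid_sd)
  }
  mvpa_accel <- pmax(mvpa_accel, 0.5)

  q100 <- (mvpa_q - config$mvpa_mean) / 100
  zbmi_noise_sd <- sqrt(max(config$zbmi_sd^2 -
                              (config$zbmi_slope * sd(q100))^2, 1e-8))
  zbmi <- config$zbmi_mean + config$zbmi_slope * q100 +
    rnorm(n, 0, zbmi_noise_sd)
  whtr_noise_sd <- sqrt(max(config$whtr_sd^2 -
                              (config$whtr_slope * sd(q100))^2, 1e-12))
  whtr <- pmax(0.30, config$whtr_mean + config$whtr_slope * q100 +
                 rnorm(n, 0, whtr_noise_sd))
  waist <- whtr * height

  cohort <- tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    sex = factor(ifelse(sex_num == 1, "boy", "girl"),
                 levels = c("girl", "boy")),
    age = age, weight = weight, height = height, waist = waist,
    zbmi = zbmi, whtr = whtr,
    mvpa_q1 = mvpa_q1, mvpa_q2 = mvpa_q2, mvpa_q = mvpa_q,
    mvpa_accel = mvpa_accel, accel_valid = TRUE
  )
  structure(
    list(cohort = cohort, responses = responses, scored = scored,
         truth = list(activity_factor = f,
                      weekly_latent_admin1 = a1$weekly_latent,
                      weekly_latent_admin2 = a2$weekly_latent,
                      linear_predictor = unname(lp), residual_sd = resid_sd,
                      criterion_slopes = b, config = config)),
    class = "pau_cohort"
  )
}

#' @export
print.pau_cohort <- function(x, ...) {
  cat("<pau_cohort> n =", nrow(x$cohort), "\n")
  print(x$cohort, n = 5)
  invisible(x)
}

#' Simulate an accelerometer epoch stream with planted ground truth
#'
#' Builds a 5-s epoch count series over whole calendar days. Nights
#' (outside `wear_start`-`wear_end`) are zero counts; worn time is filled
#' with sedentary counts; activity bouts and daytime non-wear blocks are
#' planted per the schedule. Counts are drawn strictly inside the configured
#' intensity band (never on a cut-point boundary), so the planted per-day
#' intensity minutes are recovered exactly by [process_accelerometry()].
#'
#' @param participant_id Identifier.
#' @param n_days Number of whole days, starting `start` (default Monday
#'   2019-04-01, so 7 days include one weekend).
#' @param start Start date.
#' @param bouts Optional tibble `day` (1-based), `start_min` (minutes from
#'   midnight), `duration_min`, `type` in
#'   `sedentary/light/moderate/vigorous/nonwear`. When `NULL`, a default
#'   daily schedule plants `light_minutes` at 12:00, `moderate_minutes` at
#'   10:00, `vigorous_minutes` at 17:00 and (if positive)
#'   `nonwear_block_minutes` at 14:00.
#' @param moderate_minutes,vigorous_minutes,light_minutes,nonwear_block_minutes
#'   Default daily schedule quantities (minutes).
#' @param wear_start,wear_end Hours between which the device is worn each
#'   day (baseline sedentary); default 8 to 21.5.
#' @param seed Optional seed.
#' @param config A [pau_config()] supplying epoch length and cut-points.
#' @return Epoch tibble (`participant_id`, `timestamp`, `vm`) with a
#'   `"truth"` attribute: per-day planted minutes per intensity inside the
#'   wear window.
#' @export
simulate_epoch_stream <- function(participant_id = "P1", n_days = 7,
                                  start = as.Date("2019-04-01"), bouts = NULL,
                                  moderate_minutes = 45, vigorous_minutes = 15,
                                  light_minutes = 60,
                                  nonwear_block_minutes = 0,
                                  wear_start = 8, wear_end = 21.5,
                                  seed = NULL, config = pau_config()) {
  config <- as_pau_config(config)
  if (!is.null(seed)) set.seed(seed)
  cp <- config$cutpoints
  bands <- list(
    sedentary = c(1, cp[["light"]] - 2),
    light = c(cp[["light"]] + 1, cp[["moderate"]] - 2),
    moderate = c(cp[["moderate"]] + 1, cp[["vigorous"]] - 2),
    vigorous = c(cp[["vigorous"]] + 1, cp[["vigorous"]] + 1500)
  )
  bad <- names(bands)[vapply(bands, function(b) b[2] < b[1], logical(1))]
  if (length(bad)) {
    abort(paste0("Cut-point bands too narrow to draw counts strictly ",
                 "inside: ", paste(bad, collapse = ", "), "."))
  }
  if (is.null(bouts)) {
    per_day <- tibble(
      start_min = c(10 * 60, 12 * 60, 17 * 60,
                    if (nonwear_block_minutes > 0) 14 * 60),
      duration_min = c(moderate_minutes, light_minutes, vigorous_minutes,
                       if (nonwear_block_minutes > 0) nonwear_block_minutes),
      type = c("moderate", "light", "vigorous",
               if (nonwear_block_minutes > 0) "nonwear")
    )
    per_day <- per_day[per_day$duration_min > 0, ]
    bouts <- dplyr::bind_rows(lapply(seq_len(n_days), function(d)
      dplyr::mutate(per_day, day = d)))
  }
  if (nrow(bouts)) {
    stopifnot(all(c("day", "start_min", "duration_min", "type") %in%
                    names(bouts)))
    if (any(!bouts$type %in% c(names(bands), "nonwear"))) {
      abort("Bout `type` must be sedentary/light/moderate/vigorous/nonwear.")
    }
    if (any(bouts$start_min + bouts$duration_min > 24 * 60)) {
      abort("A bout runs past midnight; schedule bouts within the day.")
    }
    if (any(bouts$type == "nonwear" & bouts$duration_min > 0 &
            bouts$duration_min < config$min_zero_run)) {
      warn("A planted non-wear block is shorter than `min_zero_run` and will be retained as wear.")
    }
  }

  epd <- as.integer(24 * 3600 / config$epoch_length) # epochs per day
  labels <- character(n_days * epd)
  minute_of_epoch <- (rep(seq_len(epd), n_days) - 1) *
    config$epoch_length / 60
  day_of_epoch <- rep(seq_len(n_days), each = epd)
  worn <- minute_of_epoch >= wear_start * 60 & minute_of_epoch < wear_end * 60
  labels[!worn] <- "nonwear"
  labels[worn] <- "sedentary"
  for (i in seq_len(nrow(bouts))) {
    sel <- day_of_epoch == bouts$day[i] &
      minute_of_epoch >= bouts$start_min[i] &
      minute_of_epoch < bouts$start_min[i] + bouts$duration_min[i]
    labels[sel] <- bouts$type[i]
  }
  vm <- numeric(length(labels))
  for (type in names(bands)) {
    sel <- labels == type
    if (any(sel)) {
      vm[sel] <- sample(seq(bands[[type]][1], bands[[type]][2]), sum(sel),
                        replace = TRUE)
    }
  }
  ts0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  epochs <- tibble(
    participant_id = participant_id,
    timestamp = ts0 + (seq_along(labels) - 1) * config$epoch_length,
    vm = vm
  )
  in_window <- minute_of_epoch >= config$wear_window[1] * 60 &
    minute_of_epoch < config$wear_window[2] * 60
  truth <- tibble(date = start + day_of_epoch - 1, label = labels,
                  in_window = in_window) |>
    dplyr::filter(.data$label != "nonwear", .data$in_window) |>
    dplyr::count(.data$date, .data$label) |>
    dplyr::mutate(minutes = .data$n * config$epoch_length / 60, n = NULL) |>
    tidyr::pivot_wider(names_from = "label", values_from = "minutes",
                       values_fill = 0)
  for (type in names(bands)) {
    if (!type %in% names(truth)) truth[[type]] <- 0
  }
  attr(epochs, "truth") <- truth
  epochs
}

#' Check a generated cohort against its moment targets
#'
#' Recomputes the observable quantities the generator aims for - age and
#' weight moments, scored questionnaire MVPA mean/SD, Cronbach alpha over
#' the six item scores, test-retest ICC, criterion mean/SD, the marginal
#' Spearman correlation, the calibrated (multiple) correlation, and the
#' construct-validity slopes - and compares each against its target at the
#' given tolerance.
#'
#' @param sim A `"pau_cohort"` from [simulate_cohort()].
#' @param config The [sim_config()] used (defaults to the one recorded in
#'   the cohort's truth).
#' @param tolerances Named list of absolute tolerances; sensible defaults
#'   scale like sampling noise at n = 10000.
#' @param pau A [pau_config()].
#' @return A tibble `check`, `target`, `achieved`, `tolerance`, `pass`.
#' @export
verify_moments <- function(sim, config = NULL,
                           tolerances = list(), pau = pau_config()) {
  stopifnot(inherits(sim, "pau_cohort"))
  config <- config %||% sim$truth$config
  pau <- as_pau_config(pau)
  tol <- modifyList(list(
    age_mean = 0.1, age_sd = 0.1, weight_mean = 0.6, weight_sd = 0.6,
    mvpa_mean = 3, mvpa_sd = 3, alpha = 0.03, retest_icc = 0.03,
    criterion_mean = 2, criterion_sd = 3, marginal_spearman = 0.04,
    multiple_r = 0.03, zbmi_slope = 0.06, whtr_slope = 0.003
  ), tolerances)
  co <- sim$cohort
  acts <- c("walking", "recess_play", "free_play", "physical_education",
            "team_sport", "individual_sport")
  s_sel <- sim$scored[sim$scored$administration == pau$administration, ]
  alpha <- cronbach_alpha(s_sel[acts])$alpha
  retest <- icc(cbind(co$mvpa_q1, co$mvpa_q2), pau$icc_model)$icc
  fit <- fit_calibration(co, pau)
  marg <- validity_correlation(co$mvpa_q, co$mvpa_accel, "spearman")$estimate
  zb <- construct_validity(co, "zbmi", config = pau)$beta
  wh <- construct_validity(co, "whtr", config = pau)$beta
  rows <- tibble(
    check = c("age_mean", "age_sd", "weight_mean", "weight_sd", "mvpa_mean",
              "mvpa_sd", "alpha", "retest_icc", "criterion_mean",
              "criterion_sd", "marginal_spearman", "multiple_r",
              "zbmi_slope", "whtr_slope"),
    target = c(config$age_mean, config$age_sd, config$weight_mean,
               config$weight_sd, config$mvpa_mean, config$mvpa_sd,
               config$alpha_target, config$retest_icc_target,
               config$criterion_mean, config$criterion_mean *
                 NA, # placeholder replaced below
               config$marginal_spearman_target, config$multiple_r,
               config$zbmi_slope, config$whtr_slope),
    achieved = c(mean(co$age), sd(co$age), mean(co$weight), sd(co$weight),
                 mean(co$mvpa_q), sd(co$mvpa_q), alpha, retest,
                 mean(co$mvpa_accel), sd(co$mvpa_accel), marg,
                 sqrt(fit$r_squared), zb, wh)
  )
  rows$target[rows$check == "criterion_sd"] <-
    sd(sim$truth$linear_predictor) / config$multiple_r
  rows$tolerance <- unlist(tol[rows$check], use.names = FALSE)
  rows$pass <- abs(rows$achieved - rows$target) <= rows$tolerance
  rows
}
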