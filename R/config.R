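#' Analysis configuration for the PAU-7S pipeline
#'
#' Central container for every tunable of the pipeline: questionnaire bin
#' minutes, the physical-education (PE) constant, accelerometer cut-points and
#' wear rules, the reliability/agreement model choices, and the sex coding
#' used by the calibration model. Every function in the package takes its
#' defaults from this object, so an analysis is fully described by one config.
#'
#' @param bin_minutes Named numeric vector mapping the response-time bins to
#'   minutes per marked day. The instrument offers four time bins per day
#'   (under 30 min, 30-60 min, 60-90 min, over 90 min); defaults are the
#'   interval midpoints with midpoint extrapolation for the open top bin:
#'   `c(NONE = 0, LT30 = 15, B30_60 = 45, B60_90 = 75, GT90 = 105)`.
#' @param pe_minutes Minutes credited per marked PE day (the PE item has no
#'   time bins). Default 30.
#' @param cutpoints Named increasing numeric vector of lower bounds (counts
#'   per epoch) for `light`, `moderate` and `vigorous` intensity; counts below
#'   `cutpoints["light"]` are sedentary. Defaults are wrist vector-magnitude
#'   thresholds for 5-s epochs in children: light 306, moderate 818,
#'   vigorous 1969. Intervals are closed on the lower bound. If you change
#'   `epoch_length` you must supply cut-points on the matching scale.
#' @param epoch_length Epoch duration in seconds (default 5).
#' @param min_zero_run Minimum duration, in minutes, of a run of zero counts
#'   for it to be flagged as non-wear (default 60).
#' @param zero_run_tolerance Minutes of non-zero interruption tolerated inside
#'   a zero run before it is split (default 0: strict zeros).
#' @param wear_window Numeric length-2, start and end hour of the daily wear
#'   accounting window; default `c(8, 22)` i.e. 08:00-22:00 (840 min).
#' @param min_wear_minutes Minimum worn minutes inside the window for a day to
#'   be valid (default 600, i.e. 10 h, compared with `>=`).
#' @param min_valid_days,min_weekend_days Participant validity rule: at least
#'   `min_valid_days` valid days (default 4) of which at least
#'   `min_weekend_days` fall on a weekend (default 1).
#' @param icc_model Intraclass-correlation flavour: `"consistency"` (two-way
#'   mixed, single measures; default) or `"agreement"` (two-way random,
#'   absolute agreement, single measures).
#' @param kappa_weights `"linear"` (default) or `"quadratic"` weights for the
#'   weighted kappa on tercile cross-classification.
#' @param agreement_ratio Direction of the proportional-agreement ratio:
#'   `"test_over_criterion"` (default) or `"criterion_over_test"`.
#' @param sex_male Numeric code given to boys in the calibration design matrix
#'   (girls get `1 - sex_male`); default 1.
#' @param administration Which questionnaire administration (1 or 2) feeds
#'   validity analyses; default 2, the one covering the accelerometer week.
#' @param conf_level Confidence level for every interval (default 0.95).
#'
#' @return A list of class `"pau_config"`.
#' @examples
#' cfg <- pau_config(pe_minutes = 45)
#' cfg$bin_minutes
#' @export
pau_config <- function(bin_minutes = c(NONE = 0, LT30 = 15, B30_60 = 45,
                                       B60_90 = 75, GT90 = 105),
                       pe_minutes = 30,
                       cutpoints = c(light = 306, moderate = 818,
                                     vigorous = 1969),
                       epoch_length = 5,
                       min_zero_run = 60,
                       zero_run_tolerance = 0,
                       wear_window = c(8, 22),
                       min_wear_minutes = 600,
                       min_valid_days = 4,
                       min_weekend_days = 1,
                       icc_model = c("consistency", "agreement"),
                       kappa_weights = c("linear", "quadratic"),
                       agreement_ratio = c("test_over_criterion",
                                           "criterion_over_test"),
                       sex_male = 1,
                       administration = 2,
                       conf_level = 0.95) {
  icc_model <- match.arg(icc_model)
  kappa_weights <- match.arg(kappa_weights)
  agreement_ratio <- match.arg(agreement_ratio)

  bins <- c("NONE", "LT30", "B30_60", "B60_90", "GT90")
  if (!identical(names(bin_minutes), bins)) {
    abort("`bin_minutes` must be named NONE, LT30, B30_60, B60_90, GT90 in order.")
  }
  if (bin_minutes[["NONE"]] != 0) {
    abort("`bin_minutes[\"NONE\"]` must be 0: no mark means no activity time.")
  }
  if (any(diff(bin_minutes) <= 0)) {
    abort("`bin_minutes` must be strictly increasing across the bins.")
  }
  if (!identical(names(cutpoints), c("light", "moderate", "vigorous")) ||
      any(diff(cutpoints) <= 0) || any(cutpoints <= 0)) {
    abort("`cutpoints` must be positive, strictly increasing and named light, moderate, vigorous.")
  }
  if (length(wear_window) != 2 || wear_window[1] >= wear_window[2] ||
      wear_window[1] < 0 || wear_window[2] > 24) {
    abort("`wear_window` must be c(start_hour, end_hour) within 0-24, start < end.")
  }
  stopifnot(
    epoch_length > 0, min_zero_run > 0, zero_run_tolerance >= 0,
    min_wear_minutes > 0, min_valid_days >= 1, min_weekend_days >= 0,
    pe_minutes >= 0, administration %in% c(1, 2),
    conf_level > 0, conf_level < 1, sex_male %in% c(0, 1)
  )
  window_minutes <- diff(wear_window) * 60
  if (min_wear_minutes > window_minutes) {
    abort("`min_wear_minutes` exceeds the wear-window length.")
  }

  structure(
    list(
      bin_minutes = bin_minutes, pe_minutes = pe_minutes,
      cutpoints = cutpoints, epoch_length = epoch_length,
      min_zero_run = min_zero_run, zero_run_tolerance = zero_run_tolerance,
      wear_window = wear_window, min_wear_minutes = min_wear_minutes,
      min_valid_days = min_valid_days, min_weekend_days = min_weekend_days,
      icc_model = icc_model, kappa_weights = kappa_weights,
      agreement_ratio = agreement_ratio, sex_male = sex_male,
      administration = administration, conf_level = conf_level
    ),
    class = "pau_config"
  )
}

#' @export
print.pau_config <- function(x, ...) {
  cat("<pau_config>\n")
  cat("  bin minutes:      ", paste(names(x$bin_minutes), x$bin_minutes,
                                    sep = "=", collapse = " "), "\n")
  cat("  PE minutes/day:   ", x$pe_minutes, "\n")
  cat("  cut-points:       ", paste(names(x$cutpoints), x$cutpoints,
                                    sep = ">=", collapse = " "),
      sprintf(" (counts/%gs)", x$epoch_length), "\n")
  cat("  non-wear:         ", x$min_zero_run, "min zero run, tolerance",
      x$zero_run_tolerance, "min\n")
  cat("  wear window:      ", sprintf("%02d:00-%02d:00", x$wear_window[1],
                                      x$wear_window[2]),
      "; valid day >=", x$min_wear_minutes, "min\n")
  cat("  valid participant: >=", x$min_valid_days, "days incl. >=",
      x$min_weekend_days, "weekend\n")
  cat("  ICC:", x$icc_model, "| kappa:", x$kappa_weights,
      "| agreement ratio:", x$agreement_ratio, "\n")
  cat("  sex coding: boy =", x$sex_male, "| administration:",
      x$administration, "| conf:", x$conf_level, "\n")
  invisible(x)
}

as_pau_config <- function(config) {
  if (inherits(config, "pau_config")) return(config)
  if (is.list(config)) return(do.call(pau_config, config))
  abort("`config` must be a pau_config() object or a list of its arguments.")
}

#' Read and write a run configuration as flat key=value text
#'
#' The on-disk format is one `key = value` pair per line (vectors
#' comma-separated, named vectors as `name:value`), so a configuration file
#' round-trips losslessly and can be edited by hand or diffed.
#'
#' @param config A [pau_config()] object.
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly; `read_run_config()`
#'   returns a `pau_config`.
#' @examples
#' p <- tempfile(fileext = ".cfg")
#' write_run_config(pau_config(), p)
#' identical(read_run_config(p), pau_config())
#' @export
write_run_config <- function(config, path) {
  config <- as_pau_config(config)
  fmt <- function(v) {
    if (!is.null(names(v)) && any(names(v) != "")) {
      paste(names(v), format(v, digits = 15, trim = TRUE, scientific = FALSE),
            sep = ":", collapse = ",")
    } else if (is.character(v)) {
      paste(v, collapse = ",")
    } else {
      paste(format(v, digits = 15, trim = TRUE, scientific = FALSE),
            collapse = ",")
    }
  }
  lines <- vapply(names(config), function(k) paste(k, "=", fmt(config[[k]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), character(1))
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")),
                 character(1))
  character_keys <- c("icc_model", "kappa_weights", "agreement_ratio")
  parse1 <- function(key, val) {
    parts <- strsplit(val, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      pieces <- strsplit(parts, ":", fixed = TRUE)
      out <- as.numeric(vapply(pieces, `[`, character(1), 2))
      names(out) <- vapply(pieces, `[`, character(1), 1)
      out
    } else if (key %in% character_keys) {
      parts
    } else {
      as.numeric(parts)
    }
  }
  args <- Map(parse1, keys, vals)
  names(args) <- keys
  do.call(pau_config, args)
}
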