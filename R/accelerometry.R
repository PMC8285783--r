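#' Read an ActiLife-style epoch-count export
#'
#' Reads a CSV of timestamped accelerometer counts at a fixed epoch length.
#' Expected columns (case/punctuation-insensitive): `Timestamp`, `Axis1`,
#' `Axis2`, `Axis3` and optionally `Vector Magnitude`; when the vector
#' magnitude column is absent it is computed as the Euclidean norm of the
#' three axes. Extra header lines (device preamble) can be skipped.
#'
#' @param path CSV path.
#' @param skip Number of preamble lines to skip before the header (default 0).
#' @param tz Time zone for timestamps (default `"UTC"`).
#' @param ts_format Timestamp format string (default `"%Y-%m-%d %H:%M:%S"`).
#' @return A tibble with `timestamp` (POSIXct), any axis columns, and `vm`.
#' @export
read_epoch_counts <- function(path, skip = 0, tz = "UTC",
                              ts_format = "%Y-%m-%d %H:%M:%S") {
  raw <- readr::read_csv(path, skip = skip, show_col_types = FALSE,
                         progress = FALSE)
  nm <- tolower(gsub("[^A-Za-z0-9]", "", names(raw)))
  lookup <- c(timestamp = "timestamp", axis1 = "axis1", axis2 = "axis2",
              axis3 = "axis3", vectormagnitude = "vm", vm = "vm",
              participantid = "participant_id")
  known <- nm %in% names(lookup)
  names(raw)[known] <- lookup[nm[known]]
  if (!"timestamp" %in% names(raw)) {
    abort(paste0("No Timestamp column found in ", path, "."))
  }
  if (!inherits(raw$timestamp, "POSIXct")) {
    raw$timestamp <- as.POSIXct(as.character(raw$timestamp),
                                format = ts_format, tz = tz)
    if (anyNA(raw$timestamp)) {
      abort("Some timestamps failed to parse; check `ts_format` and `skip`.")
    }
  }
  if (!"vm" %in% names(raw)) {
    axes <- intersect(c("axis1", "axis2", "axis3"), names(raw))
    if (!length(axes)) {
      abort("Need either a Vector Magnitude column or Axis1-Axis3 columns.")
    }
    raw$vm <- sqrt(rowSums(as.matrix(raw[axes])^2))
  }
  as_tibble(raw)
}

validate_epochs <- function(epochs, config) {
  if (!is.data.frame(epochs) || nrow(epochs) == 0) {
    abort("`epochs` must be a non-empty data frame of epoch counts.")
  }
  if (!all(c("timestamp", "vm") %in% names(epochs))) {
    abort("`epochs` needs `timestamp` and `vm` columns (see read_epoch_counts()).")
  }
  if (any(epochs$vm < 0, na.rm = TRUE) || anyNA(epochs$vm)) {
    abort("Counts (`vm`) must be non-negative and non-missing.")
  }
  check1 <- function(ts) {
    d <- diff(as.numeric(ts))
    if (any(d <= 0)) abort("Timestamps must be strictly increasing.")
    if (any(abs(d - config$epoch_length) > 1e-6)) {
      abort(paste0("Timestamps must be uniformly spaced at the epoch length (",
                   config$epoch_length, " s); aggregate first if needed ",
                   "(see aggregate_epochs())."))
    }
  }
  if ("participant_id" %in% names(epochs)) {
    invisible(lapply(split(epochs$timestamp, epochs$participant_id), check1))
  } else {
    check1(epochs$timestamp)
  }
  epochs
}

#' Aggregate epoch counts to a coarser epoch length
#'
#' Sums counts over `factor` consecutive epochs. Axis columns are summed and
#' the vector magnitude recomputed from the summed axes when they are present;
#' otherwise `vm` itself is summed.
#'
#' @param epochs Epoch tibble (see [read_epoch_counts()]).
#' @param factor Integer >= 1; the new epoch length is `factor` times the old.
#' @param config A [pau_config()] describing the *input* epoch length.
#' @return An epoch tibble at the coarser resolution.
#' @export
aggregate_epochs <- function(epochs, factor, config = pau_config()) {
  config <- as_pau_config(config)
  stopifnot(factor >= 1, factor == floor(factor))
  epochs <- validate_epochs(epochs, config)
  if (factor == 1) return(epochs)
  agg1 <- function(df) {
    grp <- (seq_len(nrow(df)) - 1L) %/% factor
    axes <- intersect(c("axis1", "axis2", "axis3"), names(df))
    out <- dplyr::summarise(
      dplyr::group_by(df, .grp = grp),
      timestamp = .data$timestamp[1],
      dplyr::across(dplyr::all_of(c(axes, "vm")), sum),
      .groups = "drop"
    )
    if (length(axes)) out$vm <- sqrt(rowSums(as.matrix(out[axes])^2))
    dplyr::select(out, -".grp")
  }
  if ("participant_id" %in% names(epochs)) {
    dplyr::group_modify(dplyr::group_by(epochs, .data$participant_id),
                        ~ agg1(.x)) |> dplyr::ungroup()
  } else {
    agg1(epochs)
  }
}

nonwear_mask <- function(zero, epoch_length, min_zero_run, tolerance) {
  r <- rle(zero)
  minutes <- r$lengths * epoch_length / 60
  nonwear_run <- logical(length(r$lengths))
  if (tolerance > 0 && length(r$lengths) > 2) {
    # absorb short non-zero interruptions between zero runs, then re-test the
    # merged span against the minimum duration
    absorbed <- !r$values & minutes <= tolerance &
      seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
    grp <- cumsum(!(r$values | absorbed)) # breaks at long non-zero runs
    zeroish <- r$values | absorbed
    for (g in unique(grp[zeroish])) {
      idx <- which(grp == g & zeroish)
      if (sum(minutes[idx]) >= min_zero_run) nonwear_run[idx] <- TRUE
    }
  } else {
    nonwear_run <- r$values & minutes >= min_zero_run
  }
  inverse.rle(list(lengths = r$lengths, values = nonwear_run))
}

#' Flag non-wear epochs from runs of zero counts
#'
#' An epoch is non-wear when it lies in a maximal run of zero counts lasting
#' at least `min_zero_run` minutes (default 60). Runs are evaluated on the
#' full series (they may straddle the wear window or midnight); windowing
#' happens later in [summarize_wear_days()]. A strictly-zero run is the
#' default; `zero_run_tolerance` permits short non-zero interruptions inside
#' a run.
#'
#' @param epochs Epoch tibble with `timestamp` and `vm` (grouped by
#'   `participant_id` when present).
#' @param config A [pau_config()] (`min_zero_run`, `zero_run_tolerance`,
#'   `epoch_length`).
#' @return The input with a logical `wear` column appended.
#' @export
detect_nonwear <- function(epochs, config = pau_config()) {
  config <- as_pau_config(config)
  epochs <- validate_epochs(epochs, config)
  run1 <- function(vm) {
    !nonwear_mask(vm == 0, config$epoch_length, config$min_zero_run,
                  config$zero_run_tolerance)
  }
  epochs$wear <- if ("participant_id" %in% names(epochs)) {
    unsplit(lapply(split(epochs$vm, epochs$participant_id), run1),
            epochs$participant_id)
  } else {
    run1(epochs$vm)
  }
  epochs
}

#' Classify worn epochs into intensity classes
#'
#' Applies the configured count cut-points (intervals closed on the lower
#' bound) to every worn epoch; non-worn epochs are left unlabelled (`NA`).
#'
#' @param epochs Epoch tibble; a `wear` column is added via [detect_nonwear()]
#'   if absent.
#' @inheritParams detect_nonwear
#' @return The input with `wear` and a factor `intensity` column
#'   (`sedentary < light < moderate < vigorous`).
#' @export
classify_intensity <- function(epochs, config = pau_config()) {
  config <- as_pau_config(config)
  if (!"wear" %in% names(epochs)) epochs <- detect_nonwear(epochs, config)
  lev <- c("sedentary", "light", "moderate", "vigorous")
  idx <- findInterval(epochs$vm, config$cutpoints) + 1L
  epochs$intensity <- factor(lev[idx], levels = lev)
  epochs$intensity[!epochs$wear] <- NA
  epochs
}

#' Per-day wear and intensity minutes inside the wear window
#'
#' For each participant and calendar day, accumulates worn minutes and
#' per-intensity minutes over epochs whose time of day falls in the wear
#' window (default 08:00-22:00, left-closed), and flags the day valid when
#' worn minutes reach `min_wear_minutes` (default 600 = 10 h).
#'
#' @inheritParams classify_intensity
#' @return A tibble with one row per participant x date: `date`, `weekend`,
#'   `wear_minutes`, `sedentary`, `light`, `moderate`, `vigorous` (minutes),
#'   and `valid`.
#' @export
summarize_wear_days <- function(epochs, config = pau_config()) {
  config <- as_pau_config(config)
  epochs <- classify_intensity(epochs, config)
  if (!"participant_id" %in% names(epochs)) epochs$participant_id <- "P1"
  tz <- attr(epochs$timestamp, "tzone") %||% "UTC"
  tod <- as.numeric(epochs$timestamp) -
    as.numeric(as.POSIXct(format(epochs$timestamp, "%Y-%m-%d", tz = tz),
                          tz = tz))
  epochs$in_window <- tod >= config$wear_window[1] * 3600 &
    tod < config$wear_window[2] * 3600
  epochs$date <- as.Date(format(epochs$timestamp, "%Y-%m-%d", tz = tz))
  min_per_epoch <- config$epoch_length / 60
  epochs$worn_in_window <- epochs$wear & epochs$in_window
  class_min <- function(worn, intensity, lev) {
    sum(worn & !is.na(intensity) & intensity == lev) * min_per_epoch
  }
  days <- dplyr::summarise(
    dplyr::group_by(epochs, .data$participant_id, .data$date),
    weekend = format(.data$date[1], "%u") %in% c("6", "7"),
    wear_minutes = sum(.data$worn_in_window) * min_per_epoch,
    sedentary = class_min(.data$worn_in_window, .data$intensity, "sedentary"),
    light = class_min(.data$worn_in_window, .data$intensity, "light"),
    moderate = class_min(.data$worn_in_window, .data$intensity, "moderate"),
    vigorous = class_min(.data$worn_in_window, .data$intensity, "vigorous"),
    .groups = "drop"
  )
  days$valid <- days$wear_minutes >= config$min_wear_minutes
  days
}

#' Participant-level accelerometer summary
#'
#' Applies the participant validity rule (at least `min_valid_days` valid
#' days including at least `min_weekend_days` weekend days) and averages
#' per-intensity minutes per day, unweighted, over valid days only. MVPA is
#' moderate plus vigorous minutes per day. Participants with no valid days
#' get `NA` means (never zero).
#'
#' @param days A day summary tibble from [summarize_wear_days()].
#' @inheritParams detect_nonwear
#' @return A tibble, one row per participant: `n_valid_days`,
#'   `n_valid_weekend_days`, `valid`, mean `sedentary`, `light`, `moderate`,
#'   `vigorous`, `wear_minutes`, and `mvpa` (min/day).
#' @export
summarize_participants <- function(days, config = pau_config()) {
  config <- as_pau_config(config)
  mean_valid <- function(x, valid) if (any(valid)) mean(x[valid]) else NA_real_
  out <- dplyr::summarise(
    dplyr::group_by(days, .data$participant_id),
    n_valid_days = sum(.data$valid),
    n_valid_weekend_days = sum(.data$valid & .data$weekend),
    sedentary = mean_valid(.data$sedentary, .data$valid),
    light = mean_valid(.data$light, .data$valid),
    moderate = mean_valid(.data$moderate, .data$valid),
    vigorous = mean_valid(.data$vigorous, .data$valid),
    wear_minutes = mean_valid(.data$wear_minutes, .data$valid),
    .groups = "drop"
  )
  out$valid <- out$n_valid_days >= config$min_valid_days &
    out$n_valid_weekend_days >= config$min_weekend_days
  out$mvpa <- out$moderate + out$vigorous
  dplyr::relocate(out, "valid", .after = "n_valid_weekend_days")
}

#' Full accelerometer reduction: epochs to criterion MVPA
#'
#' Runs non-wear detection, intensity classification, windowed day
#' accounting and the participant validity rule in one call.
#'
#' @inheritParams detect_nonwear
#' @return A list of class `"pau_accel"` with elements `days` (per-day
#'   summaries) and `participants` (per-participant summaries).
#' @examples
#' ep <- simulate_epoch_stream("P1", n_days = 7, seed = 1)
#' process_accelerometry(ep)$participants
#' @export
process_accelerometry <- function(epochs, config = pau_config()) {
  config <- as_pau_config(config)
  days <- summarize_wear_days(epochs, config)
  structure(
    list(days = days, participants = summarize_participants(days, config)),
    class = "pau_accel"
  )
}

#' @export
print.pau_accel <- function(x, ...) {
  cat("<pau_accel> ", nrow(x$participants), " participant(s), ",
      nrow(x$days), " day(s); ", sum(x$participants$valid),
      " valid participant(s)\n", sep = "")
  print(x$participants, ...)
  invisible(x)
}

#' Write accelerometer summaries as CSV
#'
#' @param accel A `"pau_accel"` object from [process_accelerometry()].
#' @param days_path,participants_path Output CSV paths (either may be `NULL`
#'   to skip).
#' @return `accel`, invisibly.
#' @export
write_accel_summaries <- function(accel, days_path = NULL,
                                  participants_path = NULL) {
  stopifnot(inherits(accel, "pau_accel"))
  if (!is.null(days_path)) {
    readr::write_csv(accel$days, days_path, progress = FALSE)
  }
  if (!is.null(participants_path)) {
    readr::write_csv(accel$participants, participants_path, progress = FALSE)
  }
  invisible(accel)
}
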