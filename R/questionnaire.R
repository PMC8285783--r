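#' @rdname score_pau7s
#' @export
pau_items <- function() {
  c("WALK", "RECESS_PLAY", "FREE_PLAY", "PE", "TEAM_SPORT", "INDIVIDUAL_SPORT")
}

#' @rdname score_pau7s
#' @export
pau_days <- function() c("MON", "TUE", "WED", "THU", "FRI", "SAT", "SUN")

school_days <- function() pau_days()[1:5]

# RECESS_PLAY and PE happen during school time: Monday-Friday only.
school_only_items <- function() c("RECESS_PLAY", "PE")

item_days <- function(item) {
  if (item %in% school_only_items()) school_days() else pau_days()
}

item_columns <- function(item) paste(item, item_days(item), sep = "_")

#' @rdname score_pau7s
#' @export
response_columns <- function() {
  c("participant_id", "administration",
    unlist(lapply(pau_items(), item_columns), use.names = FALSE),
    "aquatic", "sick")
}

# map the output (scored) column name of each item
item_output <- c(
  WALK = "walking", RECESS_PLAY = "recess_play", FREE_PLAY = "free_play",
  PE = "physical_education", TEAM_SPORT = "team_sport",
  INDIVIDUAL_SPORT = "individual_sport"
)

#' Minutes per day credited to a response-time bin
#'
#' @param bin_code Bin codes: integers 0-4 or names
#'   `NONE, LT30, B30_60, B60_90, GT90`.
#' @param config A [pau_config()].
#' @return Numeric vector of minutes per marked day.
#' @examples
#' bin_minutes(c(0, 1, 4))
#' bin_minutes("B30_60")
#' @export
bin_minutes <- function(bin_code, config = pau_config()) {
  config <- as_pau_config(config)
  bins <- names(config$bin_minutes)
  na <- is.na(bin_code)
  if (is.character(bin_code) || is.factor(bin_code)) {
    idx <- match(as.character(bin_code), bins)
  } else {
    bc <- as.integer(bin_code)
    idx <- ifelse(!na & bc >= 0 & bc <= 4, bc + 1L, NA_integer_)
  }
  if (anyNA(idx[!na])) {
    bad <- unique(bin_code[is.na(idx) & !na])
    abort(paste0("Unknown time-bin code(s): ", paste(bad, collapse = ", "),
                 ". Valid codes are 0-4 (", paste(bins, collapse = ", "), ")."))
  }
  idx[na] <- 1L  # an unmarked day contributes no time
  unname(config$bin_minutes[idx])
}

#' Score one item's day-by-bin marks into weekly minutes
#'
#' @param marks Named vector (names among `MON..SUN`) of bin codes; days
#'   absent from `marks` count as unmarked. For `PE` any non-zero mark counts
#'   the day at the fixed `pe_minutes` constant (the PE item has no time bins).
#' @param item One of [pau_items()].
#' @inheritParams bin_minutes
#' @return Weekly minutes for that item.
#' @examples
#' score_item(c(MON = 1, TUE = 1, WED = 1, THU = 1, FRI = 1), "RECESS_PLAY")
#' @export
score_item <- function(marks, item, config = pau_config()) {
  config <- as_pau_config(config)
  item <- match.arg(item, pau_items())
  if (is.null(names(marks)) || !all(names(marks) %in% pau_days())) {
    abort("`marks` must be named with days among MON..SUN.")
  }
  bad_days <- setdiff(names(marks)[marks != 0 & !is.na(marks)], item_days(item))
  if (length(bad_days)) {
    abort(paste0("Item ", item, " is school-time only (Monday-Friday); ",
                 "weekend mark on ", paste(bad_days, collapse = ", "), "."))
  }
  marks <- marks[names(marks) %in% item_days(item)]
  if (item == "PE") {
    sum(!is.na(marks) & marks != 0) * config$pe_minutes
  } else {
    sum(bin_minutes(marks, config))
  }
}

#' Build a one-row questionnaire response table
#'
#' Convenience constructor for a single PAU-7S administration in the wide
#' column layout used by [score_pau7s()] and [read_pau_responses()].
#'
#' @param participant_id Identifier.
#' @param administration 1 (baseline) or 2 (after the accelerometer week).
#' @param marks Named list, item -> named vector of day marks (see
#'   [score_item()]); items absent from the list are all-unmarked.
#' @param aquatic,sick The two qualitative flags (never used in scoring).
#' @return A one-row tibble with all [response_columns()].
#' @examples
#' week_response(marks = list(RECESS_PLAY = c(MON = 1, TUE = 1)))
#' @export
week_response <- function(participant_id = "P1", administration = 1,
                          marks = list(), aquatic = FALSE, sick = FALSE) {
  if (length(marks) && (is.null(names(marks)) ||
                        !all(names(marks) %in% pau_items()))) {
    abort("`marks` must be a named list with names among pau_items().")
  }
  row <- tibble(participant_id = as.character(participant_id),
                administration = as.integer(administration))
  for (item in pau_items()) {
    cols <- item_columns(item)
    vals <- setNames(rep(0L, length(cols)), cols)
    m <- marks[[item]]
    if (!is.null(m)) {
      if (is.null(names(m)) || !all(names(m) %in% pau_days())) {
        abort(paste0("Marks for ", item, " must be named with days MON..SUN."))
      }
      bad <- setdiff(names(m)[m != 0], item_days(item))
      if (length(bad)) {
        abort(paste0("Item ", item, " is school-time only (Monday-Friday); ",
                     "weekend mark on ", paste(bad, collapse = ", "), "."))
      }
      keep <- intersect(names(m), item_days(item))
      vals[paste(item, keep, sep = "_")] <- as.integer(m[keep])
    }
    row <- dplyr::bind_cols(row, as_tibble(as.list(vals)))
  }
  row$aquatic <- as.integer(aquatic)
  row$sick <- as.integer(sick)
  row
}

validate_responses <- function(responses, config) {
  if (!is.data.frame(responses)) {
    abort("`responses` must be a data frame of questionnaire rows.")
  }
  responses <- as_tibble(responses)
  if (!all(c("participant_id", "administration") %in% names(responses))) {
    abort("`responses` needs `participant_id` and `administration` columns.")
  }
  for (item in pau_items()) {
    cols <- item_columns(item)
    if (!any(cols %in% names(responses))) {
      abort(paste0("Item ", item, " is entirely missing from `responses` ",
                   "(expected columns ", cols[1], " .. ",
                   cols[length(cols)], ")."))
    }
    missing_cols <- setdiff(cols, names(responses))
    for (mc in missing_cols) responses[[mc]] <- 0L
    # weekend columns for school-only items may appear in a permissive file,
    # but any non-zero weekend mark is a schema violation
    if (item %in% school_only_items()) {
      extra <- paste(item, c("SAT", "SUN"), sep = "_")
      for (col in intersect(extra, names(responses))) {
        offending <- which(!is.na(responses[[col]]) & responses[[col]] != 0)
        if (length(offending)) {
          abort(paste0("Item ", item, " is school-time only (Monday-Friday); ",
                       "non-zero weekend mark in column ", col, " for ",
                       "participant(s) ",
                       paste(unique(responses$participant_id[offending]),
                             collapse = ", "), "."))
        }
      }
    }
    vals <- unlist(responses[cols], use.names = FALSE)
    vals <- vals[!is.na(vals)]
    if (length(vals) && (any(vals < 0) || any(vals > 4) ||
                         any(vals != floor(vals)))) {
      abort(paste0("Bin codes for ", item, " must be integers 0-4."))
    }
  }
  for (flag in c("aquatic", "sick")) {
    if (!flag %in% names(responses)) responses[[flag]] <- 0L
  }
  responses
}

#' Score PAU-7S questionnaire responses into minutes per day
#'
#' Converts the wide per-item, per-day time-bin marks of one or more PAU-7S
#' administrations into minutes per day of each activity, total physical
#' activity, and MVPA. Each marked day contributes the configured minutes of
#' its bin (PE days contribute the fixed `pe_minutes` constant); weekly
#' minutes are divided by 7. MVPA is the sum of all activities except
#' walking. The qualitative flags (`aquatic`, `sick`) are carried through
#' untouched and never enter the computation.
#'
#' @param responses Data frame with [response_columns()]: one row per
#'   participant x administration, bin codes 0-4 in `<ITEM>_<DAY>` columns
#'   (`NA` counts as unmarked). School-time items (`RECESS_PLAY`, `PE`) accept
#'   marks Monday-Friday only.
#' @inheritParams bin_minutes
#' @return A tibble, one row per input row: `participant_id`,
#'   `administration`, minutes/day for `walking`, `recess_play`, `free_play`,
#'   `physical_education`, `team_sport`, `individual_sport`, plus `total_pa`,
#'   `mvpa`, `aquatic` and `sick`.
#' @examples
#' resp <- week_response(marks = list(
#'   RECESS_PLAY = c(MON = 1, TUE = 1, WED = 1, THU = 1, FRI = 1)
#' ))
#' score_pau7s(resp)$recess_play  # 5 x 15 / 7 = 10.71 min/d
#' @export
score_pau7s <- function(responses, config = pau_config()) {
  config <- as_pau_config(config)
  responses <- validate_responses(responses, config)
  n <- nrow(responses)
  out <- tibble(
    participant_id = as.character(responses$participant_id),
    administration = as.integer(responses$administration)
  )
  for (item in pau_items()) {
    cols <- item_columns(item)
    m <- as.matrix(responses[cols])
    m[is.na(m)] <- 0
    weekly <- if (item == "PE") {
      rowSums(m != 0) * config$pe_minutes
    } else {
      rowSums(matrix(bin_minutes(m, config), nrow = n))
    }
    out[[item_output[[item]]]] <- weekly / 7
  }
  acts <- unname(item_output)
  out$total_pa <- rowSums(out[acts])
  out$mvpa <- out$total_pa - out$walking
  out$aquatic <- as.logical(responses$aquatic)
  out$sick <- as.logical(responses$sick)
  out
}

#' Read questionnaire responses / write scored activities as CSV
#'
#' `read_pau_responses()` reads the wide questionnaire layout (see
#' [response_columns()]); `write_scored_activities()` writes a
#' [score_pau7s()] result with display column names matching the usual
#' cohort-description table.
#'
#' @param path File path.
#' @param scored A tibble from [score_pau7s()].
#' @return `read_pau_responses()` a tibble; `write_scored_activities()`
#'   `path`, invisibly.
#' @export
read_pau_responses <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_pau_responses
#' @export
write_scored_activities <- function(scored, path) {
  display <- c(
    participant_id = "participant_id", administration = "administration",
    walking = "Walking (min/d)", recess_play = "Schoolyard active play (min/d)",
    free_play = "Non-school active play (min/d)",
    physical_education = "Physical education (min/d)",
    team_sport = "Team sport (min/d)",
    individual_sport = "Individual sport (min/d)",
    total_pa = "Total physical activity (min/d)", mvpa = "MVPA (min/d)",
    aquatic = "aquatic", sick = "sick"
  )
  keep <- intersect(names(display), names(scored))
  out <- scored[keep]
  names(out) <- display[keep]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
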