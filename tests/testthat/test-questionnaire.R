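test_that("bin minutes follow the configured midpoint map", {
  expect_equal(bin_minutes(0), 0)
  expect_equal(bin_minutes(c(1, 2, 3, 4)), c(15, 45, 75, 105))
  expect_equal(bin_minutes("GT90"), 105)
  expect_equal(bin_minutes(NA), 0)  # unmarked day
  cfg <- pau_config(bin_minutes = c(NONE = 0, LT30 = 10, B30_60 = 40,
                                    B60_90 = 70, GT90 = 100))
  expect_equal(bin_minutes(1, cfg), 10)
  expect_error(bin_minutes(7), "Unknown time-bin")
  expect_error(bin_minutes("LT15"), "Unknown time-bin")
})

test_that("item scoring sums marked days and respects the PE constant", {
  five_days <- stats::setNames(rep(1, 5), c("MON", "TUE", "WED", "THU", "FRI"))
  expect_equal(score_item(five_days, "RECESS_PLAY"), 75)
  expect_equal(score_item(stats::setNames(rep(0, 5), names(five_days)),
                          "RECESS_PLAY"), 0)
  all_week <- stats::setNames(rep(4, 7), pau_days())
  expect_equal(score_item(all_week, "WALK"), 7 * 105)
  # PE has no time bins: any mark counts the fixed constant
  expect_equal(score_item(c(MON = 1, WED = 3), "PE"), 60)
  expect_equal(score_item(c(MON = 1), "PE", pau_config(pe_minutes = 45)), 45)
  expect_error(score_item(c(SAT = 1), "RECESS_PLAY"), "school-time only.*SAT")
  expect_error(score_item(c(SUN = 2), "PE"), "school-time only.*SUN")
})

test_that("weekly scores convert to min/day and exclude walking from MVPA", {
  walk_only <- week_response(marks = list(
    WALK = stats::setNames(c(2, 3, 4, 1, 2, 3, 4), pau_days())
  ))
  s <- score_pau7s(walk_only)
  expect_equal(s$mvpa, 0)
  expect_equal(s$total_pa, s$walking)

  one_pe <- week_response(marks = list(PE = c(TUE = 1)))
  s <- score_pau7s(one_pe)
  expect_equal(s$physical_education, 30 / 7)
  expect_equal(s$mvpa, 30 / 7)

  empty <- week_response()
  s <- score_pau7s(empty)
  expect_equal(s$total_pa, 0)
  expect_equal(s$mvpa, 0)
  expect_true(all(s[c("walking", "recess_play", "free_play",
                      "physical_education", "team_sport",
                      "individual_sport")] == 0))
})

test_that("lowest-bin recess on all school days gives the 10.7 min/d median", {
  resp <- week_response(marks = list(
    RECESS_PLAY = stats::setNames(rep(1, 5), c("MON", "TUE", "WED", "THU", "FRI"))
  ))
  s <- score_pau7s(resp)
  expect_equal(s$recess_play, 75 / 7)
  expect_equal(round(s$recess_play, 1), 10.7)
})

test_that("responses with NA marks score as unmarked, whole-item absence errors", {
  resp <- week_response(marks = list(WALK = c(MON = 2)))
  resp$WALK_TUE <- NA_integer_
  expect_equal(score_pau7s(resp)$walking, 45 / 7)
  broken <- resp[setdiff(names(resp), paste0("PE_", c("MON", "TUE", "WED",
                                                      "THU", "FRI")))]
  expect_error(score_pau7s(broken), "Item PE is entirely missing")
  bad_code <- resp
  bad_code$WALK_MON <- 9
  expect_error(score_pau7s(bad_code), "integers 0-4")
})

test_that("weekend marks on school-time items are rejected with item and day", {
  resp <- week_response(marks = list(RECESS_PLAY = c(MON = 1)))
  resp$RECESS_PLAY_SAT <- 2L
  expect_error(score_pau7s(resp), "RECESS_PLAY.*SAT")
  expect_error(week_response(marks = list(PE = c(SUN = 1))),
               "PE.*school-time only")
})

random_response <- function(id, seed) {
  set.seed(seed)
  marks <- lapply(stats::setNames(pau_items(), pau_items()), function(item) {
    days <- if (item %in% c("RECESS_PLAY", "PE")) pau_days()[1:5] else pau_days()
    stats::setNames(sample(0:4, length(days), replace = TRUE), days)
  })
  week_response(id, 1, marks)
}

test_that("scoring identities hold on random responses", {
  for (seed in 1:25) {
    s <- score_pau7s(random_response("P", seed))
    expect_equal(s$mvpa + s$walking, s$total_pa)
    acts <- c("walking", "recess_play", "free_play", "physical_education",
              "team_sport", "individual_sport")
    expect_equal(sum(s[acts]), s$total_pa)
    expect_true(all(s[acts] >= 0))
  }
})

test_that("scores are additive over disjoint days and monotone in bins", {
  a <- week_response(marks = list(WALK = c(MON = 2, TUE = 3),
                                  TEAM_SPORT = c(MON = 4)))
  b <- week_response(marks = list(WALK = c(THU = 1, SUN = 4),
                                  FREE_PLAY = c(SAT = 2)))
  u <- week_response(marks = list(WALK = c(MON = 2, TUE = 3, THU = 1, SUN = 4),
                                  TEAM_SPORT = c(MON = 4),
                                  FREE_PLAY = c(SAT = 2)))
  cols <- c("walking", "free_play", "team_sport", "total_pa", "mvpa")
  expect_equal(as.data.frame(score_pau7s(u)[cols]),
               as.data.frame(score_pau7s(a)[cols]) +
                 as.data.frame(score_pau7s(b)[cols]))

  low <- week_response(marks = list(FREE_PLAY = c(WED = 1)))
  for (code in 2:4) {
    high <- week_response(marks = list(FREE_PLAY = c(WED = code)))
    expect_true(all(score_pau7s(high)[cols] >= score_pau7s(low)[cols]))
    low <- high
  }
})

test_that("questionnaire CSV reading and scored-activity writing round-trip", {
  resp <- dplyr::bind_rows(
    week_response("A", 1, list(WALK = c(MON = 1), PE = c(MON = 1))),
    week_response("B", 1, list(TEAM_SPORT = c(SAT = 4)))
  )
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(resp, f)
  s <- score_pau7s(read_pau_responses(f))
  expect_equal(s$mvpa, c(30 / 7, 105 / 7))
  out <- withr::local_tempfile(fileext = ".csv")
  write_scored_activities(s, out)
  back <- readr::read_csv(out, show_col_types = FALSE)
  expect_equal(back[["MVPA (min/d)"]], s$mvpa)
  expect_true("Total physical activity (min/d)" %in% names(back))
})
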