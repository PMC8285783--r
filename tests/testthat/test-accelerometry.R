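# 720 five-second epochs = 60 minutes
zeros <- function(minutes) rep(0, minutes * 12)
active <- function(minutes, count = 1000) rep(count, minutes * 12)

test_that("non-wear needs a zero run of at least the configured duration", {
  s60 <- epoch_series(c(active(5), zeros(60), active(5)))
  w <- detect_nonwear(s60)
  expect_equal(sum(!w$wear), 720)
  expect_true(all(!w$wear[61:780]))

  s59 <- epoch_series(c(active(5), zeros(59), active(5)))
  expect_true(all(detect_nonwear(s59)$wear))

  expect_true(all(detect_nonwear(epoch_series(active(120)))$wear))
  expect_error(detect_nonwear(epoch_series(numeric(0))), "non-empty")
})

test_that("detected non-wear is monotone in the minimum-run parameter", {
  set.seed(42)
  vm <- unlist(lapply(1:20, function(i) {
    if (runif(1) < 0.5) zeros(sample(10:90, 1)) else active(sample(5:40, 1))
  }))
  s <- epoch_series(vm)
  runs <- c(90, 60, 30, 20)
  nonwear <- vapply(runs, function(r) {
    sum(!detect_nonwear(s, pau_config(min_zero_run = r))$wear)
  }, numeric(1))
  expect_true(all(diff(nonwear) >= 0))
})

test_that("a tolerated interruption joins zero runs into one non-wear block", {
  vm <- c(active(10), zeros(35), active(1), zeros(35), active(10))
  strict <- detect_nonwear(epoch_series(vm))
  expect_true(all(strict$wear))  # neither 35-min run reaches 60 alone
  tol <- detect_nonwear(epoch_series(vm),
                        pau_config(zero_run_tolerance = 2))
  expect_equal(sum(!tol$wear), (35 + 1 + 35) * 12)
})

test_that("wear minutes are counted inside the 08:00-22:00 window only", {
  full_day <- epoch_series(active(24 * 60, count = 100),
                           start = "2019-04-01 00:00:00")
  d <- summarize_wear_days(full_day)
  expect_equal(d$wear_minutes, 840)

  early <- epoch_series(active(60, count = 100), start = "2019-04-01 07:00:00")
  expect_equal(summarize_wear_days(early)$wear_minutes, 0)

  morning <- epoch_series(active(630, count = 100),
                          start = "2019-04-01 08:00:00")
  expect_equal(summarize_wear_days(morning)$wear_minutes, 630)
})

test_that("non-wear detection precedes windowing for runs straddling 22:00", {
  # 40 min of zeros before 22:00 + 40 min after: one 80-min non-wear run,
  # of which the 40 pre-22:00 minutes are removed from windowed wear time
  vm <- c(active(120, 500), zeros(80), active(60, 500))
  s <- epoch_series(vm, start = "2019-04-01 19:20:00")
  d <- summarize_wear_days(s)
  expect_equal(d$wear_minutes, 120)  # 19:20-21:20 only
})

test_that("intensity classification is closed on the lower cut-point", {
  cfg <- pau_config()
  cp <- cfg$cutpoints
  vm <- c(0, cp[["light"]] - 1, cp[["light"]], cp[["moderate"]] - 1,
          cp[["moderate"]], cp[["vigorous"]] - 1, cp[["vigorous"]], 9999)
  s <- classify_intensity(epoch_series(vm), cfg)
  expect_equal(as.character(s$intensity),
               c("sedentary", "sedentary", "light", "light", "moderate",
                 "moderate", "vigorous", "vigorous"))
  # masked epochs stay unlabelled whatever their count
  masked <- epoch_series(c(zeros(60), active(10, 2500)))
  cl <- classify_intensity(masked)
  expect_true(all(is.na(cl$intensity[!cl$wear])))
  expect_true(all(!is.na(cl$intensity[cl$wear])))
})

test_that("short worn zero runs count as sedentary time", {
  vm <- c(active(30, 500), zeros(10), active(30, 500))
  s <- classify_intensity(epoch_series(vm, start = "2019-04-01 10:00:00"))
  expect_true(all(s$wear))
  expect_equal(sum(s$intensity == "sedentary"), 120)
})

test_that("day validity uses the 600-minute rule with >=", {
  d599 <- epoch_series(active(599, 100), start = "2019-04-01 08:00:00")
  expect_false(summarize_wear_days(d599)$valid)
  d600 <- epoch_series(active(600, 100), start = "2019-04-01 08:00:00")
  expect_true(summarize_wear_days(d600)$valid)
})

test_that("participants need 4 valid days including a weekend day", {
  # Mon-Thu fully worn: 4 valid days but no weekend
  ep <- simulate_epoch_stream("P1", n_days = 4, start = as.Date("2019-04-01"),
                              seed = 1)
  p <- process_accelerometry(ep)$participants
  expect_equal(p$n_valid_days, 4)
  expect_equal(p$n_valid_weekend_days, 0)
  expect_false(p$valid)
  # Thu-Sun: 4 valid days, 2 weekend days
  ep2 <- simulate_epoch_stream("P1", n_days = 4,
                               start = as.Date("2019-04-04"), seed = 1)
  expect_true(process_accelerometry(ep2)$participants$valid)
})

test_that("participants with no valid days report missing means, not zero", {
  short <- epoch_series(active(120, 500), start = "2019-04-01 09:00:00",
                        participant_id = "P9")
  p <- process_accelerometry(short)$participants
  expect_false(p$valid)
  expect_true(is.na(p$mvpa))
  expect_true(is.na(p$moderate))
})

test_that("planted epoch streams round-trip exactly through the pipeline", {
  ep <- simulate_epoch_stream("P1", n_days = 7, seed = 3,
                              moderate_minutes = 45, vigorous_minutes = 15,
                              light_minutes = 60)
  res <- process_accelerometry(ep)
  truth <- attr(ep, "truth")
  expect_equal(res$participants$mvpa, 60)
  expect_equal(res$participants$moderate, 45)
  expect_equal(res$participants$vigorous, 15)
  expect_equal(res$days$moderate, truth$moderate)
  expect_equal(res$days$light, truth$light)
  expect_equal(res$days$sedentary, truth$sedentary)
  # planted 61-min daytime zero block becomes non-wear, exactly
  ep_nw <- simulate_epoch_stream("P1", n_days = 2, seed = 4,
                                 nonwear_block_minutes = 61)
  w <- detect_nonwear(ep_nw)
  day1 <- w[as.Date(format(w$timestamp, "%Y-%m-%d")) == as.Date("2019-04-01"), ]
  daytime <- day1[format(day1$timestamp, "%H:%M") >= "08:00" &
                    format(day1$timestamp, "%H:%M") < "21:30", ]
  expect_equal(sum(!daytime$wear), 61 * 12)
  # an empty schedule with full wear is a sedentary day: MVPA 0
  ep0 <- simulate_epoch_stream("P1", n_days = 7, seed = 5,
                               moderate_minutes = 0, vigorous_minutes = 0,
                               light_minutes = 0)
  expect_equal(process_accelerometry(ep0)$participants$mvpa, 0)
})

test_that("intensity minutes partition worn classified time", {
  ep <- simulate_epoch_stream("P1", n_days = 5, seed = 6,
                              nonwear_block_minutes = 75)
  d <- summarize_wear_days(ep)
  expect_equal(d$sedentary + d$light + d$moderate + d$vigorous,
               d$wear_minutes)
})

test_that("permuting whole days leaves the participant summary unchanged", {
  bouts <- tibble::tibble(day = rep(1:7, each = 2),
                          start_min = rep(c(600, 1020), 7),
                          duration_min = c(rbind(10 + 5 * (1:7), 3 * (1:7))),
                          type = rep(c("moderate", "vigorous"), 7))
  ep <- simulate_epoch_stream("P1", n_days = 7, seed = 7, bouts = bouts)
  base <- process_accelerometry(ep)$participants
  days <- split(ep, as.Date(format(ep$timestamp, "%Y-%m-%d")))
  shuffled <- dplyr::bind_rows(days[c(3, 1, 7, 5, 2, 6, 4)])
  # reassign timestamps so the series stays uniform, but day contents move
  shuffled$timestamp <- ep$timestamp
  base2 <- process_accelerometry(shuffled)$participants
  expect_equal(base$n_valid_days, base2$n_valid_days)
  expect_equal(base$mvpa, base2$mvpa)
  expect_equal(base$sedentary, base2$sedentary)
})

test_that("epoch aggregation sums counts and rebuilds vector magnitude", {
  df <- tibble::tibble(
    timestamp = as.POSIXct("2019-04-01 08:00:00", tz = "UTC") + seq(0, 55, 5),
    axis1 = rep(3, 12), axis2 = rep(4, 12), axis3 = rep(0, 12)
  )
  df$vm <- sqrt(df$axis1^2 + df$axis2^2)
  agg <- aggregate_epochs(df, 12)
  expect_equal(nrow(agg), 1)
  expect_equal(agg$axis1, 36)
  expect_equal(agg$vm, sqrt(36^2 + 48^2))
})

test_that("epoch CSV reader handles preamble, axes and vector magnitude", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "ActiLife export - device XYZ",
    "Epoch 00:00:05",
    "Timestamp,Axis1,Axis2,Axis3",
    "2019-04-01 08:00:00,3,4,0",
    "2019-04-01 08:00:05,0,0,0"
  ), f)
  ep <- read_epoch_counts(f, skip = 2)
  expect_equal(ep$vm, c(5, 0))
  expect_s3_class(ep$timestamp, "POSIXct")
  suppressWarnings(expect_error(read_epoch_counts(f, skip = 0),
                                "Timestamp|parse"))
})
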