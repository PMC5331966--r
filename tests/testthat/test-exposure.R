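cmap <- default_drug_class_map()

simple_fills <- function(dates, supplies, drug = "pravastatin",
                         setting = "outpatient") {
  data.frame(patient_id = "A", drug_code = drug, fill_date = dates,
             days_supply = supplies, setting = setting,
             stringsAsFactors = FALSE)
}

test_that("a single fill exposes exactly its days of supply", {
  cal <- build_exposure_calendar(simple_fills(0L, 30L), NULL, cmap)
  expect_equal(cal$start, 0L)
  expect_equal(cal$end, 30L)
  expect_equal(proportion_days_covered(cal, "A", "statin", 29L, 30L), 1.0)
})

test_that("early refills carry surplus supply forward without cap", {
  cal <- build_exposure_calendar(simple_fills(c(0L, 20L), c(30L, 30L)),
                                 NULL, cmap)
  expect_equal(cal$start, 0L)
  expect_equal(cal$end, 60L)
  # three stacked early refills
  cal3 <- build_exposure_calendar(simple_fills(c(0L, 5L, 10L), c(30L, 30L, 30L)),
                                  NULL, cmap)
  expect_equal(cal3$end - cal3$start, 90L)
})

test_that("hospitalization pauses outpatient consumption; inpatient orders cover the stay", {
  fills <- rbind(simple_fills(0L, 30L),
                 simple_fills(10L, 10L, setting = "inpatient_order"))
  stays <- data.frame(patient_id = "A", admit_date = 10L, discharge_date = 19L)
  cal <- build_exposure_calendar(fills, stays, cmap)
  expect_equal(cal$start, 0L)
  expect_equal(cal$end, 40L)
  # without the inpatient order the stay days are unexposed
  cal2 <- build_exposure_calendar(simple_fills(0L, 30L), stays, cmap)
  expect_equal(sort(calendar_days(cal2, "A", "statin")),
               c(0:9, 20:39))
})

test_that("a same-class therapy switch discards the prior drug's stock", {
  fills <- rbind(simple_fills(0L, 30L, drug = "pravastatin"),
                 simple_fills(10L, 30L, drug = "simvastatin"))
  cal <- build_exposure_calendar(fills, NULL, cmap)
  # pravastatin contributes [0,10), simvastatin [10,40): continuous class
  # exposure but the 20 surplus pravastatin days are gone
  expect_equal(cal$start, 0L)
  expect_equal(cal$end, 40L)
})

test_that("records with days_supply < 1 are rejected with a warning", {
  fills <- rbind(simple_fills(0L, 30L), simple_fills(5L, -1L))
  expect_warning(cal <- build_exposure_calendar(fills, NULL, cmap),
                 "days_supply")
  expect_equal(cal$end, 30L)
})

test_that("overlapping hospital stays are an explicit failure", {
  stays <- data.frame(patient_id = "A",
                      admit_date = c(10L, 15L), discharge_date = c(20L, 25L))
  expect_error(build_exposure_calendar(simple_fills(0L, 30L), stays, cmap),
               "overlapping")
})

test_that("current use window includes the query day and exactly 7 days back", {
  cal <- build_exposure_calendar(simple_fills(0L, 30L), NULL, cmap)
  # last exposed day is 29
  expect_true(current_use(cal, "A", "statin", 29L))
  expect_true(current_use(cal, "A", "statin", 36L))   # 29 = 36 - 7
  expect_false(current_use(cal, "A", "statin", 37L))  # 29 = 37 - 8
  expect_false(current_use(cal, "A", "statin", -5L))  # before any exposure
  # empty calendar is never current
  expect_false(current_use(cal, "B", "statin", 10L))
})

test_that("PDC counts exposed days in the look-back window", {
  cal <- build_exposure_calendar(simple_fills(0L, 15L), NULL, cmap)
  expect_equal(proportion_days_covered(cal, "A", "statin", 29L, 30L), 0.5)
  expect_equal(proportion_days_covered(cal, "A", "statin", 14L, 15L), 1.0)
  expect_equal(proportion_days_covered(cal, "B", "statin", 14L, 15L), 0.0)
})

test_that("ever use flips on at the first exposed day and never reverts", {
  cal <- build_exposure_calendar(simple_fills(100L, 30L), NULL, cmap)
  expect_equal(ever_use(cal, "A", "statin", c(99L, 100L, 10000L)),
               c(FALSE, TRUE, TRUE))
  expect_false(any(ever_use(cal, "B", "statin", c(0L, 500L))))
})

test_that("current use implies ever use at any date", {
  set.seed(41)
  for (i in 1:20) {
    h <- random_history(sample(1:8, 1), 0)
    cal <- build_exposure_calendar(h$fills, NULL, demo_class_map())
    d <- sample(0:500, 25, TRUE)
    cu <- current_use(cal, "P1", "statin", d)
    ev <- ever_use(cal, "P1", "statin", d)
    expect_true(all(!cu | ev))
  }
})

test_that("engine matches the naive day-loop stock oracle on random histories", {
  set.seed(99)
  for (i in 1:60) {
    h <- random_history(sample(1:12, 1), sample(0:2, 1))
    stays_df <- if (is.null(h$stays)) NULL else
      data.frame(patient_id = "P1", admit_date = h$stays$admit,
                 discharge_date = h$stays$disch_excl - 1L)
    cal <- build_exposure_calendar(h$fills, stays_df, demo_class_map())
    expect_equal(calendar_days(cal, "P1", "statin"),
                 oracle_exposed_days(h$fills, h$stays),
                 info = sprintf("case %d", i))
  }
})

test_that("outpatient exposure never exceeds total supply; equality without stays", {
  set.seed(7)
  for (i in 1:40) {
    h <- random_history(sample(1:10, 1), 0, drugs = "d1")
    cal <- build_exposure_calendar(h$fills, NULL, demo_class_map())
    total <- sum(cal$end - cal$start)
    expect_equal(total, sum(h$fills$days_supply))
  }
  # with a same-class switch, exposure is strictly below supply when the
  # discarded drug still had stock
  fills <- rbind(simple_fills(0L, 30L, "pravastatin"),
                 simple_fills(10L, 5L, "simvastatin"))
  cal <- build_exposure_calendar(fills, NULL, cmap)
  expect_lt(sum(cal$end - cal$start), 35L)
})

test_that("PDC is invariant to splitting one fill into two abutting fills", {
  f1 <- simple_fills(0L, 40L)
  f2 <- simple_fills(c(0L, 25L), c(25L, 15L))
  c1 <- build_exposure_calendar(f1, NULL, cmap)
  c2 <- build_exposure_calendar(f2, NULL, cmap)
  for (d in c(10L, 39L, 50L, 80L)) {
    expect_equal(proportion_days_covered(c1, "A", "statin", d, 30L),
                 proportion_days_covered(c2, "A", "statin", d, 30L))
    # PDC * window is an integer day count
    expect_equal((proportion_days_covered(c1, "A", "statin", d, 30L) * 30) %% 1, 0)
  }
})

test_that("current use equals positive coverage over its 8-day window", {
  set.seed(13)
  for (i in 1:20) {
    h <- random_history(sample(1:6, 1), 0)
    cal <- build_exposure_calendar(h$fills, NULL, demo_class_map())
    d <- sample(0:500, 30, TRUE)
    expect_equal(current_use(cal, "P1", "statin", d),
                 proportion_days_covered(cal, "P1", "statin", d, 8L) > 0)
  }
})

test_that("exposure calendars round-trip through the run-length CSV format", {
  h <- random_history(6, 1)
  stays_df <- if (is.null(h$stays)) NULL else
    data.frame(patient_id = "P1", admit_date = h$stays$admit,
               discharge_date = h$stays$disch_excl - 1L)
  cal <- build_exposure_calendar(h$fills, stays_df, demo_class_map())
  tf <- tempfile(fileext = ".csv")
  write_exposure_csv(cal, tf)
  cal2 <- read_exposure_csv(tf)
  expect_equal(as.data.frame(cal[, c("patient_id", "class", "start", "end")]),
               as.data.frame(cal2[, c("patient_id", "class", "start", "end")]))
  unlink(tf)
})
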