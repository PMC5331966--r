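day0 <- function(x) as.integer(as.Date(x))

make_small_cohort <- function(statin_fill_offset = 30L,
                              statin_supply = 170L,
                              extra_lab = NULL) {
  base <- day0("2004-01-10")
  vls <- data.frame(
    patient_id = "X",
    date = base + c(-30L, 0L, 90L, 180L),
    value = c(50000, NA, NA, 1500),
    lloq = 50, detectable = c(TRUE, FALSE, FALSE, TRUE))
  pts <- data.frame(patient_id = "X", haart_start = base - 30L,
                    age_at_haart_start = 50, race = "White", gender = "M",
                    hcv = FALSE, hiv_dx_date = base - 400L,
                    pre_haart_arv_days = 0)
  fills <- data.frame(patient_id = "X", drug_code = "pravastatin",
                      fill_date = base + statin_fill_offset,
                      days_supply = statin_supply, setting = "outpatient")
  labs <- data.frame(patient_id = "X",
                     date = base + c(-10L, 85L),
                     analyte = c("CD4", "CD4"), value = c(250, 420))
  if (!is.null(extra_lab)) labs <- rbind(labs, extra_lab)
  cal <- build_exposure_calendar(fills, NULL, default_drug_class_map())
  coh <- build_cohort(vls, pts)
  rows <- assemble_counting_process(coh, cal, vls, pts, labs = labs)
  list(base = base, rows = rows, cal = cal, coh = coh)
}

test_that("LDL equivalent is max(LDL, nonHDL - 30) off lipid-lowering therapy", {
  expect_equal(ldl_equivalent(100, 160), 130)
  expect_equal(ldl_equivalent(120, 140), 120)
  expect_equal(ldl_equivalent(NA, 160), 130)
  expect_equal(ldl_equivalent(100, NA), 100)
  expect_true(is.na(ldl_equivalent(NA, NA)))
  # a measurement 3 days after the last statin exposure is disqualified
  fills <- data.frame(patient_id = "A", drug_code = "pravastatin",
                      fill_date = 0L, days_supply = 10L, setting = "outpatient")
  cal <- build_exposure_calendar(fills, NULL, default_drug_class_map())
  expect_true(is.na(ldl_equivalent(100, 160, cal, "A", 12L)))  # last use day 9
  expect_equal(ldl_equivalent(100, 160, cal, "A", 18L), 130)   # > 7 days off
})

test_that("substance-abuse flag needs two dated events and is monotone", {
  expect_false(substance_abuse_flag(integer(0), 100L))
  expect_false(substance_abuse_flag(50L, 100L))
  expect_true(substance_abuse_flag(c(10L, 50L), 100L))
  expect_equal(substance_abuse_flag(c(10L, 150L), c(100L, 200L)),
               c(FALSE, TRUE))
})

test_that("counting-process rows partition follow-up with the event on the last row", {
  s <- make_small_cohort()
  rows <- s$rows
  expect_equal(rows$t_start, c(0L, 90L))
  expect_equal(rows$t_stop, c(90L, 180L))
  expect_equal(rows$event, c(FALSE, TRUE))
  # conservation: total row time equals follow-up from the endpoint table
  inc <- s$coh[s$coh$included == TRUE]
  expect_equal(sum(rows$t_stop - rows$t_start),
               as.integer(inc$exit_date - inc$baseline_date))
  # statin exposure [30, 200): not current at day 0, current at day 90
  expect_equal(rows$statin_current, c(FALSE, TRUE))
  expect_equal(rows$statin_ever, c(FALSE, TRUE))
  # CD4 carried forward from the most recent measurement at row start
  expect_equal(rows$cd4, c(250, 420))
})

test_that("row covariates never use information after the row start", {
  s1 <- make_small_cohort()
  # a lab measured after the first row's start must not change that row
  s2 <- make_small_cohort(extra_lab = data.frame(
    patient_id = "X", date = s1$base + 40L, analyte = "CD4", value = 999))
  expect_equal(s1$rows[1, ]$cd4, s2$rows[1, ]$cd4)
  expect_equal(s2$rows[2, ]$cd4, 420)  # day-85 value still the latest at day 90
  # moving the statin fill after a row start flips only later rows
  s3 <- make_small_cohort(statin_fill_offset = 100L, statin_supply = 100L)
  expect_equal(s3$rows$statin_current, c(FALSE, FALSE))
  expect_equal(s3$rows$statin_ever, c(FALSE, FALSE))
})

test_that("deleting a lab value only changes rows at or after its date (LOCF)", {
  s1 <- make_small_cohort()
  s2 <- make_small_cohort(extra_lab = NULL)
  # drop the day-85 CD4: second row falls back to the day -10 value
  base <- s1$base
  vls <- data.frame(patient_id = "X", date = base + c(-30L, 0L, 90L, 180L),
                    value = c(50000, NA, NA, 1500), lloq = 50,
                    detectable = c(TRUE, FALSE, FALSE, TRUE))
  pts <- data.frame(patient_id = "X", haart_start = base - 30L,
                    age_at_haart_start = 50, race = "White", gender = "M",
                    hcv = FALSE, hiv_dx_date = base - 400L,
                    pre_haart_arv_days = 0)
  labs <- data.frame(patient_id = "X", date = base - 10L,
                     analyte = "CD4", value = 250)
  cal <- s1$cal
  coh <- build_cohort(vls, pts)
  rows <- assemble_counting_process(coh, cal, vls, pts, labs = labs)
  expect_equal(rows$cd4, c(250, 250))
  expect_equal(s1$rows$cd4, c(250, 420))
})

test_that("ever-use columns are non-decreasing within patient", {
  cfg <- sim_config(n_patients = 250L, seed = 14L)
  sim <- simulate_cohort(cfg, keep_truth = FALSE)
  cal <- build_exposure_calendar(sim$fills, sim$stays, sim$drug_classes)
  coh <- build_cohort(sim$viral_loads, sim$demographics)
  rows <- assemble_counting_process(coh, cal, sim$viral_loads,
                                    sim$demographics, labs = sim$labs,
                                    icd_events = sim$icd_events,
                                    substance_codes = c("303.90", "304.20", "305.00"))
  dec <- rows[, .(ok = all(diff(as.integer(statin_ever)) >= 0) &&
                    all(diff(as.integer(substance_abuse)) >= 0)),
              by = patient_id]
  expect_true(all(dec$ok))
  expect_true(all(rows$t_start < rows$t_stop))
  # event only on terminal rows
  last <- rows[, .SD[.N], by = patient_id]
  expect_equal(sum(rows$event), sum(last$event))
})

test_that("user-supplied extra covariates are merged onto every row", {
  s <- make_small_cohort()
  base <- s$base
  vls <- data.frame(patient_id = "X", date = base + c(-30L, 0L, 90L, 180L),
                    value = c(50000, NA, NA, 1500), lloq = 50,
                    detectable = c(TRUE, FALSE, FALSE, TRUE))
  pts <- data.frame(patient_id = "X", haart_start = base - 30L,
                    age_at_haart_start = 50, race = "White", gender = "M",
                    hcv = FALSE, hiv_dx_date = base - 400L,
                    pre_haart_arv_days = 0)
  coh <- build_cohort(vls, pts)
  rows <- assemble_counting_process(
    coh, s$cal, vls, pts,
    extra_covariates = data.frame(patient_id = "X", bmi = 27.4,
                                  smoker = TRUE))
  expect_equal(rows$bmi, c(27.4, 27.4))
  expect_equal(rows$smoker, c(TRUE, TRUE))
})

test_that("on-therapy lipid measurements are excluded from the LDL-equivalent series", {
  base <- day0("2004-01-10")
  vls <- data.frame(patient_id = "X", date = base + c(-30L, 0L, 90L, 180L),
                    value = c(50000, NA, NA, 1500), lloq = 50,
                    detectable = c(TRUE, FALSE, FALSE, TRUE))
  pts <- data.frame(patient_id = "X", haart_start = base - 30L,
                    age_at_haart_start = 50, race = "White", gender = "M",
                    hcv = FALSE, hiv_dx_date = base - 400L,
                    pre_haart_arv_days = 0)
  fills <- data.frame(patient_id = "X", drug_code = "pravastatin",
                      fill_date = base + 10L, days_supply = 60L,
                      setting = "outpatient")
  cal <- build_exposure_calendar(fills, NULL, default_drug_class_map())
  # off-therapy measurement before the fill; on-therapy measurement at day 40
  labs <- data.frame(patient_id = "X", date = base + c(-5L, 40L, 40L, -5L),
                     analyte = c("LDL", "LDL", "nonHDL", "nonHDL"),
                     value = c(110, 60, 100, 150))
  coh <- build_cohort(vls, pts)
  rows <- assemble_counting_process(coh, cal, vls, pts, labs = labs)
  # both rows carry the off-therapy value max(110, 150-30) = 120; the
  # on-therapy day-40 pair is never used
  expect_equal(rows$ldl_equiv, c(120, 120))
})
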