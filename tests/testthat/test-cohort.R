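day0 <- function(x) as.integer(as.Date(x))

vl_tab <- function(patient_id, dates, values, lloq = 50) {
  data.frame(patient_id = patient_id, date = dates,
             value = ifelse(values == 0, NA_real_, values),
             lloq = lloq, detectable = values != 0,
             stringsAsFactors = FALSE)
}

test_that("era assignment uses the documented boundaries", {
  expect_equal(assign_era("1999-06-30"), 1L)
  expect_equal(assign_era("2005-12-31"), 2L)
  expect_equal(assign_era("2006-01-01"), 3L)
  expect_equal(assign_era("2011-12-31"), 3L)
  expect_error(assign_era("1994-12-31"), "window")
  expect_error(assign_era("2012-01-01"), "window")
})

test_that("inclusion requires a high VL, later suppression, and a timely follow-up VL", {
  base <- day0("2003-01-01")
  pts <- data.frame(patient_id = c("A", "B", "C", "D"),
                    haart_start = base - 10L)
  vls <- rbind(
    vl_tab("A", base + c(0L, 60L, 150L), c(50000, 0, 75)),
    vl_tab("B", base + c(0L, 60L), c(50000, 0)),
    vl_tab("C", base + c(0L, 60L, 150L), c(800, 0, 0)),
    vl_tab("D", base + c(0L, 60L, 600L), c(50000, 0, 0)))
  sel <- select_cohort(vls, pts)
  expect_equal(sel[sel$patient_id == "A"]$included, TRUE)
  expect_equal(sel[sel$patient_id == "A"]$baseline_date, base + 60L)
  expect_equal(sel[sel$patient_id == "B"]$exclusion_reason, "no_followup_vl")
  expect_equal(sel[sel$patient_id == "C"]$exclusion_reason, "no_high_vl")
  expect_equal(sel[sel$patient_id == "D"]$exclusion_reason, "no_followup_vl")
  # no HAART start at all
  pts2 <- data.frame(patient_id = "A", haart_start = NA)
  expect_equal(select_cohort(vl_tab("A", base, 50000), pts2)$exclusion_reason,
               "no_haart")
})

test_that("inclusion counts are conserved across reasons", {
  set.seed(3)
  cfg <- sim_config(n_patients = 300L, seed = 3L)
  sim <- simulate_cohort(cfg, keep_truth = FALSE)
  sel <- select_cohort(sim$viral_loads, sim$demographics)
  expect_equal(sum(sel$included) + sum(!sel$included), nrow(sim$demographics))
  expect_true(all(!sel$included == !is.na(sel$exclusion_reason)))
})

test_that("failure is the first VL > 1000 or first of two consecutive > 200", {
  expect_equal(detect_failure(c(10L, 50L), c(0, 1500)),
               list(event = TRUE, event_date = 50L))
  expect_equal(detect_failure(c(10L, 50L, 90L), c(0, 300, 250)),
               list(event = TRUE, event_date = 50L))
  # unconfirmed blips never qualify
  expect_false(detect_failure(c(10L, 50L, 90L, 130L), c(0, 300, 150, 400))$event)
  expect_false(detect_failure(integer(0), numeric(0))$event)
  # the > 1000 rule wins even if unconfirmed
  expect_equal(detect_failure(c(10L, 50L, 90L), c(0, 150, 1200))$event_date, 90L)
})

test_that("censoring rules: gap, administrative end, and the combined endpoint", {
  # regular monitoring through 2011, never failing
  d <- day0("2008-01-01") + seq(0L, 1400L, by = 90L)
  r <- apply_censoring(d, rep(0, length(d)))
  expect_equal(r$exit_reason, "admin_censor")
  expect_equal(r$exit_date, max(d))
  expect_false(r$premature_censor)

  # gap > 13 months censors at the last VL before the gap
  d2 <- day0("2004-01-01") + c(0L, 180L, 600L)
  r2 <- apply_censoring(d2, c(0, 0, 0))
  expect_equal(r2$exit_reason, "gap_censor")
  expect_equal(r2$exit_date, d2[2])
  expect_true(r2$premature_censor)

  # death within 13 months of the last VL: combined endpoint event,
  # primary endpoint censors at the last VL
  d3 <- day0("2008-01-01")
  rp <- apply_censoring(d3, 0, death_date = d3 + 180L)
  expect_equal(rp$exit_reason, "admin_censor")
  expect_false(rp$event)
  rc <- apply_censoring(d3, 0, death_date = d3 + 180L, endpoint = "combined")
  expect_true(rc$event)
  expect_equal(rc$exit_date, d3 + 180L)
  expect_equal(rc$exit_reason, "death")

  # death before baseline is inconsistent data
  expect_error(apply_censoring(d3, 0, death_date = d3 - 10L), "death before")
})

test_that("failure beats a gap censor on the same date", {
  # confirmation arrives after a > 13-month gap: failure at the first of the
  # pair, which is also the gap-censor date
  d <- day0("2003-01-01") + c(0L, 100L, 600L)
  r <- apply_censoring(d, c(0, 300, 400))
  expect_equal(r$exit_reason, "failure")
  expect_equal(r$exit_date, d[2])
})

test_that("endpoint state machine matches the brute-force scan on random series", {
  set.seed(21)
  for (i in 1:150) {
    s <- random_vl_series()
    death <- if (runif(1) < 0.2) max(s$dates) + sample(-200:600, 1) else NA
    if (!is.na(death) && death < s$dates[1]) death <- s$dates[1]
    ep <- sample(c("primary", "combined"), 1)
    got <- apply_censoring(s$dates, s$values, death_date = death,
                           endpoint = ep)
    want <- oracle_endpoint(s$dates, s$values, death = death,
                            study_end = "2012-01-01", endpoint = ep)
    expect_equal(got[c("exit_date", "exit_reason", "event", "event_date",
                       "premature_censor")],
                 want[c("exit_date", "exit_reason", "event", "event_date",
                        "premature_censor")],
                 info = sprintf("case %d", i))
  }
})

test_that("sensitivity cohort re-anchors at the first undetectable VL 6+ months out", {
  base <- day0("2004-03-01")
  pts <- data.frame(patient_id = c("A", "B", "C"), haart_start = base - 30L)
  vls <- rbind(
    vl_tab("A", base + c(-20L, 0L, 213L, 365L), c(20000, 0, 0, 2000)),
    vl_tab("B", base + c(-20L, 0L, 120L), c(20000, 0, 5000)),
    vl_tab("C", base + c(-20L, 0L, 150L), c(20000, 0, 0)))
  coh <- build_cohort(vls, pts)
  expect_true(coh[coh$patient_id == "A"]$sensitivity_eligible)
  expect_equal(coh[coh$patient_id == "A"]$sensitivity_baseline, base + 213L)
  expect_false(coh[coh$patient_id == "B"]$sensitivity_eligible)  # failed first
  expect_false(coh[coh$patient_id == "C"]$sensitivity_eligible)  # nothing >= 6 months
  sc <- sensitivity_cohort(coh)
  expect_equal(sc$patient_id, "A")
  expect_equal(sc$baseline_date, base + 213L)
})

test_that("follow-up is positive and event dates are VL dates", {
  cfg <- sim_config(n_patients = 400L, seed = 8L)
  sim <- simulate_cohort(cfg, keep_truth = FALSE)
  coh <- build_cohort(sim$viral_loads, sim$demographics)
  inc <- coh[coh$included == TRUE]
  expect_true(all(inc$exit_date > inc$baseline_date))
  vl_days <- as.integer(as.Date(sim$viral_loads$date))
  ev <- inc[inc$event == TRUE]
  key <- paste(ev$patient_id, ev$event_date)
  have <- paste(sim$viral_loads$patient_id, vl_days)
  expect_true(all(key %in% have))
})
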