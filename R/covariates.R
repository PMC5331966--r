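#' Native LDL-equivalent cholesterol
#'
#' Unified lipid parameter: the maximum of LDL and (non-HDL cholesterol minus
#' 30 mg/dL), valid only for measurements taken while off lipid-lowering
#' therapy (no statin or non-statin lipid-lowering exposure within the
#' previous 7 days).
#'
#' @param ldl LDL cholesterol in mg/dL or `NA`.
#' @param nonhdl non-HDL cholesterol in mg/dL or `NA`.
#' @param lipid_calendar optional [exposure_calendar]; when supplied together
#'   with `patient` and `date`, measurements taken on lipid-lowering therapy
#'   (classes `statin` or `ALP`) are disqualified (`NA`).
#' @param patient,date measurement identity used with `lipid_calendar`.
#' @return mg/dL, or `NA` if neither input qualifies.
#' @export
ldl_equivalent <- function(ldl = NA_real_, nonhdl = NA_real_,
                           lipid_calendar = NULL, patient = NULL,
                           date = NULL) {
  if (!is.null(lipid_calendar)) {
    on_tx <- current_use(lipid_calendar, patient, "statin", date) |
      current_use(lipid_calendar, patient, "ALP", date)
    if (isTRUE(on_tx)) return(NA_real_)
  }
  vals <- c(ldl, nonhdl - 30)
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Time-indexed substance-abuse flag
#'
#' True once at least `min_events` qualifying diagnosis-code events have
#' occurred on or before the query date; monotone non-decreasing in date.
#'
#' @param event_dates integer days of qualifying ICD code events for one
#'   patient (already filtered to the indicative code list).
#' @param date query date(s).
#' @param min_events threshold, default 2.
#' @return logical vector along `date`.
#' @export
substance_abuse_flag <- function(event_dates, date, min_events = 2L) {
  d <- as_day(date)
  ev <- sort(as_day(event_dates))
  vapply(d, function(x) sum(ev <= x) >= min_events, logical(1))
}

# Last-observation-carried-forward lookup: for each (patient_id, date) query,
# the most recent series value at or before the date.
locf_at <- function(series, queries, value_col = "value") {
  s <- data.table::data.table(patient_id = series$patient_id,
                              date = as_day(series$date),
                              v = series[[value_col]])
  s <- s[!is.na(v)]
  data.table::setkey(s, patient_id, date)
  q <- data.table::data.table(patient_id = queries$patient_id,
                              date = as_day(queries$date))
  s[q, on = .(patient_id, date), roll = TRUE]$v
}

#' Assemble the counting-process analysis dataset
#'
#' Produces one row per inter-VL interval from baseline to exit, in start-stop
#' counting-process layout with time on study (days since baseline). All
#' time-updated covariates - the three exposure modes per medication class,
#' ART adherence (91-day PDC over all antiretroviral exposure), regimen
#' categories, CD4 and LDL-equivalent (last observation carried forward) and
#' the substance-abuse flag - are evaluated at the interval's *start* VL date
#' and carried forward, so no row uses information after its start
#' (predictable covariates, no look-ahead). The event indicator is true only
#' on the last row of a failing patient.
#'
#' @param cohort output of [build_cohort()] (included patients are used).
#' @param calendar an [exposure_calendar] covering medication and ARV classes.
#' @param vls viral-load table (`patient_id`, `date`, ...).
#' @param demographics per-patient table: `patient_id`, `age_at_haart_start`,
#'   `haart_start`, `race`, `gender`, and optionally `hcv`, `hiv_dx_date`,
#'   `pre_haart_arv_days`.
#' @param labs optional long lab table (`patient_id`, `date`, `analyte`,
#'   `value`) with analytes `CD4`, `LDL`, `nonHDL`.
#' @param icd_events optional diagnosis events (`patient_id`, `date`, `code`).
#' @param substance_codes codes counted toward the substance-abuse flag.
#' @param extra_covariates optional per-patient table (`patient_id` plus any
#'   baseline columns, e.g. BMI, smoking, diabetes or cardiovascular
#'   history) merged onto every row; code lists for such phenotypes are
#'   user-supplied, not built in.
#' @param med_classes medication classes given current/PDC/ever columns
#'   (look-back `pdc_window_med` days).
#' @param pdc_window_med,pdc_window_arv PDC look-back windows (days) for
#'   medication classes and ART adherence.
#' @return data.table of counting-process rows: `patient_id`, `t_start`,
#'   `t_stop`, `event`, `era`, covariate columns, `weight` (1).
#' @export
assemble_counting_process <- function(cohort, calendar, vls, demographics,
                                      labs = NULL, icd_events = NULL,
                                      substance_codes = NULL,
                                      extra_covariates = NULL,
                                      med_classes = c("statin", "ALP", "AHT", "ASA"),
                                      pdc_window_med = 30L,
                                      pdc_window_arv = 91L) {
  entries <- data.table::as.data.table(cohort)[included == TRUE]
  if (nrow(entries) == 0L) stop("no included patients")
  vls <- data.table::as.data.table(vls)
  vls[, date := as_day(date)]

  # Interval grid: VL dates within [baseline, exit], exit appended (it is a
  # VL date except for a combined-endpoint death).
  vz <- merge(vls[, .(patient_id, date)],
              entries[, .(patient_id, baseline_date, exit_date)],
              by = "patient_id")
  vz <- unique(vz[date >= baseline_date & date <= exit_date,
                  .(patient_id, baseline_date, exit_date, date)])
  ex <- entries[, .(patient_id, baseline_date, exit_date, date = exit_date)]
  vz <- unique(rbind(vz, ex))
  data.table::setorder(vz, patient_id, date)
  rows <- vz[, {
    n <- .N
    if (n < 2L) NULL
    else list(start_abs = date[-n], stop_abs = date[-1L])
  }, by = .(patient_id, baseline_date)]
  rows <- merge(rows, entries[, .(patient_id, era, event, exit_date,
                                  premature_censor, exit_reason)],
                by = "patient_id")
  rows[, t_start := start_abs - baseline_date]
  rows[, t_stop := stop_abs - baseline_date]
  rows[, event := event & stop_abs == exit_date]
  # Premature-censoring indicator for the censoring-propensity model: true on
  # the terminal row of a prematurely censored patient.
  rows[, censor_next := premature_censor & stop_abs == exit_date]

  q <- rows[, .(patient_id, date = start_abs)]

  for (cls in med_classes) {
    modes <- exposure_modes_at(class_intervals(calendar, cls), q,
                               pdc_window = pdc_window_med)
    nm <- tolower(cls)
    rows[, paste0(nm, c("_current", "_pdc", "_ever")) :=
           .(modes$current, modes$pdc, modes$ever)]
  }

  arv_labels <- grep("^(NRTI|anchor)", unique(calendar$class), value = TRUE)
  arv_iv <- calendar[class %in% arv_labels, .(patient_id, start, end)]
  art_union <- arv_iv[, {
    u <- union_intervals(start, end)
    list(start = u$start, end = u$end)
  }, by = patient_id]
  rows[, art_pdc := exposure_modes_at(art_union, q,
                                      pdc_window = pdc_window_arv)$pdc]

  anchor_cur <- list(
    modern = exposure_modes_at(class_intervals(calendar, "anchor:modern"),
                               q, pdc_window_arv)$current,
    boosted = exposure_modes_at(
      class_intervals(calendar, "anchor:boosted_pi_other"), q,
      pdc_window_arv)$current,
    other = exposure_modes_at(
      class_intervals(calendar, "anchor:unboosted_or_nvp_other"), q,
      pdc_window_arv)$current)
  rows[, anchor_category := data.table::fcase(
    anchor_cur$modern, "modern",
    anchor_cur$boosted, "boosted_pi_other",
    anchor_cur$other, "unboosted_nvp_other",
    default = "none")]
  rows[, nrti_tenofovir := exposure_modes_at(
    class_intervals(calendar, "NRTI:tenofovir"), q, pdc_window_arv)$current]
  rows[, nrti_3tc_ftc := exposure_modes_at(
    class_intervals(calendar, "NRTI:lamivudine_emtricitabine"), q,
    pdc_window_arv)$current]
  rows[, nrti_other := exposure_modes_at(
    class_intervals(calendar, "NRTI:other"), q, pdc_window_arv)$current]

  # ARV class experience: number of ARV exposure categories ever used.
  if (nrow(arv_iv)) {
    firsts <- calendar[class %in% arv_labels,
                       .(first = min(start)), by = .(patient_id, class)]
    q2 <- data.table::copy(q)[, idx := .I]
    fe <- firsts[q2, on = "patient_id", allow.cartesian = TRUE]
    cexp <- fe[, .(n = sum(!is.na(first) & first <= date)), by = idx]
    data.table::setorder(cexp, idx)
    rows[, arv_class_experience := cexp$n]
  } else rows[, arv_class_experience := 0L]

  # Demographics and baseline summaries.
  dem <- data.table::as.data.table(demographics)
  dem[, haart_start := as_day(haart_start)]
  base <- entries[, .(patient_id, baseline_date)]
  base <- merge(base, dem, by = "patient_id", all.x = TRUE)
  base[, age_baseline := age_at_haart_start +
         (baseline_date - haart_start) / 365.25]
  if ("hiv_dx_date" %in% names(dem))
    base[, months_dx_to_supp :=
           (baseline_date - as_day(hiv_dx_date)) / DAYS_PER_MONTH]
  # Peak (log10) VL before baseline.
  pk <- merge(vls[!is.na(value) & value > 0],
              entries[, .(patient_id, baseline_date)], by = "patient_id")
  pk <- pk[date <= baseline_date, .(peak_log_vl = log10(max(value))),
           by = patient_id]
  base <- merge(base, pk, by = "patient_id", all.x = TRUE)

  keep <- intersect(c("patient_id", "age_baseline", "race", "gender", "hcv",
                      "months_dx_to_supp", "pre_haart_arv_days",
                      "peak_log_vl", "haart_start"), names(base))
  rows <- merge(rows, base[, ..keep], by = "patient_id")
  rows[, age_current := age_baseline + t_start / 365.25]
  if ("race" %in% names(rows))
    rows[is.na(race) | race == "", race := "Unknown"]

  # Labs: LOCF at row start, cohort-median imputation with missingness flags.
  if (!is.null(labs)) {
    labs <- data.table::as.data.table(labs)
    labs[, date := as_day(date)]
    cd4 <- labs[analyte == "CD4", .(patient_id, date, value)]
    rows[, cd4 := locf_at(cd4, q)]
    lip <- data.table::dcast(labs[analyte %in% c("LDL", "nonHDL")],
                             patient_id + date ~ analyte,
                             value.var = "value", fun.aggregate = mean)
    if (nrow(lip)) {
      if (!"LDL" %in% names(lip)) lip[, LDL := NA_real_]
      if (!"nonHDL" %in% names(lip)) lip[, nonHDL := NA_real_]
      # Disqualify measurements taken on lipid-lowering therapy (<= 7 days
      # since last statin/ALP exposure).
      lql <- rbind(class_intervals(calendar, "statin"),
                   class_intervals(calendar, "ALP"))
      on_tx <- exposure_modes_at(lql, lip[, .(patient_id, date)],
                                 pdc_window = 7L)$current
      lip <- lip[!on_tx]
      lip[, value := pmax(LDL, nonHDL - 30, na.rm = TRUE)]
      lip[is.infinite(value), value := NA_real_]
      rows[, ldl_equiv := locf_at(lip[, .(patient_id, date, value)], q)]
    } else rows[, ldl_equiv := NA_real_]
    for (v in c("cd4", "ldl_equiv")) {
      miss <- is.na(rows[[v]])
      rows[, paste0(v, "_missing") := miss]
      med <- median(rows[[v]], na.rm = TRUE)
      if (is.na(med)) med <- 0
      rows[miss, (v) := med]
    }
  }

  # Substance abuse: >= 2 indicative diagnosis codes on or before row start.
  if (!is.null(icd_events)) {
    icd <- data.table::as.data.table(icd_events)
    icd[, date := as_day(date)]
    if (!is.null(substance_codes)) icd <- icd[code %in% substance_codes]
    icd <- icd[, .(patient_id, date, one = 1L)]
    data.table::setkey(icd, patient_id, date)
    icd[, cum := cumsum(one), by = patient_id]
    rows[, substance_abuse := {
      cc <- locf_at(icd[, .(patient_id, date, value = cum)], q)
      !is.na(cc) & cc >= 2L
    }]
  } else rows[, substance_abuse := FALSE]

  if (!is.null(extra_covariates)) {
    rows <- merge(rows, data.table::as.data.table(extra_covariates),
                  by = "patient_id", all.x = TRUE)
  }

  rows[, weight := 1]
  drop_cols <- intersect(c("start_abs", "stop_abs", "baseline_date",
                           "exit_date", "haart_start", "exit_reason"),
                         names(rows))
  rows[, (drop_cols) := NULL]
  data.table::setcolorder(rows, c("patient_id", "t_start", "t_stop", "event",
                                  "era"))
  rows[]
}
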