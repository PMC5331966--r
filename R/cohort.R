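#' Study-era assignment
#'
#' Assigns the calendar era of first virologic suppression, used as the
#' stratification variable in all analyses. Boundaries (half-open):
#' 1995-01-01 to 2001-01-01, 2001-01-01 to 2006-01-01, 2006-01-01 to
#' 2012-01-01.
#'
#' @param date baseline date(s) (Date, ISO string or integer day).
#' @return integer era 1..3.
#' @export
assign_era <- function(date) {
  d <- as_day(date)
  br <- ERA_BREAKS()
  if (any(d < br[1L] | d >= br[4L], na.rm = TRUE))
    stop("date outside the 1995-2011 study window")
  findInterval(d, br)
}

# Effective numeric VL for threshold comparisons: undetectable results are
# below the assay limit and never satisfy a >200 or >1000 rule.
vl_effective <- function(value, detectable) {
  ifelse(detectable, value, 0)
}

# Does a result qualify as "undetectable" for suppression purposes? A result
# is undetectable iff reported below its assay LLOQ, and the assay limit in
# effect must itself be low enough to qualify (default: LLOQ <= 1000).
vl_suppressed <- function(detectable, lloq, lloq_max = 1000) {
  !detectable & lloq <= lloq_max
}

#' Detect virologic failure after suppression
#'
#' Scans post-baseline viral loads in date order and returns the first
#' qualifying failure: a single VL > 1000 copies/mL, or the first of two
#' consecutive measurements both > 200 copies/mL; the earliest qualifying
#' date wins. An unconfirmed trailing VL in (200, 1000] does not fail.
#'
#' @param dates integer days of post-baseline VL measurements, sorted.
#' @param values effective numeric VLs (0 for undetectable results).
#' @return list with `event` (flag) and `event_date` (integer day or `NA`).
#' @export
detect_failure <- function(dates, values) {
  n <- length(dates)
  if (n == 0L) return(list(event = FALSE, event_date = NA_integer_))
  over1000 <- values > 1000
  over200 <- values > 200
  confirmed <- over200 & c(over200[-1L], FALSE)
  qual <- over1000 | confirmed
  if (!any(qual)) return(list(event = FALSE, event_date = NA_integer_))
  list(event = TRUE, event_date = dates[which(qual)[1L]])
}

#' Apply the censoring rules to one patient's follow-up
#'
#' Follow-up ends at the earliest of: the virologic-failure date; the last VL
#' before a gap of more than `gap_days` between consecutive measurements
#' (allowing one missed visit under twice-yearly monitoring); or the last VL
#' before the administrative study end. When failure and a gap censor fall on
#' the same date, failure wins. For the combined endpoint, a death within
#' `gap_days` of the last analytic VL (and before study end) counts as an
#' event at the death date. Premature (informative) censoring is censoring
#' `gap_days` or more before study end.
#'
#' @param dates integer days of VL measurements from baseline on (first
#'   element is the baseline measurement), sorted.
#' @param values effective numeric VLs aligned with `dates` (baseline first).
#' @param death_date integer day of death or `NA`.
#' @param study_end administrative end of study (exclusive; default
#'   2012-01-01).
#' @param gap_days censoring gap, default 396 (13 months).
#' @param endpoint `"primary"` (time to failure) or `"combined"` (failure or
#'   death).
#' @return list with `exit_date`, `exit_reason` (`"failure"`, `"gap_censor"`,
#'   `"admin_censor"`, `"death"`), `event`, `event_date`, `premature_censor`.
#' @export
apply_censoring <- function(dates, values, death_date = NA_integer_,
                            study_end = "2012-01-01",
                            gap_days = DAYS_13_MONTHS,
                            endpoint = c("primary", "combined")) {
  endpoint <- match.arg(endpoint)
  end_day <- as_day(study_end)
  death_date <- as_day(death_date)
  if (!is.na(death_date) && length(dates) && death_date < dates[1L])
    stop("death before baseline: inconsistent input data")
  keep <- dates < end_day & (is.na(death_date) | dates <= death_date)
  dates <- dates[keep]; values <- values[keep]
  n <- length(dates)
  stopifnot(n >= 1L)

  fail <- detect_failure(dates[-1L], values[-1L])
  gap_at <- NA_integer_
  if (n >= 2L) {
    g <- which(diff(dates) > gap_days)
    if (length(g)) gap_at <- dates[g[1L]]
  }

  if (fail$event && (is.na(gap_at) || fail$event_date <= gap_at)) {
    exit_date <- fail$event_date; exit_reason <- "failure"
    event <- TRUE; event_date <- fail$event_date
  } else if (!is.na(gap_at)) {
    exit_date <- gap_at; exit_reason <- "gap_censor"
    event <- FALSE; event_date <- NA_integer_
  } else {
    exit_date <- dates[n]; exit_reason <- "admin_censor"
    event <- FALSE; event_date <- NA_integer_
  }

  if (endpoint == "combined" && !event && !is.na(death_date) &&
      death_date >= exit_date && death_date - exit_date <= gap_days &&
      death_date < end_day) {
    exit_date <- death_date; exit_reason <- "death"
    event <- TRUE; event_date <- death_date
  }

  premature <- exit_reason %in% c("gap_censor", "admin_censor") &&
    (end_day - exit_date >= gap_days)
  list(exit_date = exit_date, exit_reason = exit_reason,
       event = event, event_date = event_date, premature_censor = premature)
}

#' Apply inclusion criteria and find baseline
#'
#' A patient is included iff the VL series shows (a) at least one detectable
#' VL > 1000 copies/mL, (b) a subsequent undetectable VL on or after HAART
#' initiation, and (c) at least one further VL measurement within 13 months
#' of that undetectable one. Baseline is the date of the first qualifying
#' undetectable VL. Exclusion reasons are tallied.
#'
#' @param vls data.frame with columns `patient_id`, `date`, `value` (`NA` when
#'   undetectable), `lloq`, `detectable`.
#' @param patients data.frame with `patient_id` and `haart_start` (`NA` if
#'   HAART was never started).
#' @param lloq_max maximum assay LLOQ that qualifies a result as suppression
#'   (default 1000; set 50 for a stricter definition).
#' @param gap_days window for criterion (c), default 396 days.
#' @return data.table per patient: `included`, `exclusion_reason`
#'   (`"no_haart"`, `"no_high_vl"`, `"no_suppression"`, `"no_followup_vl"` or
#'   `NA`), `baseline_date`, `era`.
#' @export
select_cohort <- function(vls, patients, lloq_max = 1000,
                          gap_days = DAYS_13_MONTHS) {
  vls <- data.table::as.data.table(vls)
  vls[, date := as_day(date)]
  data.table::setorder(vls, patient_id, date)
  pts <- data.table::as.data.table(patients)
  pts[, haart_start := as_day(haart_start)]

  per <- vls[, {
    veff <- vl_effective(value, detectable)
    supp <- vl_suppressed(detectable, lloq, lloq_max)
    list(dates = list(date), veff = list(veff), supp = list(supp))
  }, by = patient_id]
  per <- merge(pts[, .(patient_id, haart_start)], per,
               by = "patient_id", all.x = TRUE)

  per[, c("included", "exclusion_reason", "baseline_date") := {
    inc <- logical(.N); rea <- rep(NA_character_, .N); bl <- rep(NA_integer_, .N)
    for (i in seq_len(.N)) {
      hs <- haart_start[i]
      d <- dates[[i]]; v <- veff[[i]]; s <- supp[[i]]
      if (is.na(hs)) { rea[i] <- "no_haart"; next }
      if (is.null(d) || !any(v > 1000)) { rea[i] <- "no_high_vl"; next }
      hi <- d[which(v > 1000)[1L]]
      cand <- which(s & d >= hs & d > hi)
      if (!length(cand)) { rea[i] <- "no_suppression"; next }
      b <- cand[1L]
      later <- which(d > d[b])
      if (!length(later) || d[later[1L]] - d[b] > gap_days) {
        rea[i] <- "no_followup_vl"; next
      }
      inc[i] <- TRUE; bl[i] <- d[b]
    }
    list(inc, rea, bl)
  }]
  per[, era := {
    e <- rep(NA_integer_, .N)
    ok <- !is.na(baseline_date)
    if (any(ok)) e[ok] <- assign_era(baseline_date[ok])
    e
  }]
  per[, .(patient_id, included, exclusion_reason, baseline_date, era)]
}

#' Build the full endpoint table for a cohort
#'
#' Runs [select_cohort()], then [detect_failure()] and [apply_censoring()]
#' per included patient, and flags sensitivity-cohort eligibility.
#'
#' @inheritParams select_cohort
#' @param study_end administrative end of study, default 2012-01-01.
#' @param endpoint `"primary"` or `"combined"` (see [apply_censoring()]).
#' @return data.table per patient with inclusion, baseline, era, exit and
#'   event fields, `premature_censor`, `sensitivity_eligible` and
#'   `sensitivity_baseline`.
#' @export
build_cohort <- function(vls, patients, study_end = "2012-01-01",
                         lloq_max = 1000, gap_days = DAYS_13_MONTHS,
                         endpoint = "primary") {
  vls <- data.table::as.data.table(vls)
  vls[, date := as_day(date)]
  data.table::setorder(vls, patient_id, date)
  pts <- data.table::as.data.table(patients)
  entries <- select_cohort(vls, pts, lloq_max = lloq_max, gap_days = gap_days)
  dd <- if ("death_date" %in% names(pts))
    pts[, .(patient_id, death_date = as_day(death_date))]
  else data.table::data.table(patient_id = entries$patient_id,
                              death_date = NA_integer_)
  entries <- merge(entries, dd, by = "patient_id", all.x = TRUE)

  vsub <- merge(vls, entries[included == TRUE,
                             .(patient_id, baseline_date, death_date)],
                by = "patient_id")
  vsub <- vsub[date >= baseline_date]
  ends <- vsub[, {
    bl <- baseline_date[1L]
    res <- apply_censoring(date, vl_effective(value, detectable),
                           death_date = death_date[1L],
                           study_end = study_end, gap_days = gap_days,
                           endpoint = endpoint)
    supp <- vl_suppressed(detectable, lloq, lloq_max)
    sens_cand <- date[supp & date >= bl + DAYS_6_MONTHS &
                        date <= res$exit_date &
                        (!res$event | date < res$event_date)]
    list(exit_date = res$exit_date, exit_reason = res$exit_reason,
         event = res$event, event_date = res$event_date,
         premature_censor = res$premature_censor,
         sensitivity_eligible = length(sens_cand) > 0L,
         sensitivity_baseline = if (length(sens_cand)) sens_cand[1L] else NA_integer_)
  }, by = patient_id]

  out <- merge(entries, ends, by = "patient_id", all.x = TRUE)
  out[included != TRUE, `:=`(sensitivity_eligible = FALSE)]
  out[]
}

#' Sensitivity-cohort eligibility
#'
#' A patient qualifies for the sensitivity analysis iff an undetectable VL
#' exists at least six months after baseline with no intervening failure;
#' the sensitivity baseline is re-anchored at that measurement.
#'
#' @param entries output of [build_cohort()].
#' @return the entries restricted to eligible patients, with `baseline_date`
#'   replaced by the re-anchored sensitivity baseline.
#' @export
sensitivity_cohort <- function(entries) {
  out <- data.table::as.data.table(entries)[sensitivity_eligible == TRUE]
  out[, baseline_date := sensitivity_baseline]
  out[]
}
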