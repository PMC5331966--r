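#' Day-resolution drug exposure calendars
#'
#' An exposure calendar stores, per patient and drug class, the set of days on
#' which the patient had drug on hand, as sorted disjoint half-open integer
#' day intervals `[start, end)`. It is the substrate for the three
#' time-updated exposure modes: [current_use()], [proportion_days_covered()]
#' and [ever_use()].
#'
#' @name exposure_calendar
NULL

new_exposure_calendar <- function(dt) {
  dt <- data.table::as.data.table(dt)
  stopifnot(all(c("patient_id", "class", "start", "end") %in% names(dt)))
  dt <- dt[end > start]
  data.table::setkey(dt, patient_id, class, start)
  data.table::setattr(dt, "class", c("exposure_calendar", class(dt)))
  dt
}

#' @export
print.exposure_calendar <- function(x, ...) {
  cat(sprintf("<exposure_calendar> %d episodes, %d patients, classes: %s\n",
              nrow(x), data.table::uniqueN(x$patient_id),
              paste(sort(unique(x$class)), collapse = ", ")))
  NextMethod()
}

# Stock simulation for one drug of one patient.
#
# Each outpatient fill adds days_supply to the remaining stock; each
# non-hospitalized day with stock > 0 is exposed and consumes one day of
# stock. Hospitalized days neither consume stock nor count as outpatient
# exposure. A fill of a *different* drug in the same class discards the
# remaining stock (change of therapy). Early-refill surplus accumulates
# without cap.
simulate_drug_stock <- function(fill_day, supply, discard_day, stay_s, stay_e) {
  bp <- sort(unique(c(fill_day, discard_day, stay_s, stay_e)))
  n <- length(bp)
  out_s <- integer(n + 1L); out_e <- integer(n + 1L); m <- 0L
  stock <- 0L
  for (k in seq_len(n)) {
    t <- bp[k]
    if (t %in% discard_day) stock <- 0L
    add <- supply[fill_day == t]
    if (length(add)) stock <- stock + sum(add)
    if (stock > 0L) {
      in_hosp <- any(stay_s <= t & t < stay_e)
      if (!in_hosp) {
        seg <- if (k < n) bp[k + 1L] - t else stock
        use <- min(stock, seg)
        if (use > 0L) {
          m <- m + 1L
          out_s[m] <- t; out_e[m] <- t + use
          stock <- stock - use
        }
      }
    }
  }
  union_intervals(out_s[seq_len(m)], out_e[seq_len(m)])
}

#' Build day-level exposure calendars from dispensing records
#'
#' Reconstructs uninterrupted exposure episodes on a day-to-day basis from
#' outpatient fills and inpatient medication orders, under a stock model:
#' patients are assumed continuously exposed to filled outpatient medication
#' until the supply runs out. Early refills accumulate surplus supply; a fill
#' of a different drug in the same class discards the prior drug's remaining
#' supply; hospitalized days pause outpatient consumption and are exposed only
#' if an inpatient order for a drug of the class covers the stay. Class-level
#' exposure is the union over member drugs.
#'
#' @param fills data.frame of dispensing records with columns `patient_id`,
#'   `drug_code`, `fill_date` (Date, ISO string or integer day),
#'   `days_supply`, and optionally `setting` (`"outpatient"` (default) or
#'   `"inpatient_order"`).
#' @param stays optional data.frame of hospitalizations with columns
#'   `patient_id`, `admit_date`, `discharge_date` (inclusive; the stay covers
#'   `[admit_date, discharge_date]`). Stays must not overlap within patient.
#' @param class_map data.frame mapping `drug_code` to `class` (and optionally
#'   `subtype`; a non-empty subtype yields the label `"class:subtype"`).
#' @return an `exposure_calendar` (data.table with `patient_id`, `class`,
#'   `start`, `end`; half-open integer day intervals).
#' @export
build_exposure_calendar <- function(fills, stays = NULL, class_map) {
  fills <- data.table::as.data.table(fills)
  if (!"setting" %in% names(fills)) fills[, setting := "outpatient"]
  fills[, fill_date := as_day(fill_date)]
  fills[, days_supply := as.integer(days_supply)]

  bad <- fills$days_supply < 1L | is.na(fills$days_supply)
  if (any(bad)) {
    warning(sprintf("rejected %d dispensing record(s) with days_supply < 1", sum(bad)))
    fills <- fills[!bad]
  }

  cmap <- data.table::as.data.table(class_map)
  if ("subtype" %in% names(cmap)) {
    cmap[, label := ifelse(is.na(subtype) | subtype == "", class,
                           paste(class, subtype, sep = ":"))]
  } else cmap[, label := class]
  if (anyDuplicated(cmap$drug_code))
    stop("class_map maps some drug_code to more than one class")
  fills <- merge(fills, cmap[, .(drug_code, label)], by = "drug_code")

  if (!is.null(stays) && nrow(stays <- data.table::as.data.table(stays))) {
    stays[, `:=`(admit = as_day(admit_date), disch_excl = as_day(discharge_date) + 1L)]
    data.table::setorder(stays, patient_id, admit)
    ov <- stays[, any(admit[-1L] < disch_excl[-.N]), by = patient_id]$V1
    if (any(ov)) stop("overlapping hospital stays within patient")
  } else {
    stays <- data.table::data.table(patient_id = fills$patient_id[0],
                                    admit = integer(0), disch_excl = integer(0))
  }

  # Indexed flat loop over patient x class groups (one pass over sorted
  # vectors; per-group work is a handful of small-vector operations).
  data.table::setorder(fills, patient_id, label, drug_code, fill_date)
  fills[, gid := .GRP, by = .(patient_id, label)]

  stay_pat <- unique(stays$patient_id)
  stay_idx <- split(seq_len(nrow(stays)), match(stays$patient_id, stay_pat))
  st_admit <- stays$admit; st_disch <- stays$disch_excl

  gstart <- c(1L, which(diff(fills$gid) != 0L) + 1L)
  gend <- c(gstart[-1L] - 1L, nrow(fills))
  f_pat <- fills$patient_id; f_lab <- fills$label; f_drug <- fills$drug_code
  f_day <- fills$fill_date; f_sup <- fills$days_supply
  f_out <- fills$setting == "outpatient"
  pat_to_stay <- match(f_pat[gstart], stay_pat)

  res_pid <- vector("list", length(gstart))
  res_lab <- character(length(gstart))
  res_iv <- vector("list", length(gstart))
  for (g in seq_along(gstart)) {
    i <- gstart[g]:gend[g]
    si <- pat_to_stay[g]
    if (is.na(si)) { ss <- integer(0); se <- integer(0) }
    else { j <- stay_idx[[si]]; ss <- st_admit[j]; se <- st_disch[j] }
    op <- i[f_out[i]]
    res_s <- integer(0); res_e <- integer(0)
    if (length(op)) {
      dgs <- unique(f_drug[op])
      for (dg in dgs) {
        own <- op[f_drug[op] == dg]
        disc <- if (length(dgs) > 1L) unique(f_day[op[f_drug[op] != dg]])
        else integer(0)
        iv <- simulate_drug_stock(f_day[own], f_sup[own], disc, ss, se)
        res_s <- c(res_s, iv$start); res_e <- c(res_e, iv$end)
      }
    }
    ip <- i[!f_out[i]]
    if (length(ip) && length(ss)) {
      iv <- intersect_intervals(f_day[ip], f_day[ip] + f_sup[ip], ss, se)
      res_s <- c(res_s, iv$start); res_e <- c(res_e, iv$end)
    }
    u <- union_intervals(res_s, res_e)
    res_pid[[g]] <- f_pat[gstart[g]]
    res_lab[g] <- f_lab[gstart[g]]
    res_iv[[g]] <- u
  }
  nper <- vapply(res_iv, function(u) length(u$start), integer(1))
  out <- data.table::data.table(
    patient_id = rep(unlist(res_pid), nper),
    class = rep(res_lab, nper),
    start = unlist(lapply(res_iv, `[[`, "start")),
    end = unlist(lapply(res_iv, `[[`, "end")))
  new_exposure_calendar(out)
}

# Fetch the interval set for one patient x class.
calendar_intervals <- function(calendar, patient, cls) {
  sub <- calendar[.(patient, cls), on = c("patient_id", "class"), nomatch = NULL]
  list(start = sub$start, end = sub$end)
}

#' Current use of a drug class
#'
#' True iff there is at least one exposed day within the previous
#' `window_days` days of the query date, i.e. in the closed window
#' `[date - window_days, date]`: exposure exactly `window_days` ago still
#' counts, as does exposure on the query day itself.
#'
#' @param calendar an [exposure_calendar].
#' @param patient patient identifier.
#' @param cls class label.
#' @param date query date(s) (Date, ISO string or integer day).
#' @param window_days look-back window, default 7.
#' @return logical vector along `date`.
#' @export
current_use <- function(calendar, patient, cls, date, window_days = 7L) {
  stopifnot(window_days >= 1L)
  d <- as_day(date)
  iv <- calendar_intervals(calendar, patient, cls)
  (cum_exposed_days(iv$start, iv$end, d) -
     cum_exposed_days(iv$start, iv$end, d - as.integer(window_days) - 1L)) > 0L
}

#' Proportion of days covered (PDC)
#'
#' Fraction of the look-back window `(date - window_days, date]` on which the
#' patient had drug supply on hand. The conventional windows are 30 days for
#' statins and cardiovascular medications and 91 days for antiretrovirals.
#'
#' @inheritParams current_use
#' @param window_days look-back window length in days.
#' @return numeric vector in `[0, 1]` along `date`.
#' @export
proportion_days_covered <- function(calendar, patient, cls, date, window_days) {
  stopifnot(window_days >= 1L)
  d <- as_day(date)
  iv <- calendar_intervals(calendar, patient, cls)
  (cum_exposed_days(iv$start, iv$end, d) -
     cum_exposed_days(iv$start, iv$end, d - as.integer(window_days))) /
    as.numeric(window_days)
}

#' Ever use (categorical exposure)
#'
#' True from the first exposed day onward, permanently.
#'
#' @inheritParams current_use
#' @return logical vector along `date`.
#' @export
ever_use <- function(calendar, patient, cls, date) {
  d <- as_day(date)
  iv <- calendar_intervals(calendar, patient, cls)
  if (length(iv$start) == 0L) return(rep(FALSE, length(d)))
  d >= iv$start[1L]
}

# Vectorised exposure-mode evaluation used by the counting-process assembler.
# `intervals` is a data.table(patient_id, start, end); queries a
# data.table(patient_id, date). Computed via a patient-level join so all
# window overlaps are evaluated in one vectorised pass.
exposure_modes_at <- function(intervals, queries, pdc_window,
                              current_window = 7L) {
  q <- data.table::data.table(patient_id = queries$patient_id,
                              date = as_day(queries$date))
  q[, idx := .I]
  if (nrow(intervals) == 0L)
    return(data.table::data.table(current = rep(FALSE, nrow(q)),
                                  pdc = 0, ever = FALSE))
  m <- intervals[q, on = "patient_id", allow.cartesian = TRUE]
  w <- as.integer(pdc_window); cw <- as.integer(current_window)
  m[, ovc := pmax(0L, pmin(end, date + 1L) - pmax(start, date - cw))]
  m[, ovw := pmax(0L, pmin(end, date + 1L) - pmax(start, date - w + 1L))]
  res <- m[, .(current = sum(ovc, na.rm = TRUE) > 0L,
               pdc = sum(ovw, na.rm = TRUE) / as.numeric(w),
               ever = any(!is.na(start) & start <= date)), by = idx]
  data.table::setorder(res, idx)
  res[, .(current, pdc, ever)]
}

# Subset a calendar to one class label as a plain interval table.
class_intervals <- function(calendar, cls) {
  calendar[class == cls, .(patient_id, start, end)]
}

#' Write / read a run-length encoded exposure calendar
#'
#' @param calendar an [exposure_calendar].
#' @param path CSV path; columns `patient_id`, `class`, `start_date`,
#'   `end_date_exclusive` in ISO-8601.
#' @return `read_exposure_csv` returns an [exposure_calendar].
#' @export
write_exposure_csv <- function(calendar, path) {
  out <- data.table::data.table(
    patient_id = calendar$patient_id, class = calendar$class,
    start_date = day_to_date(calendar$start),
    end_date_exclusive = day_to_date(calendar$end))
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_exposure_csv
#' @export
read_exposure_csv <- function(path) {
  dt <- data.table::fread(path)
  new_exposure_calendar(data.table::data.table(
    patient_id = dt$patient_id, class = dt$class,
    start = as_day(dt$start_date), end = as_day(dt$end_date_exclusive)))
}
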