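# Independent oracles: deliberately naive day-by-day implementations used to
# cross-check the vectorised/event-driven package code.

# Day-loop stock simulator for one patient and one drug class. Walks every
# single day, maintaining per-drug stock: a fill adds supply; a different
# drug's outpatient fill discards stock; a non-hospitalised day with stock
# consumes one day and is exposed; hospitalised days are exposed only under
# an inpatient order. Returns the sorted exposed days.
oracle_exposed_days <- function(fills, stays = NULL, horizon = NULL) {
  if (is.null(horizon))
    horizon <- max(fills$fill_date + fills$days_supply) +
      sum(fills$days_supply) + 10L
  if (is.null(stays) || nrow(stays) == 0L)
    stays <- data.frame(admit = integer(0), disch_excl = integer(0))
  in_hosp <- function(d) any(stays$admit <= d & d < stays$disch_excl)
  exposed <- logical(horizon + 1L)
  op <- fills[fills$setting == "outpatient", , drop = FALSE]
  for (dg in unique(op$drug_code)) {
    stock <- 0L
    for (d in 0:horizon) {
      if (any(op$drug_code != dg & op$fill_date == d)) stock <- 0L
      stock <- stock + sum(op$days_supply[op$drug_code == dg & op$fill_date == d])
      if (!in_hosp(d) && stock > 0L) {
        exposed[d + 1L] <- TRUE
        stock <- stock - 1L
      }
    }
  }
  ip <- fills[fills$setting == "inpatient_order", , drop = FALSE]
  if (nrow(ip)) {
    for (d in 0:horizon) {
      if (in_hosp(d) &&
          any(ip$fill_date <= d & d < ip$fill_date + ip$days_supply))
        exposed[d + 1L] <- TRUE
    }
  }
  which(exposed) - 1L
}

calendar_days <- function(cal, pid, cls) {
  sub <- cal[cal$patient_id == pid & cal$class == cls, , drop = FALSE]
  if (nrow(sub) == 0L) return(integer(0))
  sort(unlist(mapply(function(s, e) s:(e - 1L), sub$start, sub$end,
                     SIMPLIFY = FALSE)))
}

# Random dispensing history for one patient: n_fills outpatient fills over a
# couple of drugs of one class, up to n_stays non-overlapping stays, with
# inpatient orders for some stays.
random_history <- function(n_fills, n_stays, drugs = c("d1", "d2")) {
  fills <- data.frame(
    patient_id = "P1",
    drug_code = sample(drugs, n_fills, TRUE),
    fill_date = sort(sample(0:400, n_fills, TRUE)),
    days_supply = sample(1:60, n_fills, TRUE),
    setting = "outpatient", stringsAsFactors = FALSE)
  stays <- NULL
  if (n_stays > 0L) {
    admit <- sort(sample(0:420, n_stays))
    dur <- sample(2:20, n_stays, TRUE)
    disch <- admit + dur
    keep <- c(TRUE, admit[-1L] >= cummax(disch[-n_stays]))
    admit <- admit[keep]; disch <- disch[keep]
    stays <- data.frame(patient_id = "P1", admit = admit, disch_excl = disch)
    for (i in seq_along(admit)) {
      if (runif(1) < 0.6) {
        fills <- rbind(fills, data.frame(
          patient_id = "P1", drug_code = sample(drugs, 1),
          fill_date = admit[i],
          days_supply = disch[i] - admit[i],
          setting = "inpatient_order", stringsAsFactors = FALSE))
      }
    }
  }
  list(fills = fills, stays = stays)
}

# Brute-force endpoint scan: a direct sequential transcription of the
# printed rules, walking the VL sequence one measurement at a time.
oracle_endpoint <- function(dates, values, death = NA, study_end,
                            gap = 396L, endpoint = "primary") {
  end_day <- as.integer(as.Date(study_end))
  keep <- dates < end_day
  if (!is.na(death)) keep <- keep & dates <= death
  dates <- dates[keep]; values <- values[keep]
  n <- length(dates)
  fail_date <- NA_integer_
  for (i in 2:max(2L, n)) {
    if (i > n) break
    if (values[i] > 1000) { fail_date <- dates[i]; break }
    if (values[i] > 200 && i < n && values[i + 1] > 200) {
      fail_date <- dates[i]; break
    }
  }
  gap_date <- NA_integer_
  for (i in seq_len(max(0L, n - 1L))) {
    if (dates[i + 1L] - dates[i] > gap) { gap_date <- dates[i]; break }
  }
  if (!is.na(fail_date) && (is.na(gap_date) || fail_date <= gap_date)) {
    out <- list(exit_date = fail_date, exit_reason = "failure",
                event = TRUE, event_date = fail_date)
  } else if (!is.na(gap_date)) {
    out <- list(exit_date = gap_date, exit_reason = "gap_censor",
                event = FALSE, event_date = NA_integer_)
  } else {
    out <- list(exit_date = dates[n], exit_reason = "admin_censor",
                event = FALSE, event_date = NA_integer_)
  }
  if (endpoint == "combined" && !out$event && !is.na(death) &&
      death >= out$exit_date && death - out$exit_date <= gap &&
      death < end_day) {
    out <- list(exit_date = death, exit_reason = "death",
                event = TRUE, event_date = death)
  }
  out$premature_censor <- out$exit_reason %in% c("gap_censor", "admin_censor") &&
    end_day - out$exit_date >= gap
  out
}

# Random VL series (integer days, effective values; baseline undetectable
# first). Values 0 stand for undetectable results.
random_vl_series <- function(max_len = 30L) {
  n <- sample(2:max_len, 1L)
  dates <- as.integer(as.Date("2002-06-01")) + c(0L, sort(sample(1:3000, n - 1L)))
  pool <- c(0, 0, 0, 150, 250, 400, 800, 1500, 50000)
  values <- c(0, sample(pool, n - 1L, TRUE))
  list(dates = dates, values = values)
}

# Direct truth-table evaluation of the four combination-therapy rules,
# written from the category definitions rather than the classifier code.
oracle_haart <- function(arvs) {
  voc <- arv_vocabulary()
  ty <- voc$arv_type[match(arvs, voc$compound)]
  nrti <- arvs[ty == "nrti"]
  pi <- arvs[ty == "pi"]
  nnrti <- arvs[ty == "nnrti"]
  insti <- arvs[ty == "insti"]
  anchors <- c(pi, nnrti, insti)
  rtv <- "ritonavir" %in% arvs
  rule1 <- length(anchors) >= 1 && length(nrti) >= 2
  rule2 <- length(nrti) >= 1 && length(pi) >= 1 && length(nnrti) >= 1
  rule3 <- rtv && length(pi) >= 1 && length(nnrti) >= 1
  rule4 <- ("tenofovir" %in% nrti || "abacavir" %in% nrti) &&
    ("zidovudine" %in% nrti) &&
    ("lamivudine" %in% nrti || "emtricitabine" %in% nrti)
  rule1 || rule2 || rule3 || rule4
}

demo_class_map <- function() {
  data.frame(drug_code = c("d1", "d2"), class = "statin", subtype = "",
             stringsAsFactors = FALSE)
}
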