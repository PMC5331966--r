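#' Configuration for the synthetic-cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort of patients
#' starting combination ART 1995-2011, monitored by viral load every 3-6
#' months with missed visits, era-dependent assay detection limits, about one
#' third ever using statins with only ~41% of post-initiation time actually
#' covered, and a daily rebound hazard with configurable true effects of
#' current statin exposure and ART adherence. Statin prescribing is
#' confounded by age, adherence, race, substance use and era with
#' configurable strengths.
#'
#' The rebound hazard on day t is
#' `baseline_daily * exp(b_statin * current_statin + b_adh * (ART_PDC - 1) +
#' covariate and era terms)`, with `current_statin` (any statin exposure in
#' the previous 7 days) and the 91-day ART PDC evaluated at the most recent
#' monitoring visit and carried forward until the next visit, mirroring how
#' time-updated exposure enters the analysis model.
#'
#' @param n_patients number of patients (>= 1).
#' @param seed integer RNG seed; identical config + seed reproduces the
#'   dataset byte for byte.
#' @param study_start,study_end study window (ISO dates).
#' @param true_log_hr_statin true log hazard ratio of current statin use.
#' @param true_log_hr_adherence true log HR per unit of (ART PDC - 1).
#' @param covariate_log_hr named log-HRs: `age` (per year, centered at 46),
#'   `race_white`, `substance`.
#' @param era_log_hr length-3 log-HR offsets by suppression era.
#' @param baseline_monthly_hazard monthly rebound probability for a fully
#'   adherent, statin-unexposed reference patient.
#' @param statin_ever_fraction target fraction of ever-statin users.
#' @param statin_coverage_target target proportion of post-initiation time
#'   covered by statin supply.
#' @param statin_episode_mean_days mean length of a covered statin episode.
#' @param cvm_ever_fraction,cvm_coverage_target named (ALP, AHT, ASA)
#'   analogues for the other cardiovascular medication classes.
#' @param monitoring_interval_days,monitoring_jitter_days mean VL monitoring
#'   interval and uniform jitter (days).
#' @param missed_visit_prob probability a scheduled visit is missed.
#' @param dropout_per_visit per-visit probability of permanently leaving VL
#'   monitoring (informative censoring source).
#' @param dropout_adherence_logodds log-odds shift of dropout per unit of
#'   (adherence - 0.75); negative = poor adherers drop out more.
#' @param confounding_strengths named log-odds of ever-statin prescribing:
#'   `age` (per year), `adherence` (per unit), `race_white`, `substance`,
#'   `era` (per era index).
#' @param art_adherence_beta shape parameters of the Beta distribution of
#'   the latent per-patient ART adherence.
#' @param art_episode_mean_days mean length of a covered ART episode.
#' @param hospitalization_rate_py hospital admissions per patient-year.
#' @param death_rate_py baseline death rate per patient-year (age-modified).
#' @param frac_never_suppress,frac_no_followup fractions of patients failing
#'   the inclusion criteria by never suppressing / lacking a timely
#'   follow-up VL.
#' @param fill_max_days maximum days supply per dispensing record.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000L,
                       seed = 1L,
                       study_start = "1995-01-01",
                       study_end = "2012-01-01",
                       true_log_hr_statin = log(0.8),
                       true_log_hr_adherence = -2.2,
                       covariate_log_hr = c(age = 0.01, race_white = -0.15,
                                            substance = 0.2),
                       era_log_hr = c(0.2, 0, -0.2),
                       baseline_monthly_hazard = 0.020,
                       statin_ever_fraction = 0.34,
                       statin_coverage_target = 0.41,
                       statin_episode_mean_days = 45,
                       cvm_ever_fraction = c(ALP = 0.21, AHT = 0.60, ASA = 0.30),
                       cvm_coverage_target = c(ALP = 0.32, AHT = 0.60, ASA = 0.27),
                       monitoring_interval_days = 120,
                       monitoring_jitter_days = 45,
                       missed_visit_prob = 0.12,
                       dropout_per_visit = 0.04,
                       dropout_adherence_logodds = -1,
                       confounding_strengths = c(age = 0.05, adherence = 1.5,
                                                 race_white = 0.6,
                                                 substance = -0.6, era = 0.4),
                       art_adherence_beta = c(3.2, 1.1),
                       art_episode_mean_days = 120,
                       hospitalization_rate_py = 0.2,
                       death_rate_py = 0.02,
                       frac_never_suppress = 0.03,
                       frac_no_followup = 0.02,
                       fill_max_days = 90L) {
  cfg <- as.list(environment())
  probs <- c(cfg$baseline_monthly_hazard, cfg$statin_ever_fraction,
             cfg$statin_coverage_target, cfg$cvm_ever_fraction,
             cfg$cvm_coverage_target, cfg$missed_visit_prob,
             cfg$dropout_per_visit, cfg$frac_never_suppress,
             cfg$frac_no_followup)
  stopifnot(n_patients >= 1, all(probs >= 0 & probs <= 1),
            as_day(study_start) < as_day(study_end),
            length(era_log_hr) == 3)
  class(cfg) <- "sim_config"
  cfg
}

# Alternating covered/gap episode matrices: n patients x k episodes, covered
# episodes [S, E) starting at `start`, exponential lengths with the given
# means, truncated at `horizon`.
episode_matrices <- function(n, k, start, cov_mean, gap_mean, horizon) {
  cov_len <- matrix(pmax(3, round(rexp(n * k, 1 / cov_mean))), n, k)
  gap_len <- matrix(pmax(1, round(rexp(n * k, 1 / gap_mean))), n, k)
  cyc <- cov_len + gap_len
  off <- cbind(0, t(apply(cyc, 1L, cumsum))[, -k, drop = FALSE])
  S <- start + off
  E <- S + cov_len
  S <- pmin(S, horizon); E <- pmin(E, horizon)
  E[E <= S] <- S[E <= S]  # degenerate episodes vanish
  list(S = S, E = E)
}

# Window-covered day counts against episode matrices. `row` indexes patients
# (rows of S/E), `day` the query days; counts days of (day-window, day] that
# fall in a covered episode.
planned_overlap_days <- function(S, E, row, day, window) {
  acc <- numeric(length(day))
  lo <- day - window + 1
  for (k in seq_len(ncol(S))) {
    acc <- acc + pmax(0, pmin(E[row, k], day + 1) - pmax(S[row, k], lo))
  }
  acc
}

# Assay lower limit of quantitation in effect at a date: 500 copies/mL
# before 2001, 50 from 2001, 20 from 2010.
lloq_at <- function(day) {
  data.table::fcase(day < as_day("2001-01-01"), 500,
                    day < as_day("2010-01-01"), 50,
                    default = 20)
}

# Expand clipped covered episodes into abutting outpatient fills plus
# inpatient orders. Total outpatient supply for an episode equals its
# non-hospitalized day count, so the stock model reconstructs the episode
# exactly: hospitalized days are covered by inpatient orders, outpatient
# stock is consumed only on the remaining days.
episodes_to_fills <- function(ep, stays, fill_max) {
  if (nrow(ep) == 0L)
    return(data.table::data.table(patient_id = character(0),
                                  drug_code = character(0),
                                  fill_date = integer(0),
                                  days_supply = integer(0),
                                  setting = character(0)))
  ep <- data.table::copy(ep)[, eid := .I]
  orders <- NULL
  ep[, hosp := 0L]
  if (!is.null(stays) && nrow(stays)) {
    ov <- stays[ep, on = "patient_id", allow.cartesian = TRUE, nomatch = NULL]
    ov[, o_s := pmax(admit, s)]
    ov[, o_e := pmin(disch_excl, e)]
    ov <- ov[o_e > o_s]
    if (nrow(ov)) {
      hs <- ov[, .(hosp = sum(o_e - o_s)), by = eid]
      ep[hs, hosp := i.hosp, on = "eid"]
      orders <- ov[, .(patient_id, drug_code, fill_date = o_s,
                       days_supply = o_e - o_s, setting = "inpatient_order")]
    }
  }
  ep[, supply := (e - s) - hosp]
  fl <- ep[supply > 0L]
  nf <- ceiling(fl$supply / fill_max)
  idx <- rep(seq_len(nrow(fl)), nf)
  k <- sequence(nf) - 1L
  fills <- data.table::data.table(
    patient_id = fl$patient_id[idx],
    drug_code = fl$drug_code[idx],
    fill_date = fl$s[idx] + k * fill_max,
    days_supply = pmin(fill_max, fl$supply[idx] - k * fill_max),
    setting = "outpatient")
  rbind(fills, orders)
}

#' Simulate a synthetic HIV cohort with known ground truth
#'
#' Generates the full delimited-table inputs of the analysis pipeline -
#' dispensing records, hospital stays, viral loads with era-dependent
#' detection limits, labs, demographics, diagnosis events, death dates -
#' plus a hidden per-patient-day truth table (actual statin exposure and the
#' rebound hazard in force). Rebound between visits is detected at the next
#' visit, with magnitudes drawn log-uniform on [200, 1e5] so both failure
#' rules (single VL > 1000; two consecutive > 200) occur. Identical seed and
#' config give a byte-identical dataset.
#'
#' @param config a [sim_config()].
#' @param keep_truth build the day-level truth table (set `FALSE` to save
#'   memory in large parameter-recovery runs).
#' @return a `synthetic_cohort` list of data.tables: `fills`, `stays`,
#'   `viral_loads`, `labs`, `demographics`, `icd_events`, `drug_classes`,
#'   `truth` (day level, if requested), `truth_patients` (per patient:
#'   ever-statin, latent adherence, true rebound day), and the `config`.
#' @export
simulate_cohort <- function(config, keep_truth = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  ss <- as_day(config$study_start); se <- as_day(config$study_end)
  if (se - ss < 300L)
    stop("degenerate config: study window too short for any follow-up")
  pid <- sprintf("P%06d", seq_len(n))

  ## ---- demographics and latent traits ----
  age <- pmin(75, pmax(25, round(rnorm(n, 46, 9))))
  race <- sample(c("African American", "White", "Unknown"), n, TRUE,
                 prob = c(0.47, 0.36, 0.17))
  gender <- sample(c("M", "F"), n, TRUE, prob = c(0.97, 0.03))
  hcv <- runif(n) < 0.26
  substance <- runif(n) < 0.33
  pre_arv <- ifelse(runif(n) < 0.29, round(runif(n, 30, 1000)), 0L)
  adh <- pmin(0.99, pmax(0.10, rbeta(n, config$art_adherence_beta[1],
                                     config$art_adherence_beta[2])))

  haart_start <- ss + floor(runif(n) * (as_day("2011-06-01") - ss))
  hiv_dx <- haart_start - round(runif(n, 0, 2920))
  b <- haart_start + round(runif(n, 30, 180))  # first undetectable VL
  era_b <- findInterval(b, ERA_BREAKS())
  era_h <- findInterval(haart_start, ERA_BREAKS())

  death_rate <- config$death_rate_py / 365.25 * exp(0.03 * (age - 46))
  death <- haart_start + round(rexp(n, death_rate))
  death[death >= se] <- NA_integer_

  never_sup <- runif(n) < config$frac_never_suppress
  no_fup <- !never_sup & runif(n) < config$frac_no_followup
  # patients on the normal trajectory: suppress and keep monitored follow-up
  normal <- !never_sup & !no_fup

  ## ---- statin / CVM assignment (confounded) ----
  cs <- config$confounding_strengths
  lp_statin <- cs[["age"]] * (age - 46) + cs[["adherence"]] * (adh - 0.75) +
    cs[["race_white"]] * (race == "White") + cs[["substance"]] * substance +
    cs[["era"]] * (era_b - 2)
  alpha <- if (config$statin_ever_fraction <= 0) -Inf else
    uniroot(function(a) mean(plogis(a + lp_statin)) - config$statin_ever_fraction,
            c(-12, 12))$root
  statin_user <- runif(n) < plogis(alpha + lp_statin) & normal
  # ~21% of ever-users are already on statin at first suppression (7% baseline
  # use vs 34% ever-use); the rest initiate spread over the observation period
  statin_pre_base <- runif(n) < 0.21
  statin_start <- ifelse(statin_pre_base,
                         haart_start + floor(runif(n) * pmax(1, b - haart_start)),
                         b + floor(runif(n) * pmin(6000, pmax(60, se - b - 60))))
  statin_compound <- sample(c("pravastatin", "simvastatin", "fluvastatin",
                              "rosuvastatin", "atorvastatin", "lovastatin"),
                            n, TRUE,
                            prob = c(0.40, 0.23, 0.13, 0.13, 0.09, 0.02))

  cvm_user <- list(); cvm_start <- list()
  cvm_drug <- c(ALP = "gemfibrozil", AHT = "lisinopril", ASA = "aspirin")
  for (cl in names(config$cvm_ever_fraction)) {
    lp <- 0.05 * (age - 46)
    frac <- config$cvm_ever_fraction[[cl]]
    a0 <- if (frac <= 0) -Inf else
      uniroot(function(a) mean(plogis(a + lp)) - frac, c(-12, 12))$root
    cvm_user[[cl]] <- runif(n) < plogis(a0 + lp) & normal
    cvm_start[[cl]] <- haart_start +
      pmin(round(rexp(n, 1 / 700)), pmax(0, se - haart_start - 60))
  }

  ## ---- covered/gap episode structure ----
  c_art <- adh
  art_ep <- episode_matrices(n, 40L, haart_start,
                             config$art_episode_mean_days,
                             config$art_episode_mean_days * (1 - c_art) / c_art,
                             horizon = se)
  c_st <- config$statin_coverage_target
  st_ep <- episode_matrices(n, 30L, statin_start,
                            config$statin_episode_mean_days,
                            config$statin_episode_mean_days * (1 - c_st) / c_st,
                            horizon = se)
  cvm_ep <- list()
  for (cl in names(config$cvm_ever_fraction)) {
    cc <- config$cvm_coverage_target[[cl]]
    cvm_ep[[cl]] <- episode_matrices(n, 30L, cvm_start[[cl]],
                                     config$statin_episode_mean_days,
                                     config$statin_episode_mean_days * (1 - cc) / cc,
                                     horizon = se)
  }

  ## ---- monitoring-visit schedule ----
  K <- 70L
  gaps <- matrix(pmax(14, round(config$monitoring_interval_days +
                                  runif(n * K, -1, 1) * config$monitoring_jitter_days)),
                 n, K)
  V <- b + t(apply(gaps, 1L, cumsum))
  missed <- matrix(runif(n * K) < config$missed_visit_prob, n, K)
  p_drop <- plogis(qlogis(config$dropout_per_visit) +
                     config$dropout_adherence_logodds * (adh - 0.75))
  dropm <- matrix(runif(n * K) < p_drop, n, K)
  di <- max.col(dropm, "first")
  drop_cut <- ifelse(dropm[cbind(seq_len(n), di)], di, K + 1L)

  lastday <- pmin(se - 1L, ifelse(is.na(death), se, death))
  valid <- !missed &
    sweep(matrix(rep(seq_len(K), each = n), n, K), 1L, drop_cut, "<=") &
    V <= lastday

  vi <- which(normal & b <= lastday)
  Vv <- V[vi, , drop = FALSE]
  Mv <- valid[vi, , drop = FALSE]
  sel <- which(Mv, arr.ind = TRUE)
  vis <- rbind(
    data.table::data.table(row = vi, day = b[vi]),
    data.table::data.table(row = vi[sel[, 1L]], day = Vv[sel]))
  # patients excluded for delayed follow-up contribute a baseline and later
  # (undetectable) visits only; they never enter analytic follow-up
  nf <- which(no_fup & b <= lastday)

  ## ---- hazard per inter-visit interval, rebound draw ----
  bd <- config$baseline_monthly_hazard / DAYS_PER_MONTH
  clr <- config$covariate_log_hr
  lp_cov <- clr[["age"]] * (age - 46) + clr[["race_white"]] * (race == "White") +
    clr[["substance"]] * substance + config$era_log_hr[era_b]
  data.table::setorder(vis, row, day)
  vis[, nxt := data.table::shift(day, -1L), by = row]
  iv <- vis[!is.na(nxt)]
  if (nrow(iv) == 0L)
    stop("degenerate config: no patient has any follow-up interval")
  iv[, cur_statin := statin_user[row] &
       planned_overlap_days(st_ep$S, st_ep$E, row, day, 8L) > 0]
  iv[, art_pdc := planned_overlap_days(art_ep$S, art_ep$E, row, day, 91L) / 91]
  iv[, h := pmin(0.5, bd * exp(config$true_log_hr_statin * cur_statin +
                                 config$true_log_hr_adherence * (art_pdc - 1) +
                                 lp_cov[row]))]
  iv[, L := nxt - day]
  iv[, u := runif(.N)]
  iv[, off := ifelse(h > 0, ceiling(log(u) / log1p(-h)), Inf)]
  iv[, hit := off <= L]
  reb <- iv[hit == TRUE, .(rebound = day[1L] + off[1L]), by = row]
  rebound <- rep(NA_integer_, n)
  rebound[reb$row] <- as.integer(reb$rebound)

  ## ---- observed VLs: undetectable until rebound, detection at visits ----
  vdt <- vis[, .(row, day)]
  vdt[, post := !is.na(rebound[row]) & day >= rebound[row]]
  vdt[, vl := ifelse(post, round(10^runif(.N, log10(201), 5)), NA_real_)]
  vdt[, keep := {
    p <- which(post)
    if (length(p) == 0L) rep(TRUE, .N)
    else {
      cutk <- if (vl[p[1L]] > 1000) p[1L] else min(p[1L] + 1L, .N)
      seq_len(.N) <= cutk
    }
  }, by = row]
  vdt <- vdt[keep == TRUE]

  # never-suppressing patients: persistently detectable VLs, no baseline
  ns <- which(never_sup)
  if (length(ns)) {
    nsv <- data.table::data.table(
      row = rep(ns, each = 4L),
      day = rep(haart_start[ns], each = 4L) +
        rep(c(60L, 180L, 300L, 420L), length(ns)))
    nsv <- nsv[day <= lastday[row]]
    nsv[, `:=`(post = TRUE, vl = round(10^runif(.N, 3.2, 5.3)), keep = TRUE)]
    vdt <- rbind(vdt, nsv)
  }
  # delayed-follow-up patients: baseline plus undetectable visits >= 500 days
  if (length(nf)) {
    nfv <- data.table::data.table(
      row = rep(nf, each = 3L),
      day = rep(b[nf], each = 3L) + rep(c(0L, 520L, 700L), length(nf)))
    nfv <- nfv[day <= lastday[row]]
    nfv[, `:=`(post = FALSE, vl = NA_real_, keep = TRUE)]
    vdt <- rbind(vdt, nfv)
  }

  # pre-baseline detectable VL at HAART start (peak VL, meets the > 1000
  # inclusion criterion)
  pre <- data.table::data.table(row = seq_len(n), day = haart_start,
                                post = TRUE,
                                vl = round(10^runif(n, 4.2, 5.5)), keep = TRUE)
  pre <- pre[day <= lastday[row]]
  vdt <- rbind(pre, vdt)
  data.table::setorder(vdt, row, day)
  vdt <- unique(vdt, by = c("row", "day"))

  viral_loads <- vdt[, .(
    patient_id = pid[row],
    date = day_to_date(day),
    value = ifelse(post, vl, NA_real_),
    lloq = lloq_at(day),
    detectable = post)]

  obs_end <- vdt[, .(last = max(day)), by = row]
  obs_last <- rep(NA_integer_, n)
  obs_last[obs_end$row] <- as.integer(obs_end$last)
  fills_end <- pmin(se, ifelse(is.na(obs_last), haart_start + 60L,
                               obs_last + DAYS_13_MONTHS),
                    ifelse(is.na(death), se, death + 1L))

  ## ---- hospital stays ----
  yrs <- pmax(0, (pmin(lastday, fills_end) - haart_start) / 365.25)
  n_st <- rpois(n, config$hospitalization_rate_py * yrs)
  sidx <- rep(seq_len(n), n_st)
  stays <- data.table::data.table(row = sidx)
  if (nrow(stays)) {
    stays[, admit := haart_start[row] +
            floor(runif(.N) * pmax(1, lastday[row] - haart_start[row] - 15L))]
    stays[, dur := sample(3:14, .N, TRUE)]
    stays[, disch_excl := pmin(admit + dur, lastday[row] + 1L)]
    data.table::setorder(stays, row, admit)
    # keep a stay only if it starts at/after every earlier stay's discharge
    stays[, ok := admit >= data.table::shift(cummax(disch_excl), fill = 0L),
          by = row]
    stays <- stays[ok == TRUE & disch_excl > admit]
    stays[, patient_id := pid[row]]
  } else {
    stays <- data.table::data.table(row = integer(0), admit = integer(0),
                                    dur = integer(0), disch_excl = integer(0),
                                    ok = logical(0), patient_id = character(0))
  }
  stays_iv <- stays[, .(patient_id, admit, disch_excl)]

  ## ---- dispensing records ----
  ep_long <- function(S, E, who, drugs_by_row, start_floor) {
    idx <- which(who)
    if (!length(idx)) return(NULL)
    k <- ncol(S)
    epl <- data.table::data.table(
      row = rep(idx, each = k),
      s = as.integer(t(S[idx, , drop = FALSE])),
      e = as.integer(t(E[idx, , drop = FALSE])))
    epl[, e := pmin(e, fills_end[row])]
    epl <- epl[e > s]
    dr <- drugs_by_row[epl$row]
    nd <- lengths(dr)
    out <- epl[rep(seq_len(.N), nd)]
    out[, drug_code := unlist(dr)]
    out[, patient_id := pid[row]]
    out[, .(patient_id, drug_code, s, e)]
  }

  regimens <- list(
    c("zidovudine", "lamivudine", "indinavir"),
    c("tenofovir", "lamivudine", "lopinavir", "ritonavir"),
    c("tenofovir", "emtricitabine", "efavirenz"))
  art_drugs <- regimens[era_h]
  eps <- list(
    ep_long(art_ep$S, art_ep$E, rep(TRUE, n), art_drugs),
    ep_long(st_ep$S, st_ep$E, statin_user,
            as.list(statin_compound)))
  for (cl in names(cvm_ep)) {
    eps[[length(eps) + 1L]] <-
      ep_long(cvm_ep[[cl]]$S, cvm_ep[[cl]]$E, cvm_user[[cl]],
              as.list(rep(cvm_drug[[cl]], n)))
  }
  ep_all <- data.table::rbindlist(eps)
  fills <- episodes_to_fills(ep_all, stays_iv, as.integer(config$fill_max_days))
  data.table::setorder(fills, patient_id, drug_code, fill_date, setting)
  fills_out <- fills[, .(patient_id, drug_code,
                         fill_date = day_to_date(fill_date),
                         days_supply, setting)]

  ## ---- labs ----
  lab_rows <- list()
  cd4 <- vdt[, .(row, day)]
  cd4[, value := round(pmax(15, rnorm(.N, 340 + 2.5 * (day - haart_start[row]) /
                                        DAYS_PER_MONTH, 140)))]
  lab_rows$cd4 <- cd4[, .(patient_id = pid[row], date = day_to_date(day),
                          analyte = "CD4", value)]
  nlip <- pmax(1L, floor((fills_end - haart_start) / 365L))
  lrow <- rep(seq_len(n), nlip)
  lip <- data.table::data.table(row = lrow)
  lip[, date_d := haart_start[row] +
        round(runif(.N, 30, 360)) + (rowid(row) - 1L) * 365L]
  lip <- lip[date_d <= pmin(lastday[row], fills_end[row])]
  lip[, on_statin := statin_user[row] &
        planned_overlap_days(st_ep$S, st_ep$E, row, date_d, 8L) > 0]
  lip[, ldl := round(pmax(40, rnorm(.N, 115, 25) - 30 * on_statin))]
  lip[, nonhdl := ldl + round(pmax(5, rnorm(.N, 45, 12)))]
  lab_rows$ldl <- lip[, .(patient_id = pid[row], date = day_to_date(date_d),
                          analyte = "LDL", value = ldl)]
  lab_rows$nonhdl <- lip[, .(patient_id = pid[row], date = day_to_date(date_d),
                             analyte = "nonHDL", value = nonhdl)]
  labs <- data.table::rbindlist(lab_rows)
  data.table::setorder(labs, patient_id, date, analyte)

  ## ---- diagnosis-code events ----
  sub_idx <- which(substance)
  one_idx <- which(!substance & runif(n) < 0.10)
  icd <- data.table::data.table(
    row = c(rep(sub_idx, each = 2L), one_idx),
    code = sample(c("303.90", "304.20", "305.00"),
                  2L * length(sub_idx) + length(one_idx), TRUE))
  icd[, date_d := haart_start[row] - round(runif(.N, 30, 800))]
  icd[, date_d := pmax(date_d, ss)]
  icd_events <- icd[, .(patient_id = pid[row], date = day_to_date(date_d),
                        code)]
  data.table::setorder(icd_events, patient_id, date, code)

  ## ---- demographics ----
  demographics <- data.table::data.table(
    patient_id = pid,
    age_at_haart_start = age,
    race = race, gender = gender, hcv = hcv,
    haart_start = day_to_date(haart_start),
    hiv_dx_date = day_to_date(hiv_dx),
    death_date = day_to_date(death),
    pre_haart_arv_days = pre_arv)

  ## ---- hidden truth ----
  truth_patients <- data.table::data.table(
    patient_id = pid,
    statin_ever = statin_user,
    statin_start = day_to_date(ifelse(statin_user, statin_start, NA_integer_)),
    adherence = adh,
    true_rebound_day = day_to_date(rebound),
    baseline = day_to_date(ifelse(normal & b <= lastday, b, NA_integer_)),
    era = era_b)

  truth <- NULL
  if (keep_truth) {
    tp <- iv[, .(row, day, nxt, cur_statin, art_pdc, h)]
    tp[, stop_d := pmin(nxt, obs_last[row])]
    tp <- tp[stop_d > day]
    len <- tp$stop_d - tp$day
    ridx <- rep(seq_len(nrow(tp)), len)
    truth <- data.table::data.table(
      row = tp$row[ridx],
      day = tp$day[ridx] + sequence(len))
    truth[, true_current_statin := tp$cur_statin[ridx]]
    truth[, true_art_pdc := tp$art_pdc[ridx]]
    truth[, true_hazard := tp$h[ridx]]
    truth[, true_statin_exposed := statin_user[row] &
            planned_overlap_days(st_ep$S, st_ep$E, row, day, 1L) > 0]
    truth <- truth[, .(patient_id = pid[row], day = day_to_date(day),
                       true_statin_exposed, true_current_statin,
                       true_art_pdc, true_hazard)]
  }

  out <- list(fills = fills_out,
              stays = stays[, .(patient_id,
                                admit_date = day_to_date(admit),
                                discharge_date = day_to_date(disch_excl - 1L))],
              viral_loads = viral_loads,
              labs = labs,
              demographics = demographics,
              icd_events = icd_events,
              drug_classes = default_drug_class_map(),
              truth = truth,
              truth_patients = truth_patients,
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d fills, %d viral loads, %d stays\n",
              nrow(x$demographics), nrow(x$fills), nrow(x$viral_loads),
              nrow(x$stays)))
  invisible(x)
}

#' Write a synthetic cohort to delimited text files
#'
#' Emits `fills.csv`, `stays.csv`, `viral_loads.csv`, `labs.csv`,
#' `patients.csv`, `icd_events.csv`, `drug_classes.csv`, `truth.csv` and
#' `truth_patients.csv` into `dir`.
#'
#' @param sim a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fw <- function(x, f) if (!is.null(x))
    data.table::fwrite(x, file.path(dir, f))
  fw(sim$fills, "fills.csv")
  fw(sim$stays, "stays.csv")
  fw(sim$viral_loads, "viral_loads.csv")
  fw(sim$labs, "labs.csv")
  fw(sim$demographics, "patients.csv")
  fw(sim$icd_events, "icd_events.csv")
  fw(sim$drug_classes, "drug_classes.csv")
  fw(sim$truth, "truth.csv")
  fw(sim$truth_patients, "truth_patients.csv")
  invisible(dir)
}
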