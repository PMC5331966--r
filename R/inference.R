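#' Fit an era-stratified Cox model on counting-process rows
#'
#' Partial-likelihood fit on `(t_start, t_stop]` intervals with Efron tie
#' handling, stratified by suppression era. With weights, a robust sandwich
#' variance clustered on patient is used; unweighted fits use the model-based
#' variance.
#'
#' @param rows counting-process data from [assemble_counting_process()].
#' @param exposure name of the exposure column reported as the result.
#' @param covariates additional adjustment covariate names.
#' @param weights optional positive per-row weights.
#' @param strata_col stratification column, default `"era"`.
#' @return a `cox_result`: list with `hr`, `ci_low`, `ci_high`, `p`,
#'   `log_hr`, `se`, `n`, `n_events` for the exposure term, plus the full
#'   `fit`.
#' @export
fit_cox <- function(rows, exposure, covariates = character(),
                    weights = NULL, strata_col = "era") {
  rows <- data.table::as.data.table(rows)
  terms <- c(exposure, covariates, sprintf("strata(%s)", strata_col))
  f <- as.formula(paste("survival::Surv(t_start, t_stop, event) ~",
                        paste(terms, collapse = " + ")))
  dat <- data.table::copy(rows)
  if (!is.null(weights)) {
    dat[, .wt_ := weights]
    fit <- survival::coxph(f, data = dat, weights = .wt_,
                           cluster = patient_id, ties = "efron")
  } else {
    fit <- survival::coxph(f, data = dat, ties = "efron")
  }
  s <- summary(fit)
  cn <- rownames(s$coefficients)
  j <- which(startsWith(cn, exposure))[1L]
  if (is.na(j)) stop("exposure term '", exposure, "' absent from fit")
  beta <- s$coefficients[j, "coef"]
  se <- if ("robust se" %in% colnames(s$coefficients))
    s$coefficients[j, "robust se"] else s$coefficients[j, "se(coef)"]
  pcol <- colnames(s$coefficients)[ncol(s$coefficients)]
  res <- list(exposure = exposure,
              hr = exp(beta), ci_low = exp(beta - 1.96 * se),
              ci_high = exp(beta + 1.96 * se),
              p = s$coefficients[j, pcol],
              log_hr = beta, se = se,
              n = nrow(rows), n_events = sum(rows$event),
              fit = fit)
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("%s: HR %.3f (95%% CI %.3f-%.3f), p = %.3g [%d rows, %d events]\n",
              x$exposure, x$hr, x$ci_low, x$ci_high, x$p, x$n, x$n_events))
  invisible(x)
}

#' Screen candidate covariates by main-effect significance
#'
#' Fits a single main-effects, era-stratified Cox model with all candidates
#' and retains those significant at `alpha`; a factor is retained if any of
#' its levels is significant. One pass, no stepwise iteration; deterministic
#' given the input.
#'
#' @inheritParams fit_cox
#' @param candidates candidate covariate names present in `rows`.
#' @param alpha retention threshold, default 0.05.
#' @return character vector of retained covariate names.
#' @export
select_covariates <- function(rows, candidates, alpha = 0.05,
                              strata_col = "era") {
  if (length(candidates) == 0L) return(character(0))
  f <- as.formula(paste("survival::Surv(t_start, t_stop, event) ~",
                        paste(c(candidates, sprintf("strata(%s)", strata_col)),
                              collapse = " + ")))
  fit <- tryCatch(survival::coxph(f, data = rows, ties = "efron"),
                  error = function(e)
                    stop("covariate screening failed to converge for {",
                         paste(candidates, collapse = ", "), "}: ",
                         conditionMessage(e)))
  s <- summary(fit)$coefficients
  pcol <- colnames(s)[ncol(s)]
  keep <- vapply(candidates, function(cv) {
    rows_cv <- startsWith(rownames(s), cv)
    isTRUE(any(s[rows_cv, pcol] < alpha, na.rm = TRUE))
  }, logical(1))
  candidates[keep]
}

#' Proportional-hazards diagnostics
#'
#' Scaled Schoenfeld residual tests per model term. Reporting only; no
#' automatic model modification.
#'
#' @param fit a `cox_result` or `coxph` fit.
#' @return data.frame with one row per term: `chisq`, `df`, `p`.
#' @export
check_proportionality <- function(fit) {
  if (inherits(fit, "cox_result")) fit <- fit$fit
  z <- survival::cox.zph(fit)
  as.data.frame(z$table)
}

#' Propensity model for current use or premature censoring
#'
#' Log-link binomial GLM for the per-interval probability of the outcome
#' state, optionally including follow-up time as a covariate. If the log-link
#' binomial fit fails to converge, a log-link Poisson working model is used
#' instead (with a notice). Fitted probabilities are clipped away from 0
#' and 1.
#'
#' @inheritParams fit_cox
#' @param outcome name of a binary (logical) column in `rows`.
#' @param covariates covariate names for the linear predictor.
#' @param include_time add follow-up time (years since baseline) to the
#'   linear predictor, default TRUE.
#' @return list with `prob` (per-row fitted probability), `family_used`,
#'   `n_clipped`, `fit`.
#' @export
fit_propensity <- function(rows, outcome, covariates,
                           include_time = TRUE) {
  rhs <- c(covariates, if (include_time) "I(t_start/365.25)")
  if (length(rhs) == 0L) rhs <- "1"
  f <- as.formula(paste(outcome, "~", paste(rhs, collapse = " + ")))
  y <- as.numeric(rows[[outcome]])
  X <- stats::model.matrix(f, data = rows)
  st <- c(log(max(mean(y), 1e-6)), rep(0, ncol(X) - 1L))
  fit <- tryCatch({
    withCallingHandlers(
      glm(f, data = rows, family = binomial(link = "log"), start = st),
      warning = function(w) invokeRestart("muffleWarning"))
  }, error = function(e) NULL)
  family_used <- "binomial_log"
  if (is.null(fit) || !fit$converged) {
    message("log-link binomial did not converge; using log-link Poisson working model")
    fit <- withCallingHandlers(
      glm(f, data = rows, family = poisson(link = "log")),
      warning = function(w) invokeRestart("muffleWarning"))
    family_used <- "poisson_log"
  }
  p <- as.numeric(stats::predict(fit, type = "response"))
  n_clipped <- sum(p >= 1 - 1e-6 | p <= 1e-6)
  if (n_clipped > 0L)
    warning(sprintf("%d fitted probabilities clipped away from {0,1}", n_clipped))
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  list(prob = p, family_used = family_used, n_clipped = n_clipped, fit = fit)
}

#' Stabilized inverse-probability weights
#'
#' Per-interval weights: `incidence/prob` for rows observed in the indexed
#' state and `(1 - incidence)/(1 - prob)` otherwise, where `incidence` is the
#' marginal probability of the state (the stabilizing numerator).
#'
#' @param prob fitted per-row probability of the state, in (0, 1).
#' @param observed logical: the row's observed state.
#' @param incidence marginal probability of the state; default
#'   `mean(observed)`.
#' @return positive numeric weights.
#' @export
stabilized_weights <- function(prob, observed, incidence = mean(observed)) {
  if (any(prob <= 0 | prob >= 1)) stop("probabilities must lie strictly in (0, 1)")
  ifelse(observed, incidence / prob, (1 - incidence) / (1 - prob))
}

#' Truncate weights at symmetric percentile bounds
#'
#' Weights below the p-th percentile are raised to it and weights above the
#' (100 - p)-th percentile lowered to it. Percentiles use linear
#' interpolation between order statistics (`quantile` type 7), computed over
#' all person-interval weights.
#'
#' @param weights positive numeric weights.
#' @param percentile truncation level in percent (conventionally 5, 1 or 0.1).
#' @return truncated weights.
#' @export
truncate_weights <- function(weights, percentile) {
  stopifnot(all(weights > 0), percentile > 0, percentile < 50)
  bounds <- quantile(weights, c(percentile / 100, 1 - percentile / 100),
                     type = 7, names = FALSE)
  pmin(pmax(weights, bounds[1L]), bounds[2L])
}

default_candidate_covariates <- function(rows) {
  intersect(c("age_baseline", "race", "gender", "hcv", "substance_abuse",
              "art_pdc", "cd4", "ldl_equiv", "peak_log_vl",
              "months_dx_to_supp", "pre_haart_arv_days",
              "arv_class_experience", "anchor_category",
              "nrti_tenofovir", "nrti_3tc_ftc", "nrti_other"),
            names(rows))
}

#' Format an analysis grid as a plain-text report
#'
#' Lays the grid out with exposure mode and adjustment as rows and
#' medication classes as columns, each cell `HR (low-high)` with its
#' p-value, mirroring the conventional presentation of such analyses.
#'
#' @param grid output of [run_analysis_grid()].
#' @return character vector of report lines.
#' @export
format_grid_report <- function(grid) {
  g <- data.table::as.data.table(grid)
  g[, cell := ifelse(is.na(hr), "-",
                     sprintf("%.2f (%.2f-%.2f) p=%.3g", hr, ci_low, ci_high, p))]
  wide <- data.table::dcast(g, mode + adjustment ~ class, value.var = "cell")
  hdr <- sprintf("Hazard ratios (95%% CI); %d rows, %d events",
                 g$n[1L], g$n_events[1L])
  c(hdr, strrep("-", nchar(hdr)),
    utils::capture.output(print(as.data.frame(wide), row.names = FALSE)))
}

#' Run the full exposure-mode x adjustment analysis grid
#'
#' For each medication class and exposure mode (PDC, current use, categorical
#' ever-use) fits the unadjusted and multivariate-adjusted era-stratified Cox
#' model; for the current-use mode additionally fits Cox models weighted by
#' combined stabilized inverse-probability-of-treatment-and-censoring
#' weights, truncated at each requested percentile level. Covariate selection
#' (one significance screen on the candidate set) is shared across cells;
#' propensity models use the retained covariates with time-updated age.
#' Errors in individual cells are recorded without aborting the grid.
#'
#' @inheritParams fit_cox
#' @param classes column prefixes of the medication classes in `rows`.
#' @param modes exposure modes to fit.
#' @param adjustments adjustments to fit (`"none"`, `"mva"`, `"ipw"`).
#' @param truncation_levels IPW truncation percentiles.
#' @param candidates candidate adjustment covariates; default all available.
#' @param alpha covariate retention threshold.
#' @return data.table with one row per grid cell: `class`, `mode`,
#'   `adjustment`, `hr`, `ci_low`, `ci_high`, `p`, `n`, `n_events`, `note`.
#' @export
run_analysis_grid <- function(rows,
                              classes = c("statin", "alp", "aht", "asa"),
                              modes = c("pdc", "current", "categorical"),
                              adjustments = c("none", "mva", "ipw"),
                              truncation_levels = c(5, 1, 0.1),
                              candidates = NULL, alpha = 0.05) {
  rows <- data.table::as.data.table(rows)
  if (is.null(candidates)) candidates <- default_candidate_covariates(rows)
  retained <- select_covariates(rows, candidates, alpha = alpha)
  prop_covs <- union(setdiff(retained, "age_baseline"),
                     intersect("age_current", names(rows)))

  # Censoring weights are shared across classes.
  w_cens <- NULL
  if ("ipw" %in% adjustments && "censor_next" %in% names(rows)) {
    pc <- fit_propensity(rows, "censor_next", prop_covs)
    w_cens <- stabilized_weights(pc$prob, rows$censor_next)
  }

  mode_col <- c(pdc = "_pdc", current = "_current", categorical = "_ever")
  out <- list()
  add <- function(cls, mode, adj, res, note = NA_character_) {
    out[[length(out) + 1L]] <<- data.table::data.table(
      class = cls, mode = mode, adjustment = adj,
      hr = res$hr %||% NA_real_, ci_low = res$ci_low %||% NA_real_,
      ci_high = res$ci_high %||% NA_real_, p = res$p %||% NA_real_,
      n = res$n %||% nrow(rows), n_events = res$n_events %||% NA_integer_,
      note = note)
  }
  safely <- function(cls, mode, adj, expr) {
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) add(cls, mode, adj, list(),
                                    note = conditionMessage(res))
    else add(cls, mode, adj, res)
  }

  for (cls in classes) {
    for (mode in modes) {
      expo <- paste0(cls, mode_col[[mode]])
      if (!expo %in% names(rows)) next
      if ("none" %in% adjustments)
        safely(cls, mode, "none", fit_cox(rows, expo))
      if ("mva" %in% adjustments)
        safely(cls, mode, "mva", fit_cox(rows, expo, covariates = retained))
      if ("ipw" %in% adjustments && mode == "current") {
        wt <- tryCatch({
          pt <- fit_propensity(rows, expo, prop_covs)
          w <- stabilized_weights(pt$prob, rows[[expo]])
          if (!is.null(w_cens)) w * w_cens else w
        }, error = function(e) e)
        for (lev in truncation_levels) {
          adj <- paste0("ipw@", lev)
          if (inherits(wt, "error"))
            add(cls, mode, adj, list(), note = conditionMessage(wt))
          else
            safely(cls, mode, adj,
                   fit_cox(rows, expo, weights = truncate_weights(wt, lev)))
        }
      }
    }
  }
  data.table::rbindlist(out)
}
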