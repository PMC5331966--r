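#' Read pipeline input tables
#'
#' Readers for the delimited-text interfaces consumed by the pipeline stages:
#' dispensing records, hospital stays, viral loads, patient demographics,
#' labs and diagnosis events. Dates are ISO-8601 in the files and converted
#' to the internal integer day grid where needed.
#'
#' @param path CSV file path.
#' @return a data.table.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_fills <- function(path) data.table::fread(path)

#' @rdname pipeline_io
#' @export
read_stays <- function(path) data.table::fread(path)

#' @rdname pipeline_io
#' @export
read_viral_loads <- function(path) {
  vl <- data.table::fread(path)
  vl[, detectable := as.logical(detectable)]
  vl[]
}

#' @rdname pipeline_io
#' @export
read_patients <- function(path) data.table::fread(path)

#' Pipeline configuration
#'
#' Assembles a validated pipeline configuration: either pointing at existing
#' input tables (`input_dir`) or at a simulation block to generate them.
#'
#' @param input_dir directory with input CSVs (fills, stays, viral_loads,
#'   labs, patients, icd_events, drug_classes), or `NULL` to simulate.
#' @param sim a [sim_config()] used when `input_dir` is `NULL`.
#' @param out_dir directory for stage outputs; `NULL` keeps results in
#'   memory only.
#' @param endpoint `"primary"` or `"combined"`.
#' @param cohort `"main"` or `"sensitivity"`.
#' @param truncation_levels IPW truncation percentiles.
#' @param substance_codes diagnosis codes counted as substance abuse.
#' @param seed integer seed propagated to every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir = NULL, sim = NULL, out_dir = NULL,
                            endpoint = c("primary", "combined"),
                            cohort = c("main", "sensitivity"),
                            truncation_levels = c(5, 1, 0.1),
                            substance_codes = c("303.90", "304.20", "305.00"),
                            seed = 1L) {
  endpoint <- match.arg(endpoint)
  cohort <- match.arg(cohort)
  if (is.null(input_dir) && is.null(sim))
    stop("either input_dir or a sim config block is required")
  cfg <- list(input_dir = input_dir, sim = sim, out_dir = out_dir,
              endpoint = endpoint, cohort = cohort,
              truncation_levels = truncation_levels,
              substance_codes = substance_codes, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' The YAML may contain the [pipeline_config()] keys plus a nested `sim`
#' block of [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  simcfg <- NULL
  if (!is.null(y$sim)) {
    if (!is.null(seed)) y$sim$seed <- seed
    simcfg <- do.call(sim_config, y$sim)
  }
  pipeline_config(input_dir = y$input_dir, sim = simcfg,
                  out_dir = y$out_dir,
                  endpoint = y$endpoint %||% "primary",
                  cohort = y$cohort %||% "main",
                  truncation_levels = unlist(y$truncation_levels) %||% c(5, 1, 0.1),
                  substance_codes = unlist(y$substance_codes) %||%
                    c("303.90", "304.20", "305.00"),
                  seed = seed %||% (y$seed %||% 1L))
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim, keep_truth = FALSE)
    list(fills = sim$fills, stays = sim$stays,
         viral_loads = sim$viral_loads, labs = sim$labs,
         patients = sim$demographics, icd_events = sim$icd_events,
         drug_classes = sim$drug_classes)
  } else {
    d <- config$input_dir
    need <- function(f) {
      p <- file.path(d, f)
      if (!file.exists(p)) stop("stage input missing: ", p)
      data.table::fread(p)
    }
    opt <- function(f, ...) {
      p <- file.path(d, f)
      if (file.exists(p)) data.table::fread(p, ...) else NULL
    }
    list(fills = need("fills.csv"), stays = opt("stays.csv"),
         viral_loads = need("viral_loads.csv"), labs = opt("labs.csv"),
         patients = need("patients.csv"),
         # diagnosis codes must stay character ("303.90" is not 303.9)
         icd_events = opt("icd_events.csv",
                          colClasses = list(character = "code")),
         drug_classes = opt("drug_classes.csv") %||% default_drug_class_map())
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> build exposure calendars -> build
#' cohort -> assemble counting-process rows -> fit the analysis grid, with a
#' run manifest recording seeds, row counts and exclusion tallies. Reruns
#' with the same configuration are byte-identical.
#'
#' @param config a [pipeline_config()] (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @return list with `results` (the analysis grid), `rows` (counting-process
#'   data), `cohort`, `calendar` and `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$sim)) config$sim$seed <- config$seed
  set.seed(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  inputs <- stage("simulate/load", load_pipeline_inputs(config))
  vls <- data.table::as.data.table(inputs$viral_loads)
  vls[, date := as_day(date)]
  vls[, detectable := as.logical(detectable)]

  calendar <- stage("build-exposure",
                    build_exposure_calendar(inputs$fills, inputs$stays,
                                            inputs$drug_classes))
  cohort <- stage("build-cohort",
                  build_cohort(vls, inputs$patients,
                               endpoint = config$endpoint))
  entries <- if (config$cohort == "sensitivity") {
    sc <- sensitivity_cohort(cohort)
    sc[, included := included & sensitivity_eligible]
    sc
  } else cohort

  rows <- stage("assemble",
                assemble_counting_process(
                  entries, calendar, vls, inputs$patients,
                  labs = inputs$labs, icd_events = inputs$icd_events,
                  substance_codes = config$substance_codes))
  results <- stage("analyze",
                   run_analysis_grid(rows,
                                     truncation_levels = config$truncation_levels))

  manifest <- list(
    package_version = as.character(packageVersion("hivrebound")),
    seed = config$seed,
    endpoint = config$endpoint,
    cohort = config$cohort,
    n_patients = nrow(inputs$patients),
    n_fills = nrow(inputs$fills),
    n_viral_loads = nrow(vls),
    n_included = sum(entries$included, na.rm = TRUE),
    exclusions = as.list(table(cohort$exclusion_reason[!cohort$included])),
    n_rows = nrow(rows),
    n_events = sum(rows$event))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_exposure_csv(calendar, file.path(config$out_dir, "exposure.csv"))
    data.table::fwrite(cohort, file.path(config$out_dir, "cohort.csv"))
    data.table::fwrite(cohort[included != TRUE,
                              .(patient_id, exclusion_reason)],
                       file.path(config$out_dir, "exclusions.csv"))
    data.table::fwrite(rows, file.path(config$out_dir, "analysis_rows.csv"))
    data.table::fwrite(results, file.path(config$out_dir, "results_grid.csv"))
    writeLines(format_grid_report(results),
               file.path(config$out_dir, "report.txt"))
    yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  }

  list(results = results, rows = rows, cohort = cohort,
       calendar = calendar, manifest = manifest)
}
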