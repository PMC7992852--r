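# Pipeline orchestration: simulate or ingest -> score -> describe -> mediate,
# with deterministic outputs and a config hash carried on every file.

#' Configure a full pipeline run
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"csv"` (read a
#'   long-format file from `input`).
#' @param cohort [cohort_config()] used in simulate mode.
#' @param input CSV path in csv mode.
#' @param outcomes Outcome columns to analyse (closed list).
#' @param mediators `"asi12"`, `"asi6"` or both.
#' @param waves Follow-up waves to analyse.
#' @param covariates Covariate convention, see [mediation_spec()].
#' @param boot Bootstrap replicates per analysis.
#' @param conf Confidence level.
#' @param missing Missing-data strategy for point estimates.
#' @param seed Master seed: drives simulation and every bootstrap.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "csv"),
                       cohort = cohort_config(),
                       input = NULL,
                       outcomes = c("dass_depression", "dass_anxiety",
                                    "dass_stress", "qol_physical",
                                    "qol_mental", "energy_fatigue"),
                       mediators = "asi12",
                       waves = c(3, 6),
                       covariates = "footnote",
                       boot = 1000, conf = 0.95,
                       missing = c("fiml", "complete"),
                       seed = 1L) {
  mode <- match.arg(mode)
  missing <- match.arg(missing)
  bad <- setdiff(outcomes, .outcomes)
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))
  if (!all(mediators %in% c("asi12", "asi6"))) {
    stop("mediators must be drawn from asi12, asi6")
  }
  if (mode == "csv" && is.null(input)) stop("csv mode needs an input path")
  structure(list(mode = mode, cohort = cohort, input = input,
                 outcomes = outcomes, mediators = mediators, waves = waves,
                 covariates = covariates, boot = boot, conf = conf,
                 missing = missing, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the cohort, freezes pooled rescaling bounds, scores
#' the ASI, produces descriptive and completer tables, and fits one mediation
#' analysis per outcome x wave x mediator with BC bootstrap intervals. All
#' randomness is derived from `config$seed`, so a repeated run is
#' byte-identical.
#'
#' @param config A [run_config()].
#' @param quiet Suppress stage-progress messages.
#' @return A list of class `run_bundle`: `data` (scored long data), `bounds`,
#'   `descriptives`, `completers`, `mediation` (one row per analysis),
#'   `metadata` (seed, config hash, package version).
#' @export
run_pipeline <- function(config = run_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  if (config$mode == "simulate") {
    cfg <- config$cohort
    cfg$seed <- config$seed
    data <- simulate_cohort(cfg)
    say("simulated ", length(unique(data$id)), " participants (",
        sum(data$observed), " observed participant-waves)")
  } else {
    data <- read_cohort_csv(config$input)
    say("read ", length(unique(data$id)), " participants from ", config$input)
  }

  bounds <- compute_bounds(data)
  scored <- score_asi(data, bounds)
  say("scored ASI for ", sum(!is.na(scored$asi12)), " participant-waves")

  desc <- asi_descriptives(scored)
  baseline <- baseline_characteristics(scored)
  completers <- tryCatch(compare_completers(scored),
                         error = function(e) NULL)

  rows <- list()
  for (med in config$mediators) {
    for (out in config$outcomes) {
      for (w in config$waves) {
        spec <- mediation_spec(outcome = out, mediator = med, wave = w,
                               covariates = config$covariates,
                               boot = config$boot, conf = config$conf,
                               missing = config$missing)
        seed_w <- (config$seed * 1000L +
                     match(out, .outcomes) * 10L + w) %% .Machine$integer.max
        fit <- mediate(scored, spec, seed = seed_w)
        rows[[paste(med, out, w)]] <- tibble::tibble(
          mediator = med, outcome = out, wave = w,
          a = fit$a, se_a = fit$se_a, b = fit$b, se_b = fit$se_b,
          direct = fit$c_prime, se_direct = fit$se_cprime,
          c = fit$c_total, se_c = fit$se_c,
          ab = fit$ab, se_ab = fit$se_ab,
          ab_lower = fit$ci[1], ab_upper = fit$ci[2],
          prop_mediated = fit$prop_mediated,
          interaction_p = fit$interaction$p_value,
          n = unname(fit$n["b"]))
        say("mediation: ", out, " via ", med, " at ", w, " months")
      }
    }
  }
  mediation_tbl <- dplyr::bind_rows(rows)

  bundle <- list(
    data = scored, bounds = bounds, descriptives = desc,
    baseline = baseline, completers = completers, mediation = mediation_tbl,
    metadata = list(seed = config$seed,
                    config_hash = rlang::hash(unclass(config)),
                    package_version = as.character(utils::packageVersion("asimed")))
  )
  class(bundle) <- "run_bundle"
  bundle
}

# canonical long-format columns (see the data dictionary resource)
.csv_required <- c("id", "trial", "study", "group", "sex", "age", "wave",
                   "observed")

#' Read a long-format cohort CSV
#'
#' One row per participant-wave, columns per the package data dictionary
#' (`system.file("extdata", "data_dictionary.csv", package = "asimed")`);
#' missing values as empty fields. Errors on an empty file, missing required
#' columns, or duplicated participant-wave keys.
#'
#' @param path CSV file.
#' @return Long tibble.
#' @export
read_cohort_csv <- function(path) {
  if (!file.size(path) > 0) stop("empty file: ", path)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!nrow(data)) stop("no data rows in ", path)
  miss <- setdiff(.csv_required, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  key <- paste(data$id, data$wave)
  if (anyDuplicated(key)) {
    stop("duplicated participant-wave key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  data
}

#' Write a cohort to CSV
#'
#' Missing values are written as empty fields; a write-then-read round trip
#' reproduces all values to full precision.
#'
#' @param data Long cohort tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Write a pipeline result bundle to disk
#'
#' Writes the scored dataset (`scored.csv`), bounds sidecar (`bounds.json`),
#' descriptive and mediation tables (CSV), and a machine-readable
#' `results.json` carrying the run metadata (seed, config hash, package
#' version).
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort_csv(bundle$data, file.path(dir, "scored.csv"))
  write_bounds_json(bundle$bounds, file.path(dir, "bounds.json"))
  readr::write_csv(bundle$descriptives, file.path(dir, "descriptives.csv"), na = "")
  readr::write_csv(bundle$baseline, file.path(dir, "baseline.csv"), na = "")
  readr::write_csv(bundle$mediation, file.path(dir, "mediation.csv"), na = "")
  if (!is.null(bundle$completers)) {
    readr::write_csv(bundle$completers, file.path(dir, "completers.csv"), na = "")
  }
  jsonlite::write_json(
    list(metadata = bundle$metadata,
         mediation = bundle$mediation,
         completion = as.list(attr(bundle$completers, "completion"))),
    file.path(dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Table-shaped text rendering of a mediation table
#'
#' Formats the pipeline's mediation rows in the conventional published
#' layout: `A (SE)  B (SE)  Direct (SE)  C (SE)  AB [95% CI]  % mediated`.
#'
#' @param mediation_tbl The `mediation` element of a [run_pipeline()] bundle.
#' @return Character vector of formatted lines, invisibly; printed as a side
#'   effect.
#' @export
format_mediation_table <- function(mediation_tbl) {
  lines <- c(sprintf("%-16s %4s  %-14s %-14s %-14s %-14s %-22s %s",
                     "outcome", "wave", "A (SE)", "B (SE)", "Direct (SE)",
                     "C (SE)", "AB [95% CI]", "% med"))
  fmt <- function(x, se) sprintf("%6.2f (%.2f)", x, se)
  for (i in seq_len(nrow(mediation_tbl))) {
    r <- mediation_tbl[i, ]
    lines <- c(lines, sprintf(
      "%-16s %4d  %-14s %-14s %-14s %-14s %6.2f [%6.2f,%6.2f]  %s",
      r$outcome, r$wave, fmt(r$a, r$se_a), fmt(r$b, r$se_b),
      fmt(r$direct, r$se_direct), fmt(r$c, r$se_c),
      r$ab, r$ab_lower, r$ab_upper,
      ifelse(is.na(r$prop_mediated), "-", format_percent(r$prop_mediated))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
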