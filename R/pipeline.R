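#' Configuration of an end-to-end localization run
#'
#' Bundles every tunable of the pipeline. Inputs are either in-memory
#' tibbles (or a [simulation_params()] object to simulate them) or file
#' paths understood by the readers in this package. Thresholds may be
#' calibrated from the reference panel or injected directly via
#' `threshold_override` (e.g. the published borders 0.766 and 1.42) in
#' which case no panel is required.
#'
#' @param simulation optional [simulation_params()]; when given,
#'   transitions/annotations/panel are generated.
#' @param transitions transition tibble or TSV path (ignored when
#'   simulating).
#' @param annotations annotation tibble or TSV path.
#' @param panel reference-panel tibble or TSV path.
#' @param criteria a [selection_criteria()] object.
#' @param sequences optional named character vector or FASTA path.
#' @param tm_intervals optional tibble (`accession`, `start`, `end`).
#' @param fit_scale `"raw"` or `"log"` density-fit scale (see
#'   [fit_group()]).
#' @param both_moments optional published both-group moments
#'   (`list(mean =, variance =, n =)`) used when the panel's both group
#'   has no measured members.
#' @param threshold_override optional `c(lower, upper)` to skip
#'   calibration.
#' @param var_equal pooled Student (TRUE) or Welch t-test.
#' @param average roll-up averaging, `"arithmetic"` or `"geometric"`.
#' @param bonferroni_m optional fixed Bonferroni denominator.
#' @param seed integer seed governing all randomness of the run.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, transitions = NULL,
                            annotations = NULL, panel = NULL,
                            criteria = selection_criteria(),
                            sequences = NULL, tm_intervals = NULL,
                            fit_scale = c("raw", "log"), both_moments = NULL,
                            threshold_override = NULL, var_equal = TRUE,
                            average = "arithmetic", bonferroni_m = NULL,
                            seed = 1) {
  fit_scale <- match.arg(fit_scale)
  if (!is.null(threshold_override)) {
    assert_that(length(threshold_override) == 2 &&
                  0 < threshold_override[1] &&
                  threshold_override[1] < threshold_override[2],
                "`threshold_override` must satisfy 0 < lower < upper")
  }
  assert_that(!is.null(simulation) || !is.null(transitions),
              "either `simulation` or `transitions` must be provided")
  structure(list(
    simulation = simulation, transitions = transitions,
    annotations = annotations, panel = panel, criteria = criteria,
    sequences = sequences, tm_intervals = tm_intervals,
    fit_scale = fit_scale, both_moments = both_moments,
    threshold_override = threshold_override, var_equal = var_equal,
    average = average, bonferroni_m = bonferroni_m, seed = seed
  ), class = "pipeline_config")
}

.resolve_input <- function(x, reader) {
  if (is.null(x) || !is.character(x) || length(x) != 1) return(x)
  reader(x)
}

#' Run the full localization pipeline
#'
#' Stages, in order: (1) obtain or simulate the transition table,
#' (2) quantification roll-up with peptide selection and transition
#' normalization, (3) per-protein B/A ratios over paired animals,
#' (4) threshold calibration from the reference panel (or the supplied
#' override), (5) membrane-keyword filtering, classification and
#' per-protein significance, (6) category summary. Deterministic given
#' the config (all randomness flows from `config$seed`). When `out_dir`
#' is given, results, a JSON config snapshot, and the package version are
#' written there as plain text.
#'
#' @param config a [pipeline_config()] object.
#' @param out_dir optional output directory (created if missing).
#' @return object of class `swathloc_run`: list with `quant`, `ratios`,
#'   `calibration` (NULL when overridden), `thresholds`, `calls`,
#'   `category_summary`, `simulation` (when simulated), `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "`config` must come from pipeline_config()")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sim <- NULL
  if (!is.null(config$simulation)) {
    params <- config$simulation
    params$seed <- config$seed
    sim <- stage("simulate", generate_dataset(params))
    transitions <- sim$transitions
    annotations <- sim$annotations
    panel <- sim$panel
  } else {
    transitions <- .resolve_input(config$transitions, read_transition_table)
    annotations <- .resolve_input(config$annotations, read_annotation_table)
    panel <- .resolve_input(config$panel, read_reference_panel)
  }
  sequences <- .resolve_input(config$sequences, read_fasta)

  quant <- stage("quantify", quantify_transitions(
    transitions, criteria = config$criteria, sequences = sequences,
    tm_intervals = config$tm_intervals, average = config$average))
  ratios <- stage("ratios", compute_ba_ratios(quant))

  calibration <- NULL
  if (is.null(config$threshold_override)) {
    assert_that(!is.null(panel),
                "no reference panel and no threshold override given")
    calibration <- stage("calibrate", calibrate(
      ratios, panel, scale = config$fit_scale,
      both_moments = config$both_moments, var_equal = config$var_equal))
    thresholds <- calibration$thresholds
    both <- if (!is.null(calibration$fits$both$values)) {
      calibration$fits$both$values
    } else {
      config$both_moments
    }
  } else {
    thresholds <- ba_thresholds(config$threshold_override[1],
                                config$threshold_override[2])
    both <- config$both_moments %||% both_group_moments()
  }

  calls <- stage("classify", build_call_table(
    ratios, annotations, thresholds, both, m = config$bonferroni_m,
    var_equal = config$var_equal))
  summary <- stage("summarize", summarize_categories(calls))

  run <- structure(list(
    quant = quant, ratios = ratios, calibration = calibration,
    thresholds = thresholds, calls = calls, category_summary = summary,
    simulation = sim, config = config
  ), class = "swathloc_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write a pipeline run to a directory
#'
#' Emits protein quant, ratio, call and summary TSVs, a calibration
#' report, a JSON snapshot of the configuration, and the package version,
#' so any run can be reproduced from its output directory alone.
#'
#' @param run a `swathloc_run` object.
#' @param out_dir target directory.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(run$quant$proteins, p("protein_quant.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$quant$rejected_peptides, p("rejected_peptides.tsv"),
                   progress = FALSE)
  ratios_flat <- select(run$ratios, -"ratios")
  readr::write_tsv(ratios_flat, p("ba_ratios.tsv"), progress = FALSE)
  write_call_table(run$calls, p("calls.tsv"))
  readr::write_tsv(run$category_summary, p("category_summary.tsv"),
                   progress = FALSE)
  if (!is.null(run$calibration)) {
    con <- file(p("calibration_report.txt"), "w")
    sink(con); print(run$calibration); sink()
    close(con)
    readr::write_tsv(run$calibration$ks, p("calibration_ks.tsv"),
                     progress = FALSE)
    readr::write_tsv(run$calibration$model_tests,
                     p("calibration_model_tests.tsv"), progress = FALSE)
  }
  snapshot <- run$config
  snapshot$transitions <- if (is.character(snapshot$transitions)) {
    snapshot$transitions
  } else if (!is.null(snapshot$transitions)) "<in-memory>" else NULL
  for (f in c("annotations", "panel", "sequences")) {
    if (!is.null(snapshot[[f]]) && !is.character(snapshot[[f]])) {
      snapshot[[f]] <- "<in-memory>"
    }
  }
  snapshot$thresholds <- unclass(run$thresholds)
  snapshot$package_version <- as.character(utils::packageVersion("swathloc"))
  jsonlite::write_json(snapshot, p("config_snapshot.json"),
                       auto_unbox = TRUE, force = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(out_dir)
}

#' @export
print.swathloc_run <- function(x, ...) {
  cat("<swathloc_run>\n")
  cat(sprintf("  quantified proteins: %d\n",
              n_distinct(x$quant$proteins$accession)))
  cat(sprintf("  proteins with B/A ratios: %d\n", nrow(x$ratios)))
  cat(sprintf("  borders: lower = %.4g, upper = %.4g%s\n",
              x$thresholds$lower, x$thresholds$upper,
              if (is.null(x$calibration)) " (override)" else " (calibrated)"))
  cls <- table(factor(x$calls$class, c("apical", "both", "basolateral")))
  cat(sprintf("  calls: %d apical / %d both / %d basolateral (%d excluded)\n",
              cls[["apical"]], cls[["both"]], cls[["basolateral"]],
              nrow(attr(x$calls, "excluded"))))
  invisible(x)
}
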