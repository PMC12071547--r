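#' Pipeline configuration
#'
#' Bundles the four configuration sections: `simulation`
#' ([simulation_config()]), `analysis` (`smoothing_window`,
#' `max_maneuvers`, `unit_of_analysis`), `rule` ([cutoff_rule()]) and
#' `output` (`directory`, `figures`, `verbose`). Unknown keys in a section
#' are rejected.
#'
#' @param simulation A [simulation_config()].
#' @param analysis List with `smoothing_window` (odd, default 3),
#'   `max_maneuvers` (default 6), `unit_of_analysis`
#'   (`"patient"`/`"maneuver"`).
#' @param rule A [cutoff_rule()].
#' @param output List with `directory`, `figures` (logical), `verbose`.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            analysis = list(),
                            rule = cutoff_rule(),
                            output = list()) {
  analysis_defaults <- list(smoothing_window = 3, max_maneuvers = 6,
                            unit_of_analysis = "patient")
  output_defaults <- list(directory = ".", figures = TRUE, verbose = TRUE)
  check_keys <- function(given, defaults, section) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown %s config key(s): %s", section,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    utils::modifyList(defaults, given)
  }
  analysis <- check_keys(analysis, analysis_defaults, "analysis")
  output <- check_keys(output, output_defaults, "output")
  stopifnot(analysis$smoothing_window >= 1,
            analysis$smoothing_window %% 2 == 1,
            analysis$max_maneuvers >= 1)
  if (!analysis$unit_of_analysis %in% c("patient", "maneuver")) {
    stop("unit_of_analysis must be 'patient' or 'maneuver'", call. = FALSE)
  }
  validate_simulation_config(simulation)
  stopifnot(inherits(rule, "cutoff_rule"))
  structure(list(simulation = simulation, analysis = analysis,
                 rule = rule, output = output),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Recognized top-level sections: `simulation`, `analysis`, `rule`,
#' `output`; each validated by [pipeline_config()]. Scalar fields override
#' the package defaults.
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config file must be .yaml, .yml or .json", call. = FALSE)
  }
  unknown <- setdiff(names(raw), c("simulation", "analysis", "rule", "output"))
  if (length(unknown)) {
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sim_args <- raw$simulation %||% list()
  sim_known <- names(formals(simulation_config))
  bad <- setdiff(names(sim_args), sim_known)
  if (length(bad)) {
    stop(sprintf("unknown simulation key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (p in c("prior_a", "prior_b")) {
    if (!is.null(sim_args[[p]])) {
      sim_args[[p]] <- do.call(phenotype_prior, sim_args[[p]])
    }
  }
  rule_args <- raw$rule %||% list()
  pipeline_config(
    simulation = do.call(simulation_config, sim_args),
    analysis = raw$analysis %||% list(),
    rule = do.call(cutoff_rule, rule_args),
    output = raw$output %||% list()
  )
}

#' Full cohort report: group comparison, cut-off accuracy, constipation
#'
#' Runs the complete analysis over computed patient summaries: the
#' nine-row group-comparison table, diagnostic accuracy of the cut-off
#' rule with exact confidence intervals, the threshold sweep, and the
#' constipation chi-square comparison. When truth labels are absent the
#' accuracy and comparison sections are omitted with a notice.
#'
#' @param metrics Result of [cohort_metrics()].
#' @param rule A [cutoff_rule()].
#' @param conf_level Confidence level for exact intervals.
#' @param sweep Logical: include the threshold sweep (default `TRUE`).
#' @param unit `"patient"` or `"maneuver"` for the group report.
#' @return Object of class `cohort_report` with elements `group_report`,
#'   `accuracy`, `sweep`, `constipation`, `notices`, `n_patients`.
#' @export
cohort_report <- function(metrics, rule = cutoff_rule(), conf_level = 0.95,
                          sweep = TRUE, unit = "patient") {
  patients <- metrics$patients
  notices <- character()
  has_truth <- any(patients$group_label %in% c("A", "B"))
  both_groups <- all(c("A", "B") %in% patients$group_label)
  group_report <- NULL
  accuracy <- NULL
  sweep_tab <- NULL
  constip <- NULL
  if (both_groups) {
    group_report <- build_group_report(metrics, unit = unit)
    if (!all(is.na(patients$constipated))) {
      constip <- constipation_comparison(patients)
    } else {
      notices <- c(notices, "no constipation flags: comparison omitted")
    }
  } else {
    notices <- c(notices,
                 "need both groups A and B for the comparison report")
  }
  if (has_truth) {
    accuracy <- evaluate_rule(patients, rule, conf_level)
    notices <- c(notices, accuracy$findings)
    if (sweep) sweep_tab <- threshold_sweep(patients,
                                            combination = rule$combination,
                                            aggregate = rule$aggregate,
                                            conf_level = conf_level)
  } else {
    notices <- c(notices, "no truth labels: accuracy section omitted")
  }
  structure(list(group_report = group_report, accuracy = accuracy,
                 sweep = sweep_tab, constipation = constip,
                 rule = rule, notices = notices,
                 n_patients = nrow(patients)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report (%d patients)\n", x$n_patients))
  if (!is.null(x$group_report)) {
    cat("\nGroup comparison (means by group, Mann-Whitney U):\n")
    gr <- x$group_report
    gr$group_a_mean <- round(gr$group_a_mean, 2)
    gr$group_b_mean <- round(gr$group_b_mean, 2)
    gr$p <- signif(gr$p, 3)
    print(gr, row.names = FALSE)
  }
  if (!is.null(x$accuracy)) {
    cat("\n")
    print(x$accuracy)
  }
  if (!is.null(x$constipation)) {
    ct <- x$constipation
    cat(sprintf(
      "\nConstipation: %.0f%% (A) vs %.0f%% (B), X2 = %s, p = %s\n",
      100 * ct$proportions[["A"]], 100 * ct$proportions[["B"]],
      if (is.na(ct$test$statistic_value)) "undefined" else
        sprintf("%.2f", ct$test$statistic_value),
      if (is.na(ct$test$p_value)) "undefined" else
        format.pval(ct$test$p_value, digits = 2)))
  }
  for (n in x$notices) cat("note:", n, "\n")
  invisible(x)
}

#' Flatten a cohort report into a JSON-ready list
#'
#' Every number shown by the print method appears here; rendering does no
#' arithmetic of its own.
#'
#' @param report A [cohort_report()].
#' @return A nested list suitable for `jsonlite::write_json()`.
#' @export
report_summary <- function(report) {
  acc <- report$accuracy
  ct <- report$constipation
  list(
    n_patients = report$n_patients,
    rule = unclass(report$rule),
    group_report = report$group_report,
    accuracy = if (!is.null(acc)) list(
      tp = acc$tp, fn = acc$fn, tn = acc$tn, fp = acc$fp,
      sensitivity = acc$sensitivity, specificity = acc$specificity,
      sensitivity_ci = as.list(acc$sensitivity_ci),
      specificity_ci = as.list(acc$specificity_ci),
      conf_level = acc$conf_level),
    constipation = if (!is.null(ct)) list(
      table = as.data.frame(as.table(ct$table)),
      proportions = as.list(ct$proportions),
      statistic = ct$test$statistic_value,
      p_value = ct$test$p_value,
      n_excluded = ct$n_excluded),
    sweep = report$sweep,
    notices = report$notices
  )
}

#' Boxplots of the three per-patient metrics by group
#'
#' @param patients `patients` data.frame from [cohort_metrics()].
#' @param aggregate Which aggregate to plot (default `"mean"`).
#' @return A ggplot object (three facets: circumferential, anterior, ratio).
#' @export
plot_group_boxplots <- function(patients, aggregate = "mean") {
  pats <- patients[patients$ok & patients$group_label %in% c("A", "B"), ]
  cols <- paste0(c("circ_", "ant_", "ratio_"), aggregate)
  long <- data.frame(
    group = rep(pats$group_label, 3),
    metric = rep(c("circumferential (mmHg)", "anterior (mmHg)",
                   "anterior:circumferential"), each = nrow(pats)),
    value = c(pats[[cols[1]]], pats[[cols[2]]], pats[[cols[3]]]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Group", y = sprintf("per-patient %s", aggregate),
                  title = "Sphincter pressure metrics by group") +
    ggplot2::theme_bw()
}

#' Scatter of mean anterior pressure versus ratio with the cut-off box
#'
#' @param patients `patients` data.frame.
#' @param rule A [cutoff_rule()]; its thresholds draw the decision
#'   rectangle.
#' @return A ggplot object.
#' @export
plot_cutoff_scatter <- function(patients, rule = cutoff_rule()) {
  pats <- patients[patients$ok & patients$group_label %in% c("A", "B"), ]
  ggplot2::ggplot(pats, ggplot2::aes(x = .data$ant_mean,
                                     y = .data$ratio_mean,
                                     shape = .data$group_label)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = rule$anterior_threshold,
                      ymin = -Inf, ymax = rule$ratio_threshold,
                      alpha = 0.12, fill = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = rule$anterior_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = rule$ratio_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "mean anterior pressure (mmHg)",
                  y = "mean anterior:circumferential ratio",
                  shape = "Group",
                  title = "Combined cut-off for an anus outside the sphincter complex") +
    ggplot2::theme_bw()
}

#' Run the full pipeline: simulate, analyze, report
#'
#' Convenience wrapper chaining [simulate_cohort()], [cohort_metrics()]
#' and [cohort_report()], optionally writing every artifact (cohort files,
#' metric CSVs, findings log, JSON summary, figures) to a directory.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Directory for artifacts; `NULL` (default) keeps
#'   everything in memory.
#' @return List with `cohort`, `metrics`, `report` and (if written)
#'   `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = NULL) {
  cohort <- simulate_cohort(config$simulation)
  metrics <- cohort_metrics(cohort,
                            smoothing_window = config$analysis$smoothing_window,
                            max_maneuvers = config$analysis$max_maneuvers)
  report <- cohort_report(metrics, rule = config$rule,
                          unit = config$analysis$unit_of_analysis)
  out <- list(cohort = cohort, metrics = metrics, report = report)
  if (!is.null(output_dir)) {
    out$paths <- write_report_artifacts(cohort, metrics, report, output_dir,
                                        figures = config$output$figures)
  }
  out
}

write_report_artifacts <- function(cohort, metrics, report, dir,
                                   figures = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_cohort(cohort, file.path(dir, "cohort"))
  man_csv <- file.path(dir, "maneuver_metrics.csv")
  pat_csv <- file.path(dir, "patient_summaries.csv")
  utils::write.csv(metrics$maneuvers, man_csv, row.names = FALSE)
  utils::write.csv(metrics$patients, pat_csv, row.names = FALSE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report_summary(report), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", null = "null")
  findings <- data.frame(
    level = rep("info", length(report$notices)),
    message = report$notices,
    stringsAsFactors = FALSE)
  utils::write.csv(findings, file.path(dir, "findings.csv"),
                   row.names = FALSE)
  fig_paths <- NULL
  if (figures && nrow(metrics$patients) > 0 &&
      any(metrics$patients$group_label %in% c("A", "B"))) {
    box_p <- file.path(dir, "group_boxplots.png")
    sc_p <- file.path(dir, "cutoff_scatter.png")
    ggplot2::ggsave(box_p, plot_group_boxplots(metrics$patients),
                    width = 8, height = 4, dpi = 150)
    ggplot2::ggsave(sc_p, plot_cutoff_scatter(metrics$patients, report$rule),
                    width = 6, height = 5, dpi = 150)
    fig_paths <- c(box_p, sc_p)
  }
  c(paths, list(maneuvers = man_csv, patients = pat_csv,
                report = json_path, figures = fig_paths))
}
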