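#' Combined cut-off rule for an anus outside the sphincter complex
#'
#' The decision rule flags a patient as having an abnormal sphincter when
#' the chosen per-patient aggregate of the mean anterior pressure is
#' strictly below `anterior_threshold` mmHg and (AND combination) the
#' aggregate of the anterior-to-circumferential ratio is strictly below
#' `ratio_threshold`. Defaults are the clinical cut-offs 75 mmHg and 0.7
#' applied to the per-patient mean.
#'
#' @param anterior_threshold mmHg, > 0.
#' @param ratio_threshold Dimensionless, > 0.
#' @param combination `"AND"` (both conditions required, default) or `"OR"`.
#' @param aggregate Which [aggregate_patient()] statistic feeds the rule:
#'   `"mean"` (default), `"min"` or `"max"`.
#' @return A `cutoff_rule` object.
#' @export
cutoff_rule <- function(anterior_threshold = 75, ratio_threshold = 0.7,
                        combination = c("AND", "OR"),
                        aggregate = c("mean", "min", "max")) {
  combination <- match.arg(combination)
  aggregate <- match.arg(aggregate)
  stopifnot(anterior_threshold >= 0, ratio_threshold >= 0)
  structure(list(anterior_threshold = anterior_threshold,
                 ratio_threshold = ratio_threshold,
                 combination = combination,
                 aggregate = aggregate),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("Cut-off rule: %s anterior < %g mmHg %s ratio < %g\n",
              x$aggregate, x$anterior_threshold,
              if (x$combination == "AND") "AND" else "OR",
              x$ratio_threshold))
  invisible(x)
}

#' Classify patients with a cut-off rule
#'
#' @param patients A `patients` data.frame from [cohort_metrics()] (or a
#'   single [aggregate_patient()] row).
#' @param rule A [cutoff_rule()].
#' @return Character vector, `"abnormal"` or `"normal"` per patient (`NA`
#'   where the required aggregates are missing).
#' @export
classify_patient <- function(patients, rule = cutoff_rule()) {
  ant <- patients[[paste0("ant_", rule$aggregate)]]
  ratio <- patients[[paste0("ratio_", rule$aggregate)]]
  if (is.null(ant) || is.null(ratio)) {
    stop(sprintf("patient summary lacks the '%s' aggregates the rule needs",
                 rule$aggregate), call. = FALSE)
  }
  cond_a <- ant < rule$anterior_threshold
  cond_r <- ratio < rule$ratio_threshold
  hit <- if (rule$combination == "AND") cond_a & cond_r else cond_a | cond_r
  ifelse(hit, "abnormal", "normal")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval obtained by inverting binomial tail tests; the
#' standard beta-quantile form is used, with the conventional closures
#' lower = 0 at `k = 0` and upper = 1 at `k = n`.
#'
#' @param k Number of successes. @param n Number of trials.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` in `[0, 1]`.
#' @export
#' @examples
#' clopper_pearson(8, 10)  # lower bound 0.444 -> "44%"
clopper_pearson <- function(k, n, conf_level = 0.95) {
  stopifnot(n >= 1, k >= 0, k <= n, conf_level > 0, conf_level < 1)
  alpha <- 1 - conf_level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Diagnostic accuracy of a cut-off rule against ground truth
#'
#' Cross-tabulates rule predictions against the truth labels (group A =
#' condition positive, i.e. abnormal sphincter) and reports sensitivity
#' and specificity with exact Clopper-Pearson intervals. An empty truth
#' class leaves that metric `NA` with a finding rather than erroring.
#'
#' @param patients `patients` data.frame from [cohort_metrics()] with
#'   `group_label` in `"A"`/`"B"`.
#' @param rule A [cutoff_rule()].
#' @param conf_level Confidence level for the exact intervals.
#' @return Object of class `diagnostic_accuracy`: counts `tp`, `fn`,
#'   `tn`, `fp`; `sensitivity`, `specificity`; `sensitivity_ci`,
#'   `specificity_ci`; `conf_level`; `findings` (character vector).
#' @export
evaluate_rule <- function(patients, rule = cutoff_rule(),
                          conf_level = 0.95) {
  keep <- patients$group_label %in% c("A", "B") &
    !is.na(patients$ok) & patients$ok
  pats <- patients[keep, , drop = FALSE]
  pred <- classify_patient(pats, rule)
  truth_pos <- pats$group_label == "A"
  tp <- sum(truth_pos & pred == "abnormal")
  fn <- sum(truth_pos & pred == "normal")
  tn <- sum(!truth_pos & pred == "normal")
  fp <- sum(!truth_pos & pred == "abnormal")
  findings <- character()
  sens <- spec <- NA_real_
  sens_ci <- spec_ci <- c(lower = NA_real_, upper = NA_real_)
  if (tp + fn > 0) {
    sens <- tp / (tp + fn)
    sens_ci <- clopper_pearson(tp, tp + fn, conf_level)
  } else {
    findings <- c(findings, "no condition-positive patients: sensitivity undefined")
  }
  if (tn + fp > 0) {
    spec <- tn / (tn + fp)
    spec_ci <- clopper_pearson(tn, tn + fp, conf_level)
  } else {
    findings <- c(findings, "no condition-negative patients: specificity undefined")
  }
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = sens, specificity = spec,
                 sensitivity_ci = sens_ci, specificity_ci = spec_ci,
                 conf_level = conf_level, rule = rule,
                 findings = findings),
            class = "diagnostic_accuracy")
}

# Percentages are reported rounded half-up to integers, matching clinical
# reporting convention.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @export
print.diagnostic_accuracy <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy (TP %d, FN %d, TN %d, FP %d)\n",
              x$tp, x$fn, x$tn, x$fp))
  lvl <- round(100 * x$conf_level)
  fmt <- function(est, ci) {
    if (is.na(est)) return("undefined")
    sprintf("%g%% (%d%% CI %g-%g%%)", round_half_up(100 * est), lvl,
            round_half_up(100 * ci[["lower"]]),
            round_half_up(100 * ci[["upper"]]))
  }
  cat("  sensitivity:", fmt(x$sensitivity, x$sensitivity_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$specificity_ci), "\n")
  for (f in x$findings) cat("  note:", f, "\n")
  invisible(x)
}

#' Sweep a grid of cut-off thresholds
#'
#' Evaluates the rule at every combination of the supplied anterior and
#' ratio thresholds and reports the confusion counts, sensitivity,
#' specificity and Youden index (sensitivity + specificity - 1) per grid
#' point. Systematizes the visual selection of a combined cut-off from the
#' anterior-pressure-versus-ratio scatter.
#'
#' @param patients `patients` data.frame with truth labels.
#' @param anterior_grid,ratio_grid Numeric threshold grids; the default
#'   grids include the clinical point (75, 0.7).
#' @param combination,aggregate Passed to [cutoff_rule()].
#' @param conf_level Confidence level for the exact intervals.
#' @return Data.frame, one row per grid point.
#' @export
threshold_sweep <- function(patients,
                            anterior_grid = seq(25, 150, by = 5),
                            ratio_grid = seq(0.3, 1.1, by = 0.05),
                            combination = "AND", aggregate = "mean",
                            conf_level = 0.95) {
  stopifnot(length(anterior_grid) >= 1, length(ratio_grid) >= 1)
  grid <- expand.grid(anterior_threshold = anterior_grid,
                      ratio_threshold = ratio_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rule <- cutoff_rule(grid$anterior_threshold[i], grid$ratio_threshold[i],
                        combination = combination, aggregate = aggregate)
    acc <- evaluate_rule(patients, rule, conf_level)
    data.frame(anterior_threshold = rule$anterior_threshold,
               ratio_threshold = rule$ratio_threshold,
               tp = acc$tp, fn = acc$fn, tn = acc$tn, fp = acc$fp,
               sensitivity = acc$sensitivity,
               specificity = acc$specificity,
               youden = acc$sensitivity + acc$specificity - 1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
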