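new_test_result <- function(statistic_name, statistic_value, p_value,
                            n1 = NA_integer_, n2 = NA_integer_,
                            z_value = NA_real_, df = NA_integer_,
                            unit_of_analysis = "patient",
                            extra = list()) {
  structure(c(list(statistic_name = statistic_name,
                   statistic_value = statistic_value,
                   z_value = z_value, df = df, p_value = p_value,
                   n1 = n1, n2 = n2,
                   unit_of_analysis = unit_of_analysis),
              extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s = %s", x$statistic_name,
              if (is.na(x$statistic_value)) "undefined" else
                format(x$statistic_value)))
  if (!is.na(x$df)) cat(sprintf(", df = %d", x$df))
  if (!is.na(x$z_value)) cat(sprintf(", z = %.3f", x$z_value))
  cat(sprintf(", p = %s\n", if (is.na(x$p_value)) "undefined" else
    format.pval(x$p_value, digits = 3)))
  if (!is.null(x$findings) && length(x$findings)) {
    for (f in x$findings) cat("  note:", f, "\n")
  }
  invisible(x)
}

#' Mann-Whitney U test (tie-corrected, from first principles)
#'
#' Ranks the pooled samples with midranks for ties and computes
#' `U1 = R1 - n1 (n1 + 1) / 2`; the reported statistic is `min(U1, U2)`
#' (the convention of common statistical calculators; both are retained).
#' The two-sided p-value comes from the tie-corrected normal approximation
#' without continuity correction:
#' \deqn{\sigma_U^2 = \frac{n_1 n_2}{12}\left[(N + 1) -
#'   \frac{\sum_t (t^3 - t)}{N (N - 1)}\right].}
#' With `exact = TRUE` (available when `choose(n1 + n2, n1) <= 2e6`) the
#' p-value is instead computed by complete enumeration of all group
#' assignments of the observed pooled values, counting assignments with
#' `|U - n1 n2 / 2|` at least as extreme as observed.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param exact Logical; `FALSE` (default) uses the normal approximation.
#' @param unit_of_analysis Label recorded in the result.
#' @return A `test_result` with fields `u1`, `u2`,
#'   `statistic_value = min(U1, U2)`, `z_value`, `p_value`, `n1`, `n2`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0
mann_whitney_u <- function(sample_a, sample_b, exact = FALSE,
                           unit_of_analysis = "patient") {
  a <- sample_a[!is.na(sample_a)]
  b <- sample_b[!is.na(sample_b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks for ties
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  N <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  mu <- n1 * n2 / 2

  if (exact) {
    if (choose(N, n1) > 2e6) {
      stop("exact enumeration not feasible for these sample sizes",
           call. = FALSE)
    }
    combos <- utils::combn(N, n1)
    stat_u1 <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
    us <- apply(combos, 2, stat_u1)
    p <- mean(abs(us - mu) >= abs(u1 - mu) - 1e-9)
    return(new_test_result("Mann-Whitney U", u, p, n1, n2,
                           unit_of_analysis = unit_of_analysis,
                           extra = list(u1 = u1, u2 = u2,
                                        method = "exact enumeration")))
  }

  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0) {
    # all observations tied: U is at its null mean, no evidence either way
    z <- 0
    p <- 1
  } else {
    z <- (u1 - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  new_test_result("Mann-Whitney U", u, p, n1, n2, z_value = z,
                  unit_of_analysis = unit_of_analysis,
                  extra = list(u1 = u1, u2 = u2,
                               method = "normal approximation, tie-corrected"))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected by default:
#' \deqn{X^2 = \frac{N (ad - bc)^2}{(a+b)(c+d)(a+c)(b+d)}, \quad df = 1,}
#' with the optional Yates continuity correction replacing `|ad - bc|` by
#' `max(0, |ad - bc| - N/2)`. A zero row or column marginal leaves the
#' statistic undefined, reported as a finding rather than an error.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @param yates Apply the Yates continuity correction (default `FALSE`).
#' @return A `test_result` with `statistic_value`, `df = 1`, `p_value`,
#'   the input `table`, and possibly `findings`.
#' @export
#' @examples
#' chi_square_2x2(matrix(c(10, 0, 0, 10), 2))  # X^2 = 20
chi_square_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || sum(tab) == 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  N <- sum(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  marg <- c(a + b, c + d, a + c, b + d)
  findings <- character()
  if (any(marg == 0)) {
    return(new_test_result("X-squared", NA_real_, NA_real_,
                           df = 1L,
                           extra = list(table = tab, yates = yates,
                                        findings = "zero marginal: statistic undefined")))
  }
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - N / 2)
  x2 <- N * num^2 / prod(marg)
  if (sum(tab) < 20 || any(tab <= 1)) {
    findings <- c(findings,
                  "small counts: chi-square approximation may be unreliable")
  }
  new_test_result("X-squared", x2, stats::pchisq(x2, df = 1, lower.tail = FALSE),
                  df = 1L,
                  extra = list(table = tab, yates = yates,
                               findings = findings))
}

#' Group-comparison report: the three metrics by three aggregates
#'
#' For each metric (mean circumferential pressure, mean anterior pressure,
#' anterior-to-circumferential ratio) and each per-patient aggregate (min,
#' mean, max), reports the group A and group B arithmetic means and the
#' Mann-Whitney U comparison — nine rows in total. The default unit of
#' analysis is the patient (per-patient aggregates); `unit = "maneuver"`
#' compares the raw per-maneuver values instead (only the three metric
#' rows are then meaningful, repeated across aggregates is avoided by
#' returning three rows).
#'
#' @param metrics Result of [cohort_metrics()] (list with `patients` and
#'   `maneuvers`), or a `patients` data.frame for patient-level analysis.
#' @param unit `"patient"` (default) or `"maneuver"`.
#' @param exact Passed to [mann_whitney_u()].
#' @return Data.frame with columns `metric`, `aggregate`, `group_a_mean`,
#'   `group_b_mean`, `u`, `p`, `n_a`, `n_b`.
#' @export
build_group_report <- function(metrics, unit = c("patient", "maneuver"),
                               exact = FALSE) {
  unit <- match.arg(unit)
  if (unit == "maneuver") {
    if (!is.list(metrics) || is.null(metrics$maneuvers)) {
      stop("maneuver-level report needs the full cohort_metrics() result",
           call. = FALSE)
    }
    man <- metrics$maneuvers[metrics$maneuvers$valid, , drop = FALSE]
    pat <- if (!is.null(metrics$patients)) metrics$patients else
      stop("patient metadata required", call. = FALSE)
    man <- merge(man, pat[, c("patient_id", "group_label")], by = "patient_id")
    rows <- lapply(c(mean_circumferential = "mean_circumferential",
                     mean_anterior = "mean_anterior", ratio = "ratio"),
                   identity)
    out <- do.call(rbind, lapply(names(rows), function(metric) {
      va <- man[[metric]][man$group_label == "A"]
      vb <- man[[metric]][man$group_label == "B"]
      tr <- mann_whitney_u(va, vb, exact = exact,
                           unit_of_analysis = "maneuver")
      data.frame(metric = metric, aggregate = "raw",
                 group_a_mean = mean(va), group_b_mean = mean(vb),
                 u = tr$statistic_value, p = tr$p_value,
                 n_a = length(va), n_b = length(vb),
                 stringsAsFactors = FALSE)
    }))
    return(out)
  }

  patients <- if (is.data.frame(metrics)) metrics else metrics$patients
  patients <- patients[patients$ok & patients$group_label %in% c("A", "B"), ,
                       drop = FALSE]
  if (sum(patients$group_label == "A") < 1 ||
      sum(patients$group_label == "B") < 1) {
    stop("need at least one analyzable patient per group", call. = FALSE)
  }
  metrics_cols <- c(circ = "circumferential", ant = "anterior",
                    ratio = "ratio")
  aggregates <- c("min", "mean", "max")
  rows <- list()
  for (m in names(metrics_cols)) {
    for (agg in aggregates) {
      col <- paste0(m, "_", agg)
      va <- patients[[col]][patients$group_label == "A"]
      vb <- patients[[col]][patients$group_label == "B"]
      tr <- mann_whitney_u(va, vb, exact = exact)
      rows[[length(rows) + 1]] <- data.frame(
        metric = metrics_cols[[m]], aggregate = agg,
        group_a_mean = mean(va), group_b_mean = mean(vb),
        u = tr$statistic_value, p = tr$p_value,
        n_a = length(va), n_b = length(vb),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Constipation prevalence comparison between groups
#'
#' Cross-tabulates group membership against the constipation flag and
#' applies the (uncorrected) Pearson chi-square test. Patients with an
#' unknown flag are excluded and counted.
#'
#' @param patients `patients` data.frame from [cohort_metrics()], or a
#'   `manometry_cohort`.
#' @param yates Passed to [chi_square_2x2()].
#' @return List with `table` (2x2: rows group A/B, cols constipated
#'   yes/no), `test` (`test_result`), `proportions` (per-group constipated
#'   fraction), `n_excluded`.
#' @export
constipation_comparison <- function(patients, yates = FALSE) {
  if (inherits(patients, "manometry_cohort")) {
    pats <- cohort_patients(patients)
    df <- data.frame(
      group_label = vapply(pats, function(p) p$group_label, character(1)),
      constipated = vapply(pats, function(p) as.logical(p$constipated),
                           logical(1)))
  } else {
    df <- patients[, c("group_label", "constipated")]
  }
  known <- df$group_label %in% c("A", "B") & !is.na(df$constipated)
  n_excluded <- sum(!known)
  df <- df[known, , drop = FALSE]
  tab <- matrix(c(sum(df$group_label == "A" & df$constipated),
                  sum(df$group_label == "A" & !df$constipated),
                  sum(df$group_label == "B" & df$constipated),
                  sum(df$group_label == "B" & !df$constipated)),
                nrow = 2, byrow = TRUE,
                dimnames = list(group = c("A", "B"),
                                constipated = c("yes", "no")))
  test <- chi_square_2x2(tab, yates = yates)
  props <- c(A = if (sum(tab[1, ]) > 0) tab[1, 1] / sum(tab[1, ]) else NA_real_,
             B = if (sum(tab[2, ]) > 0) tab[2, 1] / sum(tab[2, ]) else NA_real_)
  list(table = tab, test = test, proportions = props,
       n_excluded = n_excluded)
}
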