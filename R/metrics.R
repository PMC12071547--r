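# Moving average with edge truncation: the window shrinks at the
# boundaries instead of padding, so no sample is extrapolated.
moving_average <- function(x, window) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(x)
  h <- (window - 1) %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Locate the high-pressure zone of a pull-through recording
#'
#' The high-pressure zone (HPZ) is the axial level taken as the sphincter
#' complex: the sample maximizing the moving-average-smoothed mean of the
#' eight channels. Ties break toward the rectal (earlier) side. Smoothing
#' is used only for peak localization; metric values are read from the raw
#' pressures at the returned index.
#'
#' @param rec A [pull_through_recording()].
#' @param smoothing_window Odd window length in samples (default 3).
#' @return The 1-based sample index of the HPZ.
#' @export
detect_high_pressure_zone <- function(rec, smoothing_window = 3) {
  assert_recording(rec)
  level_mean <- rowMeans(rec$pressures)
  smoothed <- moving_average(level_mean, smoothing_window)
  which.max(smoothed)  # first max = rectal-side tie-break
}

#' Per-maneuver sphincter metrics at the high-pressure zone
#'
#' Reads the raw eight circumferential pressures at the HPZ and computes
#' the mean circumferential pressure (all 8 channels), the mean anterior
#' pressure (channels 1, 2, 8) and their ratio. A non-positive
#' circumferential mean leaves the ratio undefined: the maneuver is
#' flagged invalid (`valid = FALSE`) rather than erroring, so it can be
#' dropped and tallied downstream.
#'
#' @inheritParams detect_high_pressure_zone
#' @return An object of class `maneuver_metrics`: a list with
#'   `patient_id`, `maneuver_id`, `hpz_index`, `hpz_axial`,
#'   `circumferential_pressures` (8 values), `mean_circumferential`,
#'   `mean_anterior`, `ratio` and `valid`.
#' @export
maneuver_metrics <- function(rec, smoothing_window = 3) {
  idx <- detect_high_pressure_zone(rec, smoothing_window)
  p <- rec$pressures[idx, ]
  mc <- mean(p)
  ma <- mean(p[anterior_channels()])
  valid <- mc > 0
  structure(
    list(patient_id = rec$patient_id,
         maneuver_id = rec$maneuver_id,
         hpz_index = idx,
         hpz_axial = rec$axial_positions[idx],
         circumferential_pressures = as.numeric(p),
         mean_circumferential = mc,
         mean_anterior = ma,
         ratio = if (valid) ma / mc else NA_real_,
         valid = valid),
    class = "maneuver_metrics"
  )
}

#' @export
print.maneuver_metrics <- function(x, ...) {
  cat(sprintf(
    "Maneuver %d (patient %s): HPZ at %.2f cm (sample %d)\n",
    x$maneuver_id, x$patient_id, x$hpz_axial, x$hpz_index))
  cat(sprintf("  mean circumferential %.1f mmHg, mean anterior %.1f mmHg, ratio %s\n",
              x$mean_circumferential, x$mean_anterior,
              if (x$valid) sprintf("%.3f", x$ratio) else "undefined"))
  invisible(x)
}

#' Aggregate a patient's maneuvers into min/mean/max summaries
#'
#' Uses at most the first `max_maneuvers` maneuvers in acquisition order
#' (the clinical protocol analyzes a maximum of six per patient).
#' Maneuvers with an undefined ratio are excluded from all three metrics
#' and counted in `n_dropped`. With zero valid maneuvers a failure record
#' (`ok = FALSE`, all aggregates `NA`) is returned rather than an error.
#'
#' @param metrics List of [maneuver_metrics()] in acquisition order.
#' @param patient_id Identifier copied into the summary.
#' @param group_label,constipated Patient metadata carried through.
#' @param max_maneuvers Cap on maneuvers analyzed (default 6).
#' @return A one-row data.frame (class `patient_summary`) with columns
#'   `patient_id`, `group_label`, `constipated`, `n_maneuvers_used`,
#'   `n_dropped`, `ok`, and `{circ,ant,ratio}_{min,mean,max}`.
#' @export
aggregate_patient <- function(metrics, patient_id,
                              group_label = "unknown", constipated = NA,
                              max_maneuvers = 6) {
  if (length(metrics) < 1) stop("no maneuver metrics supplied", call. = FALSE)
  used <- metrics[seq_len(min(length(metrics), max_maneuvers))]
  valid <- Filter(function(m) isTRUE(m$valid), used)
  n_dropped <- length(used) - length(valid)
  agg <- function(values) {
    if (length(values) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(min(values), mean(values), max(values))
  }
  circ <- agg(vapply(valid, `[[`, numeric(1), "mean_circumferential"))
  ant <- agg(vapply(valid, `[[`, numeric(1), "mean_anterior"))
  ratio <- agg(vapply(valid, `[[`, numeric(1), "ratio"))
  out <- data.frame(
    patient_id = patient_id,
    group_label = group_label,
    constipated = constipated,
    n_maneuvers_used = length(valid),
    n_dropped = n_dropped,
    ok = length(valid) > 0,
    circ_min = circ[1], circ_mean = circ[2], circ_max = circ[3],
    ant_min = ant[1], ant_mean = ant[2], ant_max = ant[3],
    ratio_min = ratio[1], ratio_mean = ratio[2], ratio_max = ratio[3],
    stringsAsFactors = FALSE
  )
  class(out) <- c("patient_summary", class(out))
  out
}

#' Run the measurement pipeline over a whole cohort
#'
#' Computes [maneuver_metrics()] for every recording and
#' [aggregate_patient()] for every patient.
#'
#' @param cohort A `manometry_cohort` or list of [patient_record()]s.
#' @inheritParams detect_high_pressure_zone
#' @inheritParams aggregate_patient
#' @return A list with `maneuvers` (one row per maneuver) and `patients`
#'   (one [aggregate_patient()] row per patient) data.frames.
#' @export
cohort_metrics <- function(cohort, smoothing_window = 3, max_maneuvers = 6) {
  patients <- cohort_patients(cohort)
  man_rows <- list()
  pat_rows <- list()
  for (pat in patients) {
    mm <- lapply(pat$recordings, maneuver_metrics,
                 smoothing_window = smoothing_window)
    for (m in mm) {
      man_rows[[length(man_rows) + 1]] <- data.frame(
        patient_id = m$patient_id, maneuver_id = m$maneuver_id,
        hpz_index = m$hpz_index, hpz_axial = m$hpz_axial,
        mean_circumferential = m$mean_circumferential,
        mean_anterior = m$mean_anterior, ratio = m$ratio,
        valid = m$valid, stringsAsFactors = FALSE)
    }
    pat_rows[[length(pat_rows) + 1]] <-
      aggregate_patient(mm, pat$patient_id,
                        group_label = pat$group_label,
                        constipated = pat$constipated,
                        max_maneuvers = max_maneuvers)
  }
  empty_man <- data.frame(patient_id = character(), maneuver_id = integer(),
                          hpz_index = integer(), hpz_axial = numeric(),
                          mean_circumferential = numeric(),
                          mean_anterior = numeric(), ratio = numeric(),
                          valid = logical(), stringsAsFactors = FALSE)
  empty_pat <- data.frame(patient_id = character(), group_label = character(),
                          constipated = logical(),
                          n_maneuvers_used = integer(), n_dropped = integer(),
                          ok = logical(),
                          circ_min = numeric(), circ_mean = numeric(),
                          circ_max = numeric(),
                          ant_min = numeric(), ant_mean = numeric(),
                          ant_max = numeric(),
                          ratio_min = numeric(), ratio_mean = numeric(),
                          ratio_max = numeric(), stringsAsFactors = FALSE)
  list(
    maneuvers = if (length(man_rows)) do.call(rbind, man_rows) else empty_man,
    patients = if (length(pat_rows)) do.call(rbind, pat_rows) else empty_pat
  )
}
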