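#' Construct a pull-through recording
#'
#' The raw unit of analysis: one withdrawal of the eight-channel
#' water-perfused catheter through the anal canal. Each sample row maps to
#' an axial position (cm; 0 at the anal verge, positive toward the rectum,
#' strictly decreasing during the pull).
#'
#' @param patient_id Opaque patient identifier (string).
#' @param maneuver_id 1-based ordinal in acquisition order.
#' @param axial_positions Numeric vector of axial positions, cm, strictly
#'   decreasing (rectal to external).
#' @param pressures Numeric matrix, `length(axial_positions)` rows by 8
#'   channel columns, mmHg.
#' @param channel_angles 8 channel angles in degrees; default
#'   [channel_angles()].
#' @param pull_speed Catheter withdrawal speed, cm/s.
#' @param sampling_rate Samples per second.
#' @return An object of class `pull_through_recording`.
#' @export
pull_through_recording <- function(patient_id, maneuver_id,
                                   axial_positions, pressures,
                                   channel_angles = manopull::channel_angles(),
                                   pull_speed = 1, sampling_rate = 10) {
  rec <- structure(
    list(
      patient_id = as.character(patient_id),
      maneuver_id = as.integer(maneuver_id),
      axial_positions = as.numeric(axial_positions),
      pressures = as.matrix(pressures),
      channel_angles = as.numeric(channel_angles),
      pull_speed = as.numeric(pull_speed),
      sampling_rate = as.numeric(sampling_rate)
    ),
    class = "pull_through_recording"
  )
  assert_recording(rec)
  rec
}

# Hard invariants: violation is a construction/read error, not a finding.
assert_recording <- function(rec) {
  findings <- validate_recording(rec)
  errors <- findings[findings$level == "error", , drop = FALSE]
  if (nrow(errors) > 0) {
    stop(sprintf("invalid recording (patient %s, maneuver %d): %s",
                 rec$patient_id, rec$maneuver_id,
                 paste(errors$message, collapse = "; ")),
         call. = FALSE)
  }
  invisible(rec)
}

#' Validate a recording, returning machine-readable findings
#'
#' Structural violations (wrong channel count, non-monotone axial
#' coordinates, non-finite pressures, too few samples) are error-level;
#' physiologically implausible pressures (below -5 or above 300 mmHg) are
#' warnings. Findings are returned, never thrown.
#'
#' @param rec A `pull_through_recording` (or a bare list with its fields).
#' @return A data.frame with columns `level` ("error"/"warning"), `code`,
#'   `message`; zero rows for a clean recording.
#' @export
validate_recording <- function(rec) {
  f <- list()
  add <- function(level, code, message) {
    f[[length(f) + 1]] <<- data.frame(level = level, code = code,
                                      message = message,
                                      stringsAsFactors = FALSE)
  }
  p <- rec$pressures
  if (!is.matrix(p) || ncol(p) != 8) {
    add("error", "channels",
        sprintf("pressures must have exactly 8 channels, found %s",
                if (is.matrix(p)) ncol(p) else "a non-matrix"))
  }
  n <- length(rec$axial_positions)
  if (n < 3) add("error", "samples", "fewer than 3 samples")
  if (is.matrix(p) && nrow(p) != n) {
    add("error", "rows", sprintf(
      "pressure rows (%d) != axial positions (%d)", nrow(p), n))
  }
  if (n >= 2 && any(diff(rec$axial_positions) >= 0)) {
    add("error", "axial",
        "axial positions must be strictly decreasing (rectal to external)")
  }
  if (is.matrix(p) && any(!is.finite(p))) {
    add("error", "finite", "non-finite pressure values")
  }
  if (length(rec$channel_angles) != 8 ||
      !setequal(round(sort(rec$channel_angles %% 360)), seq(0, 315, by = 45))) {
    add("error", "angles", "channel angles must cover the circle at 45-degree spacing")
  }
  if (is.matrix(p) && all(is.finite(p))) {
    if (any(p < -5)) {
      add("warning", "low_pressure",
          sprintf("%d sample(s) below -5 mmHg", sum(p < -5)))
    }
    if (any(p > 300)) {
      add("warning", "high_pressure",
          sprintf("%d sample(s) above 300 mmHg", sum(p > 300)))
    }
  }
  if (length(f) == 0) {
    data.frame(level = character(), code = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, f)
  }
}

#' @export
print.pull_through_recording <- function(x, ...) {
  cat(sprintf(
    "Pull-through recording: patient %s, maneuver %d, %d samples x 8 channels\n",
    x$patient_id, x$maneuver_id, nrow(x$pressures)))
  cat(sprintf("  axial %.2f -> %.2f cm at %.1f cm/s, %.0f samples/s\n",
              x$axial_positions[1],
              x$axial_positions[length(x$axial_positions)],
              x$pull_speed, x$sampling_rate))
  invisible(x)
}

#' Construct a patient record
#'
#' @param patient_id Identifier.
#' @param recordings List of [pull_through_recording()] with unique,
#'   contiguous 1-based maneuver ids.
#' @param group_label `"A"` (abnormal sphincter), `"B"` (normal) or
#'   `"unknown"`.
#' @param constipated Logical or `NA` (unknown).
#' @param age_months,sex Optional metadata.
#' @return Object of class `patient_record`.
#' @export
patient_record <- function(patient_id, recordings,
                           group_label = "unknown", constipated = NA,
                           age_months = NA_real_, sex = NA_character_) {
  if (length(recordings) < 1) {
    stop("a patient record needs at least one recording", call. = FALSE)
  }
  ids <- vapply(recordings, function(r) r$maneuver_id, integer(1))
  if (!identical(sort(ids), seq_along(ids))) {
    stop(sprintf("patient %s: maneuver ids must be unique and contiguous from 1",
                 patient_id), call. = FALSE)
  }
  if (!group_label %in% c("A", "B", "unknown")) {
    stop("group_label must be 'A', 'B' or 'unknown'", call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         recordings = recordings[order(ids)],
         group_label = group_label,
         constipated = as.logical(constipated),
         age_months = as.numeric(age_months),
         sex = as.character(sex)),
    class = "patient_record"
  )
}

COHORT_FORMAT_VERSION <- "1.0"

#' Write a cohort to disk (long CSV + JSON metadata sidecar)
#'
#' The interchange format is a long-format CSV of samples
#' (`patient_id, maneuver_id, sample_index, time_s, axial_cm, channel,
#' pressure_mmHg`, RFC-4180, UTF-8, '.' decimal separator) plus a JSON
#' sidecar holding per-patient labels, channel geometry, the simulation
#' config echo if present, and a format version. The round trip through
#' [read_cohort()] is lossless up to numeric printing precision.
#'
#' @param cohort A `manometry_cohort` (see [simulate_cohort()]) or list of
#'   [patient_record()]s.
#' @param path Directory to write into (created if missing).
#' @return Invisibly, the paths written (`csv`, `json`).
#' @export
write_cohort <- function(cohort, path) {
  patients <- cohort_patients(cohort)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(path, "recordings.csv")
  json_path <- file.path(path, "cohort.json")

  rows <- list()
  for (pat in patients) {
    for (rec in pat$recordings) {
      n <- length(rec$axial_positions)
      rows[[length(rows) + 1]] <- data.table::data.table(
        patient_id = rec$patient_id,
        maneuver_id = rec$maneuver_id,
        sample_index = rep(seq_len(n), times = 8),
        time_s = rep((seq_len(n) - 1) / rec$sampling_rate, times = 8),
        axial_cm = rep(rec$axial_positions, times = 8),
        channel = rep(1:8, each = n),
        pressure_mmHg = as.vector(rec$pressures)
      )
    }
  }
  long <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(patient_id = character(), maneuver_id = integer(),
                           sample_index = integer(), time_s = numeric(),
                           axial_cm = numeric(), channel = integer(),
                           pressure_mmHg = numeric())
  data.table::fwrite(long, csv_path)

  meta <- list(
    format_version = COHORT_FORMAT_VERSION,
    channel_angles = as.numeric(channel_angles()),
    patients = lapply(patients, function(pat) {
      list(patient_id = pat$patient_id,
           group_label = pat$group_label,
           constipated = pat$constipated,
           age_months = pat$age_months,
           sex = pat$sex,
           n_maneuvers = length(pat$recordings),
           pull_speed = pat$recordings[[1]]$pull_speed,
           sampling_rate = pat$recordings[[1]]$sampling_rate)
    }),
    config = attr(cohort, "config_echo")
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(list(csv = csv_path, json = json_path))
}

#' Read a cohort from disk, enforcing all format invariants
#'
#' Fails hard (no partial cohort) on: missing files, unknown major format
#' version, a patient/maneuver present in only one of CSV and sidecar, a
#' maneuver block without exactly 8 channels, non-monotone axial
#' coordinates, or non-finite pressures. Error messages name the patient
#' and maneuver.
#'
#' @param path Directory written by [write_cohort()].
#' @return A `manometry_cohort`.
#' @export
read_cohort <- function(path) {
  csv_path <- file.path(path, "recordings.csv")
  json_path <- file.path(path, "cohort.json")
  if (!file.exists(csv_path) || !file.exists(json_path)) {
    stop("cohort directory must contain recordings.csv and cohort.json",
         call. = FALSE)
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = FALSE)
  ver <- meta$format_version
  if (is.null(ver) ||
      strsplit(ver, ".", fixed = TRUE)[[1]][1] !=
      strsplit(COHORT_FORMAT_VERSION, ".", fixed = TRUE)[[1]][1]) {
    stop(sprintf("unsupported cohort format version '%s'", ver %||% "missing"),
         call. = FALSE)
  }
  long <- data.table::fread(csv_path)
  required_cols <- c("patient_id", "maneuver_id", "sample_index", "time_s",
                     "axial_cm", "channel", "pressure_mmHg")
  if (!all(required_cols %in% names(long))) {
    stop("recordings.csv is missing required columns", call. = FALSE)
  }

  meta_ids <- vapply(meta$patients, function(p) p$patient_id, character(1))
  csv_ids <- unique(long$patient_id)
  if (!setequal(meta_ids, csv_ids) &&
      !(length(csv_ids) == 0 && length(meta_ids) == 0)) {
    stop(sprintf(
      "patient sets differ between CSV and metadata (CSV-only: %s; metadata-only: %s)",
      paste(setdiff(csv_ids, meta_ids), collapse = ",") %|e|% "none",
      paste(setdiff(meta_ids, csv_ids), collapse = ",") %|e|% "none"),
      call. = FALSE)
  }

  patients <- lapply(meta$patients, function(pm) {
    pid <- pm$patient_id
    pdata <- long[long$patient_id == pid, ]
    recs <- lapply(sort(unique(pdata$maneuver_id)), function(mid) {
      mdata <- pdata[pdata$maneuver_id == mid, ]
      chans <- sort(unique(mdata$channel))
      if (!identical(as.integer(chans), 1:8)) {
        stop(sprintf(
          "patient %s maneuver %d: expected channels 1..8, found {%s}",
          pid, mid, paste(chans, collapse = ",")), call. = FALSE)
      }
      mdata <- mdata[order(mdata$channel, mdata$sample_index), ]
      n <- nrow(mdata) / 8
      if (n != round(n)) {
        stop(sprintf("patient %s maneuver %d: truncated sample block",
                     pid, mid), call. = FALSE)
      }
      per_chan <- split(as.data.frame(mdata), mdata$channel)
      counts <- vapply(per_chan, nrow, integer(1))
      if (length(unique(counts)) != 1) {
        stop(sprintf("patient %s maneuver %d: unequal samples per channel",
                     pid, mid), call. = FALSE)
      }
      axial <- per_chan[[1]]$axial_cm
      if (any(!is.finite(mdata$pressure_mmHg))) {
        stop(sprintf("patient %s maneuver %d: non-finite pressure",
                     pid, mid), call. = FALSE)
      }
      if (length(axial) >= 2 && any(diff(axial) >= 0)) {
        stop(sprintf("patient %s maneuver %d: axial coordinates not strictly decreasing",
                     pid, mid), call. = FALSE)
      }
      pressures <- vapply(per_chan, function(d) d$pressure_mmHg,
                          numeric(length(axial)))
      pull_through_recording(
        patient_id = pid, maneuver_id = mid,
        axial_positions = axial,
        pressures = matrix(pressures, ncol = 8),
        channel_angles = unlist(meta$channel_angles),
        pull_speed = pm$pull_speed %||% 1,
        sampling_rate = pm$sampling_rate %||% 10)
    })
    patient_record(pid, recs,
                   group_label = pm$group_label %||% "unknown",
                   constipated = if (is.null(pm$constipated)) NA else pm$constipated,
                   age_months = pm$age_months %||% NA_real_,
                   sex = pm$sex %||% NA_character_)
  })
  new_cohort(patients, config_echo = meta$config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|e|%` <- function(a, b) if (length(a) == 0 || identical(a, "")) b else a

new_cohort <- function(patients, config_echo = NULL) {
  structure(list(patients = patients),
            config_echo = config_echo,
            class = "manometry_cohort")
}

cohort_patients <- function(cohort) {
  if (inherits(cohort, "manometry_cohort")) cohort$patients else cohort
}

#' @export
print.manometry_cohort <- function(x, ...) {
  pats <- x$patients
  groups <- vapply(pats, function(p) p$group_label, character(1))
  nman <- vapply(pats, function(p) length(p$recordings), integer(1))
  cat(sprintf("Manometry cohort: %d patients (A=%d, B=%d), %d maneuvers total\n",
              length(pats), sum(groups == "A"), sum(groups == "B"), sum(nman)))
  invisible(x)
}
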