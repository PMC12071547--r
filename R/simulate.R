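#' Phenotype prior for one patient group
#'
#' Distributions the cohort simulator draws a [sphincter_phenotype()] from.
#' Baseline, amplitude, axial center and axial sigma are truncated normals
#' (sd 0 gives a point mass); the anterior deficit is Beta with mean
#' `deficit_mean` and concentration `deficit_conc` (shape1 = mean * conc,
#' shape2 = (1 - mean) * conc; `deficit_conc = Inf` gives a point mass),
#' optionally mixed with probability `deficit_mix_prob` with a uniform draw
#' over `deficit_mix_range` — this models the minority of clinically
#' "normal" children with a moderately weaker anterior segment.
#'
#' @param baseline_mean,baseline_sd Resting baseline, mmHg.
#' @param amplitude_mean,amplitude_sd High-pressure-zone amplitude, mmHg.
#' @param center_mean,center_sd Axial center of the sphincter complex, cm.
#' @param sigma_mean,sigma_sd Axial sigma, cm.
#' @param deficit_mean,deficit_conc Beta prior on the anterior deficit.
#' @param deficit_mix_prob,deficit_mix_range Uniform contamination of the
#'   deficit prior.
#' @param offset_sd Angular offset jitter, degrees (sd of a normal about 0).
#' @return A `phenotype_prior` list.
#' @export
phenotype_prior <- function(baseline_mean = 15, baseline_sd = 3,
                            amplitude_mean = 120, amplitude_sd = 25,
                            center_mean = 1.0, center_sd = 0.25,
                            sigma_mean = 0.6, sigma_sd = 0.1,
                            deficit_mean = 0.5, deficit_conc = 10,
                            deficit_mix_prob = 0,
                            deficit_mix_range = c(0.35, 0.85),
                            offset_sd = 10) {
  pr <- as.list(environment())
  stopifnot(pr$deficit_mean >= 0, pr$deficit_mean <= 1,
            pr$deficit_mix_prob >= 0, pr$deficit_mix_prob <= 1)
  structure(pr, class = "phenotype_prior")
}

# Calibrated so that, through the default acquisition settings and the
# metrics pipeline, cohort mean anterior pressures land near 61 mmHg
# (group A) and 136 mmHg (group B) with slightly overlapping group
# histograms; see the methods vignette for the calibration procedure.
default_prior_a <- function() {
  phenotype_prior(amplitude_mean = 120, amplitude_sd = 25,
                  deficit_mean = 0.92, deficit_conc = 10)
}

default_prior_b <- function() {
  phenotype_prior(amplitude_mean = 135, amplitude_sd = 28,
                  deficit_mean = 0.08, deficit_conc = 13,
                  deficit_mix_prob = 0.12,
                  deficit_mix_range = c(0.35, 0.85))
}

#' Simulation configuration for a synthetic manometry cohort
#'
#' Defaults mirror the study conditions the analysis was designed for:
#' 12 patients with an abnormal sphincter (group A) and 26 with a normal
#' one (group B); 1-10 pull-through maneuvers per exam with mean 4.5
#' (drawn as 1 + Binomial(9, 7/18)); a 1 cm/s manual pull sampled at
#' 10 samples/s (1 mm axial resolution) over a 6 cm span starting 3 cm
#' rectal of the anal verge; constipation prevalence 45% in group A and
#' 15% in group B.
#'
#' @param n_group_a,n_group_b Patients per group.
#' @param prior_a,prior_b [phenotype_prior()]s per group.
#' @param maneuvers_distribution Probability vector over 1..10 maneuvers.
#' @param pull_speed cm/s. @param sampling_rate samples/s.
#' @param recording_span cm of catheter travel.
#' @param span_start_cm Axial position (cm above the verge) where the pull
#'   starts.
#' @param noise_sd Per-sample, per-channel Gaussian noise sd, mmHg.
#' @param artifact_probability Per-maneuver probability of one transient
#'   all-channel agitation artifact.
#' @param artifact_magnitude Peak artifact amplitude, mmHg.
#' @param amplitude_jitter_cv Per-maneuver multiplicative amplitude jitter
#'   (coefficient of variation; 0 disables).
#' @param pull_speed_jitter_cv Per-maneuver pull-speed jitter (0 disables;
#'   manual pulling is prone to speed error, off by default).
#' @param constipation_prob_a,constipation_prob_b Bernoulli constipation
#'   probabilities per group.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_group_a = 12, n_group_b = 26,
                              prior_a = default_prior_a(),
                              prior_b = default_prior_b(),
                              maneuvers_distribution =
                                stats::dbinom(0:9, 9, 7 / 18),
                              pull_speed = 1, sampling_rate = 10,
                              recording_span = 6, span_start_cm = 3,
                              noise_sd = 8,
                              artifact_probability = 0.1,
                              artifact_magnitude = 40,
                              amplitude_jitter_cv = 0,
                              pull_speed_jitter_cv = 0,
                              constipation_prob_a = 0.45,
                              constipation_prob_b = 0.15,
                              seed = 1L) {
  cfg <- as.list(environment())
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_group_a >= 0, n_group_b >= 0,
              pull_speed > 0, sampling_rate > 0, recording_span > 0,
              noise_sd >= 0,
              artifact_probability >= 0, artifact_probability <= 1,
              constipation_prob_a >= 0, constipation_prob_a <= 1,
              constipation_prob_b >= 0, constipation_prob_b <= 1)
    if (length(maneuvers_distribution) != 10 ||
        any(maneuvers_distribution < 0) ||
        abs(sum(maneuvers_distribution) - 1) > 1e-8) {
      stop("maneuvers_distribution must be a probability vector over 1..10",
           call. = FALSE)
    }
  })
  invisible(cfg)
}

#' Draw one sphincter phenotype from a group's prior
#'
#' @param config A [simulation_config()].
#' @param group `"A"` or `"B"`.
#' @return A [sphincter_phenotype()]. Uses the current RNG state; seed via
#'   `set.seed()` or let [simulate_cohort()] manage seeding.
#' @export
sample_phenotype <- function(config, group) {
  prior <- switch(group, A = config$prior_a, B = config$prior_b,
                  stop(sprintf("unknown group label '%s'", group),
                       call. = FALSE))
  rtnorm <- function(mean, sd, lower) {
    if (sd == 0) return(max(mean, lower))
    max(stats::rnorm(1, mean, sd), lower)
  }
  d <- if (prior$deficit_mix_prob > 0 &&
           stats::runif(1) < prior$deficit_mix_prob) {
    stats::runif(1, prior$deficit_mix_range[1], prior$deficit_mix_range[2])
  } else if (is.infinite(prior$deficit_conc)) {
    prior$deficit_mean
  } else if (prior$deficit_mean == 0 || prior$deficit_mean == 1) {
    prior$deficit_mean
  } else {
    stats::rbeta(1, prior$deficit_mean * prior$deficit_conc,
                 (1 - prior$deficit_mean) * prior$deficit_conc)
  }
  sphincter_phenotype(
    baseline_pressure = rtnorm(prior$baseline_mean, prior$baseline_sd, 0),
    peak_amplitude = rtnorm(prior$amplitude_mean, prior$amplitude_sd, 10),
    axial_center = rtnorm(prior$center_mean, prior$center_sd, 0.2),
    axial_sigma = rtnorm(prior$sigma_mean, prior$sigma_sd, 0.2),
    anterior_deficit = d,
    angular_offset = if (prior$offset_sd == 0) 0 else
      stats::rnorm(1, 0, prior$offset_sd)
  )
}

#' Simulate one pull-through maneuver
#'
#' Axial positions advance from the rectal side outward at
#' `pull_speed / sampling_rate` cm per sample over `recording_span`. Each
#' channel samples the phenotype's [pressure_field()] at its fixed angle
#' plus independent Gaussian noise; with probability
#' `artifact_probability` a transient positive all-channel bump (an
#' agitation artifact) is added at a random time. Warns (and still returns
#' the recording) if the span does not contain the phenotype's axial
#' center.
#'
#' @param phenotype A [sphincter_phenotype()].
#' @param config A [simulation_config()].
#' @param patient_id,maneuver_id Identifiers stored in the recording.
#' @return A [pull_through_recording()]. Uses the current RNG state.
#' @export
simulate_pullthrough <- function(phenotype, config,
                                 patient_id = "P1", maneuver_id = 1L) {
  speed <- config$pull_speed
  if (config$pull_speed_jitter_cv > 0) {
    speed <- speed * max(stats::rnorm(1, 1, config$pull_speed_jitter_cv), 0.2)
  }
  amp <- phenotype$peak_amplitude
  if (config$amplitude_jitter_cv > 0) {
    amp <- amp * max(stats::rnorm(1, 1, config$amplitude_jitter_cv), 0)
  }
  ph <- phenotype
  ph$peak_amplitude <- amp

  dz <- speed / config$sampling_rate
  n <- floor(config$recording_span / dz) + 1L
  axial <- config$span_start_cm - dz * (seq_len(n) - 1)
  if (phenotype$axial_center > max(axial) ||
      phenotype$axial_center < min(axial)) {
    warning(sprintf(
      "recording span [%.2f, %.2f] cm does not contain axial_center %.2f cm",
      min(axial), max(axial), phenotype$axial_center), call. = FALSE)
  }

  angles <- channel_angles()
  clean <- vapply(angles, function(a) pressure_field(ph, axial, a),
                  numeric(n))
  noise <- if (config$noise_sd > 0) {
    matrix(stats::rnorm(n * 8, 0, config$noise_sd), nrow = n)
  } else {
    0
  }
  pressures <- clean + noise
  if (config$artifact_probability > 0 &&
      stats::runif(1) < config$artifact_probability) {
    t0 <- stats::runif(1, 0, (n - 1) / config$sampling_rate)
    tt <- (seq_len(n) - 1) / config$sampling_rate
    bump <- config$artifact_magnitude * exp(-(tt - t0)^2 / (2 * 0.15^2))
    pressures <- pressures + bump  # same transient on all 8 channels
  }
  pull_through_recording(patient_id, maneuver_id, axial, pressures,
                         channel_angles = angles,
                         pull_speed = speed,
                         sampling_rate = config$sampling_rate)
}

#' Simulate a full cohort of patients
#'
#' Draws `n_group_a + n_group_b` patients. Per patient: one phenotype from
#' the group prior, a maneuver count from `maneuvers_distribution`, that
#' many pull-through recordings from the fixed phenotype, and a
#' constipation flag from the group's Bernoulli probability. Fully
#' reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A `manometry_cohort` carrying ground-truth group labels and a
#'   config echo used by [write_cohort()].
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  groups <- rep(c("A", "B"), times = c(config$n_group_a, config$n_group_b))
  patients <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    pid <- sprintf("%s%02d", g, sum(groups[seq_len(i)] == g))
    phen <- sample_phenotype(config, g)
    n_man <- sample.int(10, 1, prob = config$maneuvers_distribution)
    recs <- lapply(seq_len(n_man), function(m) {
      simulate_pullthrough(phen, config, patient_id = pid, maneuver_id = m)
    })
    const_p <- if (g == "A") config$constipation_prob_a else
      config$constipation_prob_b
    pat <- patient_record(pid, recs, group_label = g,
                          constipated = stats::runif(1) < const_p)
    pat$phenotype <- phen  # ground truth retained for validation studies
    patients[[i]] <- pat
  }
  echo <- config
  echo$prior_a <- unclass(echo$prior_a)
  echo$prior_b <- unclass(echo$prior_b)
  new_cohort(patients, config_echo = unclass(echo))
}
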