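# Shared fixtures: all synthetic, built in code at test time.

# A recording from an explicit pressure matrix (axial positions strictly
# decreasing as during a pull).
make_recording <- function(pressures, patient_id = "T1", maneuver_id = 1L,
                           dz = 0.1) {
  n <- nrow(pressures)
  pull_through_recording(
    patient_id = patient_id, maneuver_id = maneuver_id,
    axial_positions = seq(3, by = -dz, length.out = n),
    pressures = pressures)
}

# Noise-free, artifact-free acquisition settings (overridable).
quiet_config <- function(...) {
  args <- utils::modifyList(list(noise_sd = 0, artifact_probability = 0),
                            list(...))
  do.call(simulation_config, args)
}

# A maneuver_metrics stub with a given ratio triple, for aggregation tests.
fake_metrics <- function(ratio, ant = 100, circ = 120, id = 1L,
                         valid = TRUE) {
  structure(list(patient_id = "T1", maneuver_id = id, hpz_index = 1L,
                 hpz_axial = 1, circumferential_pressures = rep(circ, 8),
                 mean_circumferential = circ, mean_anterior = ant,
                 ratio = if (valid) ratio else NA_real_, valid = valid),
            class = "maneuver_metrics")
}

# Brute-force Mann-Whitney U via pair counting (the independent oracle).
u_pair_count <- function(a, b) {
  gt <- sum(outer(a, b, ">"))
  eq <- sum(outer(a, b, "=="))
  gt + eq / 2
}
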