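test_that("HPZ detection matches a brute-force smoothed argmax", {
  # independent oracle: explicit window means at every index
  brute <- function(pressures, window) {
    lm <- rowMeans(pressures)
    n <- length(lm)
    h <- (window - 1) %/% 2
    sm <- vapply(seq_len(n), function(i) {
      mean(lm[max(1, i - h):min(n, i + h)])
    }, numeric(1))
    which.max(sm)
  }
  set.seed(77)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    p <- matrix(runif(n * 8, 0, 150), nrow = n)
    # inject ties occasionally
    if (i %% 4 == 0) p[sample(n, 2), ] <- 80
    rec <- make_recording(p)
    w <- sample(c(1, 3, 5), 1)
    expect_equal(detect_high_pressure_zone(rec, w), brute(p, w))
  }
})

test_that("HPZ ties break toward the rectal (earlier) side", {
  # constant recording: every index ties, the first must win
  flat <- make_recording(matrix(50, nrow = 20, ncol = 8))
  expect_equal(detect_high_pressure_zone(flat), 1L)

  # two identical, well-separated peaks at samples 10 and 40
  n <- 60
  base <- matrix(20, nrow = n, ncol = 8)
  for (peak in c(10, 40)) base[peak + (-1:1), ] <- c(60, 100, 60)
  rec <- make_recording(base)
  expect_equal(detect_high_pressure_zone(rec, 3), 10L)
})

test_that("HPZ recovers the phenotype's axial center on noise-free pulls", {
  cfg <- quiet_config()
  dz <- cfg$pull_speed / cfg$sampling_rate
  set.seed(19)
  for (i in 1:100) {
    ph <- sphincter_phenotype(
      baseline_pressure = runif(1, 5, 25),
      peak_amplitude = runif(1, 60, 180),
      axial_center = runif(1, 0.3, 2.5),
      axial_sigma = runif(1, 0.3, 1),
      anterior_deficit = runif(1, 0, 1))
    rec <- simulate_pullthrough(ph, cfg)
    m <- maneuver_metrics(rec)
    expect_lte(abs(m$hpz_axial - ph$axial_center), dz + 1e-9)
  }
})

test_that("maneuver metrics reproduce hand-computed channel summaries", {
  # hand-sums: anterior = (100 + 60 + 70)/3, circumferential = 880/8
  vals <- c(100, 60, 120, 130, 140, 135, 125, 70)
  p <- matrix(10, nrow = 9, ncol = 8)
  p[5, ] <- vals
  m <- maneuver_metrics(make_recording(p), smoothing_window = 1)
  expect_equal(m$hpz_index, 5L)
  expect_equal(m$circumferential_pressures, vals)
  expect_equal(m$mean_anterior, (100 + 60 + 70) / 3)
  expect_equal(m$mean_circumferential, 110)
  expect_equal(m$ratio, ((100 + 60 + 70) / 3) / 110)
  expect_equal(m$ratio * m$mean_circumferential, m$mean_anterior)

  # uniform level: ratio exactly 1
  u <- matrix(10, nrow = 9, ncol = 8); u[5, ] <- 140
  mu <- maneuver_metrics(make_recording(u), smoothing_window = 1)
  expect_equal(mu$mean_circumferential, 140)
  expect_equal(mu$mean_anterior, 140)
  expect_equal(mu$ratio, 1)

  # complete anterior absence: anterior mean and ratio are zero
  z <- matrix(1, nrow = 9, ncol = 8)
  z[5, ] <- c(0, 0, 120, 120, 120, 120, 120, 0)
  mz <- maneuver_metrics(make_recording(z), smoothing_window = 1)
  expect_equal(mz$mean_anterior, 0)
  expect_equal(mz$ratio, 0)
})

test_that("a non-positive circumferential mean flags the maneuver invalid", {
  p <- matrix(-1, nrow = 9, ncol = 8)
  m <- maneuver_metrics(make_recording(p))
  expect_false(m$valid)
  expect_true(is.na(m$ratio))
})

test_that("metrics are scale-equivariant and the ratio scale-invariant", {
  set.seed(5)
  p <- matrix(runif(30 * 8, 10, 150), nrow = 30)
  rec <- make_recording(p)
  m1 <- maneuver_metrics(rec)
  for (k in c(0.5, 2, 7.3)) {
    rec_k <- make_recording(p * k)
    mk <- maneuver_metrics(rec_k)
    expect_equal(mk$mean_anterior, k * m1$mean_anterior)
    expect_equal(mk$mean_circumferential, k * m1$mean_circumferential)
    expect_equal(mk$ratio, m1$ratio)
  }
})

test_that("swapping anterior and posterior channels flips the ratio", {
  ph <- sphincter_phenotype(anterior_deficit = 0.8)
  rec <- simulate_pullthrough(ph, quiet_config())
  m <- maneuver_metrics(rec)
  # shift channel assignments by 4: anterior slots now read posterior angles
  swapped <- rec
  shift <- c(5:8, 1:4)
  swapped$pressures <- rec$pressures[, shift]
  swapped$channel_angles <- rec$channel_angles[shift]
  ms <- maneuver_metrics(swapped)
  expect_lt(m$ratio, 1)
  expect_gt(ms$ratio, m$ratio)
  expect_gt(ms$ratio, 1)
})

test_that("pipeline ratio matches the analytic angular means at the peak", {
  # at the exact peak the Gaussian factor cancels:
  # ratio = mean_anterior g / mean_all g, up to axial discretization
  angles <- channel_angles()
  for (d in c(0.2, 0.5, 0.9)) {
    ph <- sphincter_phenotype(baseline_pressure = 10, peak_amplitude = 130,
                              axial_center = 1, anterior_deficit = d)
    g <- 1 - d * ifelse(abs(angles) <= 90,
                        0.5 * (1 + cos(pi * angles / 90)), 0)
    num <- 10 + 130 * mean(g[c(1, 2, 8)])
    den <- 10 + 130 * mean(g)
    m <- maneuver_metrics(simulate_pullthrough(ph, quiet_config()))
    expect_lt(abs(m$ratio - num / den) / (num / den), 0.01)
  }
})

test_that("the computed ratio is strictly decreasing in the anterior deficit", {
  cfg <- quiet_config()
  ratios <- vapply(seq(0, 1, by = 0.1), function(d) {
    ph <- sphincter_phenotype(anterior_deficit = d)
    maneuver_metrics(simulate_pullthrough(ph, cfg))$ratio
  }, numeric(1))
  expect_equal(ratios[1], 1)
  expect_true(all(diff(ratios) < 0))
})

test_that("patient aggregation caps at six maneuvers and drops invalid ones", {
  # direct arithmetic on ratio triples
  ms <- lapply(seq_along(c(0.5, 0.7, 0.9)), function(i) {
    fake_metrics(c(0.5, 0.7, 0.9)[i], id = i)
  })
  s <- aggregate_patient(ms, "pX")
  expect_equal(c(s$ratio_min, s$ratio_mean, s$ratio_max), c(0.5, 0.7, 0.9))
  expect_true(s$ratio_min <= s$ratio_mean && s$ratio_mean <= s$ratio_max)

  # single maneuver: min = mean = max
  s1 <- aggregate_patient(list(fake_metrics(0.6)), "pY")
  expect_equal(s1$ratio_min, s1$ratio_max)
  expect_equal(s1$n_maneuvers_used, 1)

  # eight supplied: only the first six used, in acquisition order
  ms8 <- lapply(1:8, function(i) fake_metrics(i / 10, ant = 10 * i, id = i))
  s8 <- aggregate_patient(ms8, "pZ")
  expect_equal(s8$n_maneuvers_used, 6)
  expect_equal(s8$ratio_max, 0.6)  # maneuvers 7-8 ignored
  expect_equal(s8$ant_max, 60)

  # invalid maneuvers are excluded and tallied
  mix <- list(fake_metrics(0.5, id = 1), fake_metrics(NA, id = 2,
                                                      valid = FALSE),
              fake_metrics(0.9, id = 3))
  sm <- aggregate_patient(mix, "pW")
  expect_equal(sm$n_maneuvers_used, 2)
  expect_equal(sm$n_dropped, 1)
  expect_equal(sm$ratio_mean, 0.7)

  # all invalid: a failure record, not an error
  bad <- aggregate_patient(list(fake_metrics(NA, valid = FALSE)), "pV")
  expect_false(bad$ok)
  expect_true(is.na(bad$ratio_mean))
  expect_error(aggregate_patient(list(), "p0"), "no maneuver")
})
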