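test_that("U statistic equals brute-force pair counting (with ties)", {
  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(1:8, 1)
    n2 <- sample(1:8, 1)
    # integer-valued draws force plenty of ties
    a <- sample(1:6, n1, replace = TRUE)
    b <- sample(1:6, n2, replace = TRUE)
    res <- mann_whitney_u(a, b)
    expect_equal(res$u1, u_pair_count(a, b))
    expect_equal(res$u2, u_pair_count(b, a))
    expect_equal(res$u1 + res$u2, n1 * n2)
    expect_equal(res$statistic_value, min(res$u1, res$u2))
    expect_gte(res$p_value, 0)
    expect_lte(res$p_value, 1)
  }
})

test_that("U handles the textbook corner cases", {
  # perfect separation
  sep <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic_value, 0)

  # fully tied samples: U at its null mean, p = 1
  tied <- mann_whitney_u(c(5, 5, 5), c(5, 5, 5))
  expect_equal(tied$u1, 4.5)
  expect_equal(tied$u2, 4.5)
  expect_equal(tied$p_value, 1)

  # single observation per group
  expect_true(mann_whitney_u(1, 2)$statistic_value %in% c(0, 0.5, 1))
  expect_equal(mann_whitney_u(3, 3)$statistic_value, 0.5)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("U is invariant under strictly monotone transforms", {
  set.seed(55)
  a <- rnorm(10); b <- rnorm(12, 1)
  base <- mann_whitney_u(a, b)
  for (f in list(function(x) exp(x), function(x) x^3,
                 function(x) atan(x) * 5 - 2)) {
    tr <- mann_whitney_u(f(a), f(b))
    expect_equal(tr$statistic_value, base$statistic_value)
    expect_equal(tr$p_value, base$p_value)
  }
})

test_that("approximate p agrees with wilcox.test and with exact enumeration", {
  set.seed(7)
  # against the reference implementation (no ties, no correction)
  for (i in 1:20) {
    a <- rnorm(sample(8:15, 1))
    b <- rnorm(sample(8:15, 1), 0.5)
    ours <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = FALSE)
    expect_equal(min(ours$u1, ours$u2),
                 unname(min(ref$statistic,
                            length(a) * length(b) - ref$statistic)))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # exact enumeration matches the reference exact p (tie-free case)
  for (i in 1:5) {
    a <- rnorm(7); b <- rnorm(8, 0.3)
    expect_equal(mann_whitney_u(a, b, exact = TRUE)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # the uncorrected normal approximation converges on the exact p at the
  # rate set by the discreteness of U: the worst-case two-sided gap stays
  # under ~0.55/sigma_U (about 0.058 at n=8, 0.032 at n=12, 0.023 at n=15)
  for (n in c(8, 12, 15)) {
    tol <- 0.55 / sqrt(n * n * (2 * n + 1) / 12)
    for (i in 1:8) {
      a <- rnorm(n); b <- rnorm(n, 0.3)
      approx_p <- mann_whitney_u(a, b)$p_value
      exact_p <- if (n <= 8) mann_whitney_u(a, b, exact = TRUE)$p_value else
        wilcox.test(a, b, exact = TRUE)$p.value
      expect_lt(abs(approx_p - exact_p), tol)
    }
  }
  # exact enumeration is a genuine permutation p-value on tiny samples
  ex <- mann_whitney_u(c(1, 2), c(3, 4), exact = TRUE)
  expect_equal(ex$p_value, 2 / 6)  # only the two extreme assignments
})

test_that("chi-square matches the closed form and its symmetries", {
  d <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(d$statistic_value, 20)
  expect_equal(d$df, 1L)

  indep <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(indep$statistic_value, 0)
  expect_equal(indep$p_value, 1)

  t3 <- chi_square_2x2(matrix(c(5, 4, 7, 22), 2))  # ((5,7),(4,22))
  expect_equal(t3$statistic_value, 38 * (5 * 22 - 7 * 4)^2 /
                 (12 * 26 * 9 * 29))
  expect_equal(round(t3$statistic_value, 2), 3.14)

  # invariance under transposition and row/column swaps
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    x <- chi_square_2x2(tab)$statistic_value
    expect_equal(chi_square_2x2(t(tab))$statistic_value, x)
    expect_equal(chi_square_2x2(tab[2:1, ])$statistic_value, x)
    expect_equal(chi_square_2x2(tab[, 2:1])$statistic_value, x)
    # cross-check with the reference implementation
    expect_equal(x, unname(suppressWarnings(
      chisq.test(tab, correct = FALSE)$statistic)))
    expect_equal(chi_square_2x2(tab, yates = TRUE)$statistic_value,
                 unname(suppressWarnings(
                   chisq.test(tab, correct = TRUE)$statistic)))
  }

  # zero marginal: undefined statistic as a finding, not an error
  zm <- chi_square_2x2(matrix(c(0, 0, 3, 5), 2, byrow = TRUE))
  expect_true(is.na(zm$statistic_value))
  expect_match(zm$findings, "zero marginal")
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("group report has the nine-row structure with sane p-values", {
  co <- simulate_cohort(simulation_config(seed = 21))
  m <- cohort_metrics(co)
  rep9 <- build_group_report(m)
  expect_equal(nrow(rep9), 9)
  expect_setequal(unique(rep9$metric),
                  c("circumferential", "anterior", "ratio"))
  expect_setequal(unique(rep9$aggregate), c("min", "mean", "max"))
  expect_true(all(rep9$u >= 0 & rep9$u <= rep9$n_a * rep9$n_b))
  # the generator's design forces the anterior ordering
  ant <- rep9[rep9$metric == "anterior" & rep9$aggregate == "mean", ]
  expect_lt(ant$group_a_mean, ant$group_b_mean)

  # identical groups: all p near 1 (every patient duplicated into both)
  p2 <- m$patients
  pa <- p2; pa$group_label <- "A"
  pb <- p2; pb$group_label <- "B"; pb$patient_id <- paste0(pb$patient_id, "x")
  same <- build_group_report(rbind(pa, pb))
  expect_true(all(same$p > 0.9))

  # one patient per group: U in {0, 1/2, 1}
  single <- build_group_report(rbind(pa[1, ], pb[2, ]))
  expect_true(all(single$u %in% c(0, 0.5, 1)))

  # maneuver-level mode uses raw per-maneuver values
  rep_man <- build_group_report(m, unit = "maneuver")
  expect_equal(nrow(rep_man), 3)
  expect_true(all(rep_man$n_a + rep_man$n_b <= nrow(m$maneuvers)))
})

test_that("constipation comparison tabulates, tests and excludes unknowns", {
  df <- data.frame(
    group_label = rep(c("A", "B"), c(12, 26)),
    constipated = c(rep(TRUE, 5), rep(FALSE, 7), rep(TRUE, 4),
                    rep(FALSE, 22)))
  cc <- constipation_comparison(df)
  expect_equal(unname(cc$table[1, ]), c(5, 7))
  expect_equal(unname(cc$table[2, ]), c(4, 22))
  expect_equal(round(cc$test$statistic_value, 2), 3.14)
  expect_equal(cc$n_excluded, 0)

  # unknown flags are excluded and counted
  df$constipated[1:3] <- NA
  cc2 <- constipation_comparison(df)
  expect_equal(cc2$n_excluded, 3)
  expect_equal(sum(cc2$table), 35)

  # all-false flags: zero marginal finding
  df3 <- data.frame(group_label = c("A", "A", "B"),
                    constipated = c(FALSE, FALSE, FALSE))
  cc3 <- constipation_comparison(df3)
  expect_true(is.na(cc3$test$statistic_value))
  expect_match(cc3$test$findings, "zero marginal")

  # a single constipated patient: computation valid, small-count note
  df4 <- data.frame(group_label = rep(c("A", "B"), c(10, 10)),
                    constipated = c(TRUE, rep(FALSE, 19)))
  cc4 <- constipation_comparison(df4)
  expect_false(is.na(cc4$test$statistic_value))
  expect_match(cc4$test$findings, "small counts", all = FALSE)

  # generator defaults at scale: rates near design, p well under 0.05
  co <- simulate_cohort(simulation_config(n_group_a = 1000,
                                          n_group_b = 1000, seed = 14,
                                          maneuvers_distribution =
                                            c(1, rep(0, 9))))
  cc5 <- constipation_comparison(cohort_metrics(co)$patients)
  expect_lt(abs(cc5$proportions[["A"]] - 0.45), 0.05)
  expect_lt(abs(cc5$proportions[["B"]] - 0.15), 0.05)
  expect_lt(cc5$test$p_value, 0.001)
})
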