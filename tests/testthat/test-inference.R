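# The fitting chain: empirical distributions, N(t) fits, cutoff scans,
# age trends and derived rates.

test_that("empirical distribution computes tails and incomplete moments", {
  d <- empirical_distribution(c(1, 2, 12), n_boot = 0)
  expect_equal(d$C_n[d$n == 10], 1 / 3)
  expect_equal(d$C_n[d$n == 0], 1)
  d2 <- empirical_distribution(c(1, 2, 3), n_boot = 0)
  expect_equal(d2$mu1[d2$n == 2] / d2$mu1_total, 0.5)
  # a dataset where exactly a quarter of clones exceed 10 cells
  sizes <- c(rep(2, 75), rep(15, 25))
  d3 <- empirical_distribution(sizes, n_boot = 50)
  expect_equal(d3$C_n[d3$n == 10], 0.25)
  expect_true(all(diff(d3$C_n) <= 0))
  expect_true(all(diff(d3$mu1) >= 0))
  expect_equal(d3$mu1_total, sum(sizes))
  expect_true(all(is.finite(d3$se_C)))
  expect_error(empirical_distribution(numeric(0)), "at least one")
  expect_error(empirical_distribution(c(1, 0)), "at least 1")
})

test_that("noise-free moment curves are recovered exactly", {
  n <- 1:60
  y <- truncated_moment_ratio(n, 60, 25)
  fit <- fit_moment_curve(n, y, 60)
  expect_equal(fit$N_hat, 25, tolerance = 1e-6)
})

test_that("all fit_N methods recover N on model-exact data", {
  pmf <- ongoing_pmf(40, 1)   # integer support: no clonal-unit rounding
  d <- empirical_distribution(expected_count_sample(pmf), n_boot = 0)
  for (meth in c("ls", "moment", "mle")) {
    f <- fit_N(d, M = max(d$sizes), method = meth, n_boot = 0)
    expect_equal(f$N_hat, 40, tolerance = 0.05)
  }
})

test_that("doubling all clone sizes doubles the fitted N", {
  set.seed(42)
  s <- sample_pmf(ongoing_pmf(30, 1), 800)
  f1 <- fit_N(empirical_distribution(s, n_boot = 0),
              M = max(s), method = "moment", n_boot = 0)
  f2 <- fit_N(empirical_distribution(2 * s, n_boot = 0),
              M = 2 * max(s), method = "moment", n_boot = 0)
  expect_equal(f2$N_hat / f1$N_hat, 2, tolerance = 0.03)
})

test_that("bootstrap ranges cover the generating N at roughly nominal rate", {
  set.seed(43)
  pmf <- ongoing_pmf(40, 1/3)
  covered <- replicate(60, {
    s <- sample_pmf(pmf, 300)
    f <- fit_N(empirical_distribution(s, n_boot = 0), method = "mle",
               n_boot = 200)
    f$lower <= 40 && 40 <= f$upper
  })
  expect_gte(mean(covered), 0.85)
})

test_that("fit_N rejects degenerate and out-of-range inputs", {
  d <- empirical_distribution(rep(5, 40), n_boot = 0)
  expect_error(fit_N(d), "degenerate")
  d2 <- empirical_distribution(c(1:3, 30, 40), n_boot = 0)
  expect_error(fit_N(d2, M = 100), "maximum observed")
  expect_error(fit_N(d2, M = 4, method = "ls"), "distinct")
})

test_that("the cutoff scan is stable on model data and unstable on bimodal data", {
  pmf <- ongoing_pmf(40, 1)
  d <- empirical_distribution(expected_count_sample(pmf), n_boot = 0)
  for (meth in c("ls", "mle")) {
    sc <- scan_M(d, method = meth)
    expect_true(sc$stable)
    expect_lt(sc$spread, 0.15)
  }
  # a second mode of large clones breaks M-stability
  set.seed(44)
  s_bad <- c(sample_pmf(ongoing_pmf(20, 1), 400),
             sample(180:220, 120, replace = TRUE))
  sc_bad <- scan_M(empirical_distribution(s_bad, n_boot = 0), method = "mle")
  expect_false(sc_bad$stable)
})

test_that("fitting pulse-labelled data shows the documented ongoing-induction bias", {
  # The ongoing-induction family has an extra 1/n factor; applied to
  # pulse-labelled clones (pure exponential) the moment-ratio fit
  # overestimates the pulse mean by a factor computable from the exact
  # pulse curve. Establish that factor from the noise-free curve, then
  # check sampled fits land near it.
  Np <- 30
  n <- 1:(12 * Np)
  pulse_mu1 <- cumsum(n * exp(-n / Np))          # size-weighted exponential
  y <- pulse_mu1 / pulse_mu1[length(n)]
  bias_factor <- fit_moment_curve(n, y, max(n))$N_hat / Np
  expect_gt(bias_factor, 1)    # the correction matters
  set.seed(45)
  s <- 1 + stats::rgeom(3000, 1 / Np)            # pulse-like geometric sizes
  f <- fit_N(empirical_distribution(s, n_boot = 0), M = max(s),
             method = "ls", n_boot = 0)
  expect_equal(f$N_hat / mean(s), bias_factor, tolerance = 0.15)
})

test_that("age trends recover slope and onset age from exact points", {
  ages <- c(39, 55, 79)
  tr <- fit_age_trend(ages, 2.7 * (ages - 20))
  expect_equal(tr$slope, 2.7, tolerance = 1e-10)
  expect_equal(tr$t0, 20, tolerance = 1e-8)
  # permutation invariance
  perm <- c(3, 1, 2)
  tr2 <- fit_age_trend(ages[perm], (2.7 * (ages - 20))[perm])
  expect_equal(tr2$slope, tr$slope)
  expect_equal(tr2$t0, tr$t0)
  expect_error(fit_age_trend(50, 80), "at least 2")
})

test_that("derived rates follow their exact identities", {
  expect_equal(derive_loss_replacement_rate(2.7, 1/3), 1.8)
  expect_equal(derive_loss_replacement_rate(1.5, 1/3), 1.0)
  expect_equal(derive_loss_replacement_rate(4.2, 1), 8.4)
  expect_equal(per_cell_mutation_rate(100, 1e6), 1e-4)
  expect_equal(per_cell_mutation_rate(60, 1e6), 6e-5)
  expect_equal(per_cell_mutation_rate(0, 1e6), 0)
  sep <- separation_statistics(100, 1e6)
  expect_equal(sep$ratio, 100)
  expect_equal(sep$a_cm, 1 / sqrt(pi * 100))
  expect_equal(separation_statistics(250, 250)$ratio, 1)
  expect_equal(estimate_rho(1/3), 1/3)
  expect_equal(estimate_rho(0.347), 0.347)
  expect_error(estimate_rho(0), "between")
  expect_error(estimate_rho(1), "between")
})

test_that("mutation-rate inversion round-trips the density law", {
  rho <- 1/3; rlambda <- 0.9; slope <- rlambda / rho
  N <- c(55, 100, 160)
  for (R in c(100, 60)) {
    sigma <- clone_density(R, rho, rlambda, N)
    expect_equal(as.numeric(estimate_mutation_rate(sigma, N, slope)), R,
                 tolerance = 1e-6)
  }
  # absolute form for a single observation
  R1 <- estimate_mutation_rate(clone_density(100, rho, rlambda, 80), 80, slope)
  expect_equal(as.numeric(R1), 100, tolerance = 1e-6)
  expect_equal(attr(R1, "form"), "absolute")
  expect_error(estimate_mutation_rate(c(10, 20), c(50, 50), slope),
               "identical")
})

test_that("single-cell clones are more prevalent in non-smokers than smokers", {
  fr <- sapply(1:6, function(seed) {
    cohort <- generate_cohort(cohort_config(seed = seed))
    s <- unlist(lapply(Filter(function(d) d$smoker == 1 && d$age >= 39,
                              cohort), function(d) d$clones$n_cells))
    n <- unlist(lapply(Filter(function(d) d$smoker == 0 && d$age >= 39,
                              cohort), function(d) d$clones$n_cells))
    c(mean(s == 1), mean(n == 1))
  })
  expect_gt(mean(fr[2, ]), mean(fr[1, ]))
})

test_that("cohort estimates are invariant to row order and patient relabeling", {
  cohort <- generate_cohort(cohort_config(seed = 31))
  fit1 <- suppressWarnings(fit_cohort(cohort, n_boot = 0))
  shuffled <- lapply(cohort, function(d) {
    set.seed(d$seed)
    d$clones <- d$clones[sample(nrow(d$clones)), ]
    d
  })
  fit2 <- suppressWarnings(fit_cohort(shuffled[sample(length(shuffled))],
                                      n_boot = 0))
  expect_equal(sort(fit1$patients$N_hat), sort(fit2$patients$N_hat),
               tolerance = 1e-9)
  expect_equal(fit1$groups$smoker$slope, fit2$groups$smoker$slope,
               tolerance = 1e-9)
  relabeled <- cohort
  for (i in seq_along(relabeled))
    relabeled[[i]]$patient_id <- paste0("Q", i)
  names(relabeled) <- paste0("Q", seq_along(relabeled))
  fit3 <- suppressWarnings(fit_cohort(relabeled, n_boot = 0))
  expect_equal(fit3$groups$smoker$two_rlambda,
               fit1$groups$smoker$two_rlambda, tolerance = 1e-9)
})

test_that("cohort fitting reports per-patient and per-group quantities", {
  cohort <- generate_cohort(cohort_config(seed = 8))
  fit <- suppressWarnings(fit_cohort(cohort, n_boot = 30))
  expect_s3_class(fit, "cohort_fit")
  expect_equal(nrow(fit$patients), 7)
  ok <- !is.na(fit$patients$N_hat)
  expect_true(all(fit$patients$lower[ok] <= fit$patients$N_hat[ok]))
  expect_true(all(fit$patients$N_hat[ok] <= fit$patients$upper[ok]))
  for (grp in c("smoker", "nonsmoker")) {
    g <- fit$groups[[grp]]
    expect_false(is.null(g))
    expect_equal(g$two_rlambda, 2 * fit$rho * g$slope, tolerance = 1e-12)
    if (g$R >= 0)
      expect_equal(g$per_cell_rate, g$R / fit$kappa, tolerance = 1e-12)
  }
  # results JSON is written and parseable
  path <- tempfile(fileext = ".json")
  write_results_json(fit, path)
  res <- jsonlite::read_json(path)
  expect_named(res, c("patients", "groups", "settings"))
  unlink(path)
})
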