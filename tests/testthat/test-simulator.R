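# Gillespie simulation of the fate process, the reduced birth-death
# process, and whole-tissue realizations.

smoker <- default_parameters(smoker = TRUE)

test_that("with r = 0 the progenitor count never changes", {
  p0 <- fate_parameters(lambda = 5, r = 0, rho = 1/3, allow_r_zero = TRUE)
  cl <- simulate_clone(p0, duration = 5, n_rep = 200, seed = 101)
  expect_true(all(cl$k_S == 1))
})

test_that("zero duration returns the initial single progenitor", {
  expect_identical(simulate_reduced(0.9, 0, n_rep = 50, seed = 1),
                   rep(1L, 50))
  cl <- simulate_clone(smoker, 0, n_rep = 20, seed = 1)
  expect_true(all(cl$k_S == 1 & cl$k_D == 0))
})

test_that("reduced simulator reproduces the survival probability and survivor mean", {
  n <- 2e4
  k1 <- simulate_reduced(1, 1, n_rep = n, seed = 102)   # tau = 1
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(k1 > 0) - 0.5), 3 * se)
  k4 <- simulate_reduced(1, 4, n_rep = n, seed = 103)   # tau = 4
  mS <- mean(k4[k4 > 0])
  expect_lt(abs(mS - 5), 3 * sd(k4[k4 > 0]) / sqrt(sum(k4 > 0)))
})

test_that("conservation law holds in simulation: overall mean progenitor count stays one", {
  for (tau in c(1, 5)) {
    k <- simulate_reduced(1, tau, n_rep = 2e4, seed = 104 + tau)
    expect_lt(abs(mean(k) - 1), 3 * sd(k) / sqrt(length(k)))
  }
})

test_that("survivor sizes are geometric (chi-square against the closed form)", {
  k <- simulate_reduced(1, 1, n_rep = 2e4, seed = 106)
  surv <- k[k > 0]
  pmf <- progenitor_pmf_pulse(1, 1, tail = 1e-12)
  # bin the tail so expected counts stay above 5
  kmax <- max(which(pmf$mass * length(surv) > 5))
  obs <- c(tabulate(pmin(surv, kmax + 1), nbins = kmax + 1))
  pr <- c(pmf$mass[seq_len(kmax)], 1 - sum(pmf$mass[seq_len(kmax)]))
  expect_gt(chisq.test(obs, p = pr)$p.value, 0.01)
})

test_that("reduced and full simulators agree on the progenitor-count marginal", {
  dur <- 4
  kr <- simulate_reduced(smoker$rlambda, dur, n_rep = 1e4, seed = 107)
  cl <- simulate_clone(smoker, dur, n_rep = 1e4, seed = 108)
  p <- suppressWarnings(ks.test(kr, cl$k_S))$p.value
  expect_gt(p, 0.01)
})

test_that("clone composition settles at the progenitor fraction rho", {
  cl <- simulate_clone(smoker, duration = 20, n_rep = 4000, seed = 109)
  surv <- cl[cl$k_S >= 1, ]
  frac <- sum(surv$k_S) / sum(surv$n)
  se <- sd(surv$k_S / surv$n) / sqrt(nrow(surv))
  expect_lt(abs(frac - smoker$rho), 4 * se + 0.01)
})

test_that("simulation is reproducible from its seed", {
  a <- simulate_tissue(smoker, 0.5, 60, seed = 110)
  b <- simulate_tissue(smoker, 0.5, 60, seed = 110)
  expect_identical(a$clones, b$clones)
  expect_false(identical(
    simulate_tissue(smoker, 0.5, 60, seed = 111)$clones, a$clones))
})

test_that("tissue induction counts follow the thinned Poisson rate", {
  n_rep <- 200
  counts <- vapply(seq_len(n_rep), function(i)
    nrow(simulate_tissue(smoker, 0.1, 40, seed = 200 + i)$clones), 0)
  expected <- smoker$rho * smoker$R_area * 0.1 * (40 - smoker$t0)
  se <- sqrt(expected / n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # all birth times lie between onset and observation
  tis <- simulate_tissue(smoker, 0.5, 60, seed = 201)
  expect_true(all(tis$clones$birth_time >= smoker$t0))
  expect_true(all(tis$clones$birth_time <= 60))
})

test_that("surviving-clone density matches the logarithmic clone-density law", {
  # in clonal units (rho = 1, N = 1 + r*lambda*t) the law is exact:
  # density = (rho*R/rlambda) * ln(1 + r*lambda*(t - t0))
  n_rep <- 60
  dens <- vapply(seq_len(n_rep), function(i)
    surviving_density(simulate_tissue(smoker, 0.5, 60, seed = 300 + i),
                      progenitor_only = TRUE), 0)
  expected <- clone_density(smoker$rho * smoker$R_area, 1, smoker$rlambda,
                            1 + smoker$rlambda * (60 - smoker$t0))
  expect_lt(abs(mean(dens) - expected), 2 * sd(dens) / sqrt(n_rep))
})

test_that("clone density rises logarithmically with age at slope rho*R/rlambda", {
  ages <- c(30, 40, 55, 70, 85)
  dens <- sapply(ages, function(a) {
    mean(vapply(1:25, function(i)
      surviving_density(simulate_tissue(smoker, 0.4, a, seed = 400 + 31 * a + i),
                        progenitor_only = TRUE), 0))
  })
  x <- log(1 + smoker$rlambda * (ages - smoker$t0))
  fit <- summary(lm(dens ~ x))
  slope_expected <- smoker$rho * smoker$R_area / smoker$rlambda
  expect_lt(abs(coef(fit)[2, 1] - slope_expected), 2.5 * coef(fit)[2, 2])
})

test_that("tissue progenitor counts follow the ongoing-induction distribution", {
  tis <- simulate_tissue(smoker, 12, 50, seed = 500)
  k <- tis$clones$k_S[tis$clones$k_S >= 1]
  rhoN <- 1 + smoker$rlambda * (50 - smoker$t0)
  pmf <- ongoing_progenitor_pmf(rhoN / smoker$rho, smoker$rho, tail = 1e-10)
  set.seed(501)
  expect_gt(ks_test_discrete(k, pmf, n_mc = 200), 0.01)
})

test_that("merging only joins overlapping discs and conserves mutant cells", {
  base <- simulate_tissue(smoker, 1, 60, seed = 600)
  # two far-apart clones are untouched
  far <- base
  far$clones <- data.frame(clone_id = 1:2, birth_time = c(30, 40),
                           k_S = c(5L, 3L), k_D = c(10L, 6L), n = c(15L, 9L),
                           x = c(0.1, 0.9), y = c(0.1, 0.9))
  merged <- apply_merger(far, kappa = 1e6)
  expect_equal(nrow(merged$clones), 2)
  expect_equal(sort(merged$clones$n), c(9L, 15L))
  # cell conservation and monotone clone count on a dense realization
  m2 <- apply_merger(base, kappa = 1e4)   # artificially sparse cells = big discs
  expect_equal(sum(m2$clones$n), sum(base$clones$n))
  expect_lte(nrow(m2$clones), nrow(base$clones))
  expect_error(apply_merger(local({
    b <- base
    b$clones$x[which(b$clones$n >= 1)[1]] <- NA
    b
  })), "positions")
})

test_that("merger frequency matches the Poisson disc-overlap expectation", {
  # equal-size clones of n cells merge when centres fall within twice the
  # clone radius; the package formula evaluated at 4n gives that
  # probability, since (2 r_n)^2 = 4 n / (pi kappa)
  n_cells <- 50L; kappa <- 1e6; area <- 4; sigma <- 100
  set.seed(601)
  n_rep <- 40
  frac <- vapply(seq_len(n_rep), function(i) {
    m <- rpois(1, sigma * area)
    side <- sqrt(area)
    tis <- structure(list(
      clones = data.frame(clone_id = seq_len(m), birth_time = 0,
                          k_S = 1L, k_D = n_cells - 1L, n = n_cells,
                          x = runif(m, 0, side), y = runif(m, 0, side)),
      area = area, observation_age = 60, onset_age = 20,
      params = default_parameters(TRUE), seed = NULL),
      class = "tissue_realization")
    merged <- apply_merger(tis, kappa = kappa)
    1 - sum(merged$clones$n == n_cells) / m   # fraction absorbed into mergers
  }, 0)
  expected <- merger_probability(4 * n_cells, kappa, sigma)
  expect_lt(abs(mean(frac) - expected),
            2 * sd(frac) / sqrt(n_rep) + 0.1 * expected)
})

test_that("nearest-centre geometry reproduces the merger probability and separation density", {
  # a disc of radius r_n around a clone contains another centre with
  # probability 1 - exp(-n*sigma/kappa)
  n_cells <- 200; kappa <- 1e6; sigma <- 300
  r_n <- sqrt(n_cells / (pi * kappa))
  set.seed(602)
  n_rep <- 3000
  hits <- vapply(seq_len(n_rep), function(i) {
    m <- rpois(1, sigma)          # unit square, intensity sigma
    if (m == 0) return(0)
    d2 <- (runif(m) - 0.5)^2 + (runif(m) - 0.5)^2
    as.numeric(min(d2) < r_n^2)
  }, 0)
  expected <- merger_probability(n_cells, kappa, sigma)
  expect_lt(abs(mean(hits) - expected), 2 * sd(hits) / sqrt(n_rep))
  # nearest-neighbour distances are KS-consistent with the closed-form density
  set.seed(603)
  nn <- vapply(seq_len(2000), function(i) {
    m <- rpois(1, sigma)
    if (m == 0) return(NA_real_)
    sqrt(min((runif(m) - 0.5)^2 + (runif(m) - 0.5)^2))
  }, 0)
  nn <- nn[!is.na(nn) & nn < 0.4]   # stay clear of boundary effects
  a <- 1 / sqrt(pi * sigma)
  cdf <- function(q) (1 - exp(-(q / a)^2)) / (1 - exp(-(0.4 / a)^2))
  expect_gt(ks.test(nn, cdf)$p.value, 0.01)
})
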