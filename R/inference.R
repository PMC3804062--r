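# The fitting chain: empirical cumulative distributions and incomplete
# moments, the cutoff-robust fit of the mean clone size N(t), the age
# regression giving the loss/replacement clock and the onset age, and the
# derived physiological rates.

#' Empirical clone-size distribution
#'
#' Computes, on the integer size grid, the cumulative tail C_n (fraction
#' of clones larger than n cells) and the first incomplete moment mu1(n)
#' (total cells in clones of size at most n), with bootstrap-over-clones
#' standard errors for C_n.
#'
#' @param sizes Integer clone sizes, all at least 1.
#' @param n_boot Bootstrap resamples for the standard errors (0 to skip).
#' @return An object of class `empirical_clone_distribution`: list with
#'   `sizes` (sorted), `n` (grid 0..max), `C_n`, `se_C`, `mu1`,
#'   `mu1_total`.
#' @examples
#' d <- empirical_distribution(c(1, 2, 12))
#' d$C_n[d$n == 10]  # 1/3: one clone out of three exceeds 10 cells
#' @export
empirical_distribution <- function(sizes, n_boot = 200) {
  sizes <- as.numeric(sizes)
  if (length(sizes) == 0L) stop("at least one clone size is required")
  if (anyNA(sizes) || any(sizes < 1) || any(sizes != round(sizes)))
    stop("clone sizes must be integers of at least 1")
  sizes <- sort(sizes)
  m <- length(sizes)
  n <- 0:max(sizes)
  counts <- tabulate(sizes, nbins = max(sizes))
  C_n <- 1 - cumsum(c(0, counts)) / m
  mu1 <- cumsum(c(0, counts * seq_along(counts)))
  se_C <- rep(NA_real_, length(n))
  if (n_boot > 0) {
    boot <- matrix(0, nrow = n_boot, ncol = length(n))
    for (b in seq_len(n_boot)) {
      s <- sizes[sample.int(m, m, replace = TRUE)]
      boot[b, ] <- 1 - cumsum(c(0, tabulate(s, nbins = max(sizes)))) / m
    }
    se_C <- apply(boot, 2, sd)
  }
  structure(
    list(sizes = sizes, n = n, C_n = C_n, se_C = se_C,
         mu1 = mu1, mu1_total = mu1[length(mu1)]),
    class = "empirical_clone_distribution"
  )
}

#' @export
print.empirical_clone_distribution <- function(x, ...) {
  cat(sprintf(
    "Empirical clone-size distribution: %d clones, %d mutant cells, max size %d\n",
    length(x$sizes), as.integer(x$mu1_total), as.integer(max(x$sizes))))
  invisible(x)
}

#' Fit the mean clone size to a moment-ratio curve
#'
#' Least-squares fit of observed incomplete-moment ratios y_n =
#' mu1(n)/mu1(M) to the model curve (1 - exp(-n/N)) / (1 - exp(-M/N))
#' over the supplied grid. This is the low-level deterministic fitter;
#' [fit_N()] adds the empirical-curve construction and bootstrap ranges.
#'
#' @param n Size grid (cells).
#' @param y Observed moment ratios at `n`.
#' @param M Cutoff used to normalize `y`.
#' @return List with `N_hat` and `residual` (sum of squares).
#' @export
fit_moment_curve <- function(n, y, M) {
  stopifnot(length(n) == length(y), length(n) >= 2, all(n <= M))
  obj <- function(logN) {
    sum((y - truncated_moment_ratio(n, M, exp(logN)))^2)
  }
  opt <- optimize(obj, lower = log(0.2), upper = log(200 * M),
                  tol = 1e-12)
  list(N_hat = exp(opt$minimum), residual = opt$objective)
}

.moment_ratio_curve <- function(sizes, M) {
  n <- seq_len(M)
  counts <- tabulate(pmin(sizes, M + 1), nbins = M + 1)[seq_len(M)]
  mu1 <- cumsum(counts * n)
  if (mu1[M] <= 0) return(NULL)
  list(n = n, y = mu1 / mu1[M])
}

.default_M <- function(sizes, method) {
  if (method == "ls") max(quantile(sizes, 0.9, type = 1, names = FALSE), 5)
  else max(sizes)
}

# Point estimators behind fit_N. All see only sizes <= M.
.estimate_N <- function(sizes, M, method, n_min) {
  m_is_cutoff <- M < max(sizes)
  sizes <- sizes[sizes <= M]
  if (method == "ls") {
    curve <- .moment_ratio_curve(sizes, M)
    if (is.null(curve)) return(NULL)
    return(fit_moment_curve(curve$n, curve$y, M))
  }
  if (method == "moment") {
    # match the cell-weighted mean mu2/mu1 of the exponential the first
    # incomplete moment is predicted to follow
    emp <- sum(sizes^2) / sum(sizes)
    if (emp <= 1) return(NULL)
    q <- 1 - sum(sizes) / sum(sizes^2)
    N <- -1 / log(q)
    return(list(N_hat = N, residual = NA_real_))
  }
  # method == "mle": maximum likelihood of the predicted size
  # distribution p_n ~ exp(-n/N)/n restricted to sizes >= n_min, where the
  # clonal-unit smearing and doomed small clones do not distort the form
  s <- sizes[sizes >= n_min]
  if (length(s) < 10) return(NULL)
  # an M below the sample maximum is a real cutoff and truncates the
  # family; otherwise the family is unbounded (numerically, far past M)
  n_max <- if (m_is_cutoff) M else max(1000, 12 * max(s))
  n <- n_min:n_max
  nll <- function(logN) {
    N <- exp(logN)
    sum(s) / N + length(s) * log(sum(exp(-n / N) / n))
  }
  opt <- optimize(nll, c(log(2), log(5e4)), tol = 1e-9)
  list(N_hat = exp(opt$minimum), residual = opt$objective)
}

#' Fit the mean clone size N(t) for one patient
#'
#' Estimates the mean size N(t) of the oldest surviving clones from the
#' observed clone sizes, under the model prediction that the first
#' incomplete moment follows a saturating exponential with constant 1/N.
#' Three estimators are available:
#'
#' * `"ls"` (default): least squares of the cutoff-normalized moment
#'   ratio mu1(n)/mu1(M) against [truncated_moment_ratio()] over the
#'   integer sizes 1..M — the classical curve fit, with default cutoff at
#'   the 90th-percentile clone size to exclude rare-event fluctuations.
#' * `"moment"`: closed-form matching of the cell-weighted mean
#'   mu2(M)/mu1(M) to the exponential the incomplete moment is predicted
#'   to follow; robust to the shape of the small-size prefactor and to
#'   clone miscounting at small sizes. Default M is the maximum size.
#' * `"mle"`: maximum likelihood of the predicted size distribution
#'   proportional to exp(-n/N)/n, restricted to sizes of at least
#'   `n_min`; the most precise option. Sizes below `n_min` are excluded
#'   because there the clonal-unit granularity (about 1/rho cells per
#'   progenitor) and doomed basal-cell-free clones distort the continuum
#'   form. Default M is the maximum size.
#'
#' The acceptable range of N is the 2.5/97.5 percentile of refits over
#' bootstrap resamples of the clones.
#'
#' @param dist An [empirical_clone_distribution].
#' @param M Large-size cutoff (cells); at most the maximum observed size,
#'   with at least 5 distinct sizes below it.
#' @param method Estimator, see Details.
#' @param n_min Small-size floor for `method = "mle"` (cells).
#' @param n_boot Bootstrap resamples for the acceptable range.
#' @param level Coverage of the bootstrap percentile range.
#' @return An object of class `n_fit`: list with `N_hat`, `lower`,
#'   `upper`, `M`, `method`, `residual`, `n_clones`.
#' @export
fit_N <- function(dist, M = NULL, method = c("ls", "moment", "mle"),
                  n_min = 5, n_boot = 500, level = 0.95) {
  stopifnot(inherits(dist, "empirical_clone_distribution"))
  method <- match.arg(method)
  sizes <- dist$sizes
  if (length(unique(sizes)) < 2)
    stop("degenerate input: all clone sizes are equal, ",
         "the size distribution carries no information about N")
  if (is.null(M)) M <- .default_M(sizes, method)
  M <- as.integer(M)
  if (M > max(sizes)) stop("`M` must not exceed the maximum observed size")
  if (length(unique(sizes[sizes < M])) < 5)
    stop("at least 5 distinct clone sizes below `M` are required")
  fit <- .estimate_N(sizes, M, method, n_min)
  if (is.null(fit))
    stop("clone sizes carry too little usable signal for method '",
         method, "' at this cutoff")
  lower <- upper <- NA_real_
  if (n_boot > 0) {
    m <- length(sizes)
    boot <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      s <- sizes[sample.int(m, m, replace = TRUE)]
      fb <- .estimate_N(s, M, method, n_min)
      if (!is.null(fb)) boot[b] <- fb$N_hat
    }
    qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                   na.rm = TRUE, names = FALSE)
    lower <- min(qs[1], fit$N_hat)
    upper <- max(qs[2], fit$N_hat)
  }
  structure(
    list(N_hat = fit$N_hat, lower = lower, upper = upper, M = M,
         method = method, residual = fit$residual,
         n_clones = length(sizes)),
    class = "n_fit"
  )
}

#' @export
print.n_fit <- function(x, ...) {
  cat(sprintf("N(t) fit (%s): N_hat = %.2f cells [%.2f, %.2f], M = %d, %d clones\n",
              x$method, x$N_hat, x$lower, x$upper, x$M, x$n_clones))
  invisible(x)
}

#' Scan the large-size cutoff M
#'
#' Refits N across a set of cutoffs and flags stability when the fitted
#' values vary by less than `threshold` (relative spread about the
#' median). By default the cutoffs are the 75th/90th/95th-percentile and
#' the maximum clone size, operationalizing the requirement that the fit
#' depend only weakly on where rare large clones are excluded.
#'
#' @param dist An [empirical_clone_distribution].
#' @param M_values Integer cutoffs (at least 2 after filtering); defaults
#'   as described.
#' @param threshold Relative spread below which the scan is stable.
#' @param method Estimator passed to [fit_N()].
#' @return An object of class `m_scan`: list with `table` (M, N_hat,
#'   residual), `stable`, `spread`.
#' @export
scan_M <- function(dist, M_values = NULL, threshold = 0.15,
                   method = "ls") {
  stopifnot(inherits(dist, "empirical_clone_distribution"))
  sizes <- dist$sizes
  if (is.null(M_values)) {
    M_values <- unique(c(
      quantile(sizes, c(0.75, 0.9, 0.95), type = 1, names = FALSE),
      max(sizes)))
  }
  M_values <- sort(unique(as.integer(M_values)))
  M_values <- M_values[vapply(M_values, function(M)
    M <= max(sizes) && length(unique(sizes[sizes < M])) >= 5, logical(1))]
  if (length(M_values) < 2)
    stop("at least 2 usable cutoffs are required")
  fits <- lapply(M_values, function(M)
    fit_N(dist, M = M, method = method, n_boot = 0))
  tab <- data.frame(
    M = M_values,
    N_hat = vapply(fits, `[[`, 0, "N_hat"),
    residual = vapply(fits, `[[`, 0, "residual")
  )
  # a cutoff well below N leaves the fit unidentified (the truncated curve
  # is flat in N); such fits run to large values and are excluded from the
  # stability assessment
  tab$identified <- tab$N_hat < 50 * tab$M
  idd <- tab$N_hat[tab$identified]
  if (length(idd) >= 2) {
    spread <- (max(idd) - min(idd)) / median(idd)
    stable <- spread < threshold
  } else {
    spread <- Inf
    stable <- FALSE
  }
  structure(list(table = tab, stable = stable, spread = spread),
            class = "m_scan")
}

#' @export
print.m_scan <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("relative spread %.1f%% — %s\n", 100 * x$spread,
              if (x$stable) "stable" else "NOT stable"))
  invisible(x)
}

#' Age trend of the mean clone size
#'
#' Weighted least squares of fitted N(t) values on patient age within one
#' exposure group. The slope estimates the loss/replacement clock over
#' the progenitor fraction, r*lambda/rho (cells/year), and the age at
#' which the fitted line crosses N = 0 estimates the onset age t0 at
#' which mutant clones first become visible. Uncertainty is propagated
#' either from the regression alone or, when per-patient acceptable
#' ranges are supplied, by Monte-Carlo redraws of the N values.
#'
#' @param ages Patient ages (years), at least 2.
#' @param N_hats Fitted mean clone sizes (cells), same length.
#' @param weights Optional regression weights.
#' @param ranges Optional 2-column matrix (lower, upper) of per-patient
#'   acceptable ranges used for Monte-Carlo propagation.
#' @param n_draws Monte-Carlo draws when `ranges` is given.
#' @return An object of class `age_trend_fit`: list with `slope`,
#'   `slope_se`, `t0`, `t0_se`, `t0_range`, `intercept`, `fit` (the lm).
#' @examples
#' f <- fit_age_trend(c(39, 55, 79), 2.7 * (c(39, 55, 79) - 20))
#' c(f$slope, f$t0)  # 2.7 and 20
#' @export
fit_age_trend <- function(ages, N_hats, weights = NULL, ranges = NULL,
                          n_draws = 500) {
  if (length(ages) < 2 || length(N_hats) != length(ages))
    stop("at least 2 patients of the same exposure group are required")
  df <- data.frame(age = ages, N = N_hats)
  fit <- lm(N ~ age, data = df, weights = weights)
  b <- coef(fit)
  slope <- unname(b[2])
  if (!is.finite(slope) || slope == 0)
    stop("degenerate age trend: slope is zero or undefined")
  t0 <- unname(-b[1] / b[2])
  V <- suppressWarnings(vcov(fit))   # perfect fits trip summary.lm
  slope_se <- sqrt(V[2, 2])
  # delta method for t0 = -b0/b1
  g <- c(-1 / b[2], b[1] / b[2]^2)
  t0_se <- sqrt(as.numeric(t(g) %*% V %*% g))
  t0_range <- c(NA_real_, NA_real_)
  if (!is.null(ranges)) {
    ranges <- as.matrix(ranges)
    stopifnot(nrow(ranges) == length(ages), ncol(ranges) == 2)
    sds <- (ranges[, 2] - ranges[, 1]) / (2 * qnorm(0.975))
    draws_t0 <- draws_slope <- rep(NA_real_, n_draws)
    for (i in seq_len(n_draws)) {
      Ni <- stats::rnorm(length(ages), N_hats, sds)
      bi <- coef(lm(Ni ~ ages, weights = weights))
      draws_slope[i] <- bi[2]
      draws_t0[i] <- -bi[1] / bi[2]
    }
    slope_se <- sd(draws_slope, na.rm = TRUE)
    t0_se <- sd(draws_t0, na.rm = TRUE)
    t0_range <- quantile(draws_t0, c(0.025, 0.975), na.rm = TRUE,
                         names = FALSE)
  }
  structure(
    list(slope = slope, slope_se = slope_se, t0 = t0, t0_se = t0_se,
         t0_range = t0_range, intercept = unname(b[1]), fit = fit),
    class = "age_trend_fit"
  )
}

#' @export
print.age_trend_fit <- function(x, ...) {
  cat(sprintf(
    "Age trend: slope %.2f +/- %.2f cells/year; onset t0 = %.1f +/- %.1f years\n",
    x$slope, x$slope_se, x$t0, x$t0_se))
  invisible(x)
}

#' Progenitor loss/replacement rate
#'
#' Converts the N(t)-vs-age slope (an estimate of r*lambda/rho) into the
#' loss/replacement rate 2*r*lambda = 2 * rho * slope: the rate at which
#' any given progenitor is lost and replaced by a duplicating neighbour.
#'
#' @param slope Age-trend slope (cells/year), positive.
#' @param rho Progenitor fraction, in (0, 1].
#' @return Rate per year.
#' @examples
#' derive_loss_replacement_rate(2.7, 1/3)  # 1.8 per year
#' @export
derive_loss_replacement_rate <- function(slope, rho) {
  if (any(slope <= 0)) stop("`slope` must be positive")
  if (any(rho <= 0) || any(rho > 1)) stop("`rho` must lie in (0, 1]")
  2 * rho * slope
}

#' Visible mutation rate from clone densities
#'
#' Inverts the logarithmic density relation sigma = (rho*R/(r*lambda)) *
#' log(N) on density differences: R = (delta sigma / delta log N) * slope
#' with slope = r*lambda/rho, so any additive density offset cancels.
#' With more than two (density, N) pairs the difference quotient is the
#' least-squares slope of density on log(N). With a single pair the
#' absolute form R = sigma * slope / log(N) is used and the result is
#' labelled accordingly (attribute `form = "absolute"`).
#'
#' @param densities Surviving-clone densities (clones/cm^2) at two or
#'   more ages (one allowed for the absolute form).
#' @param N_hats Fitted mean clone sizes (cells) at the same ages; must
#'   not all be equal.
#' @param slope Age-trend slope r*lambda/rho (cells/year).
#' @return Mutation rate (mutations/year/cm^2) with attribute `form`
#'   ("difference" or "absolute").
#' @export
estimate_mutation_rate <- function(densities, N_hats, slope) {
  stopifnot(length(densities) == length(N_hats), length(densities) >= 1)
  if (any(N_hats <= 1)) stop("`N_hats` must exceed 1")
  if (slope <= 0) stop("`slope` must be positive")
  if (length(densities) == 1L) {
    R <- densities * slope / log(N_hats)
    attr(R, "form") <- "absolute"
    return(R)
  }
  if (max(N_hats) - min(N_hats) == 0)
    stop("`N_hats` must not be identical (delta log N is zero)")
  b <- coef(lm(densities ~ log(N_hats)))
  R <- unname(b[2]) * slope
  attr(R, "form") <- "difference"
  R
}

#' Per-cell visible mutation rate
#'
#' @param R Mutation rate (mutations/year/cm^2), non-negative.
#' @param kappa Cell density (cells/cm^2), positive.
#' @return Rate per cell per year, `R / kappa`.
#' @examples
#' per_cell_mutation_rate(100, 1e6)  # 1e-4 per cell per year
#' @export
per_cell_mutation_rate <- function(R, kappa) {
  if (any(R < 0)) stop("`R` must be non-negative")
  if (any(kappa <= 0)) stop("`kappa` must be positive")
  R / kappa
}

#' Clone separation statistics
#'
#' The typical nearest-neighbour separation scale of a Poisson clone
#' pattern, a = (pi*sigma)^(-1/2), and its ratio to the cell diameter,
#' (kappa/sigma)^(1/2) — about 100 cell diameters at a density of
#' 100 clones/cm^2 and 1e6 cells/cm^2.
#'
#' @param sigma Clone density (clones/cm^2), positive.
#' @param kappa Cell density (cells/cm^2), positive.
#' @return List with `a_cm` and `ratio`.
#' @export
separation_statistics <- function(sigma, kappa) {
  if (any(sigma <= 0) || any(kappa <= 0))
    stop("`sigma` and `kappa` must be positive")
  list(a_cm = 1 / sqrt(pi * sigma), ratio = sqrt(kappa / sigma))
}

#' Progenitor fraction from the basal-cell share
#'
#' The progenitor fraction rho is estimated by the basal-cell share of
#' the epithelium under the assumption that basal cells comprise the
#' tissue-maintaining population. This is a documented pass-through: no
#' hidden rounding is applied, so a measured share of 0.347 stays 0.347 —
#' rounding to 1/3 is the caller's explicit choice.
#'
#' @param basal_fraction Basal-cell fraction, strictly between 0 and 1.
#' @return The same fraction.
#' @export
estimate_rho <- function(basal_fraction) {
  if (any(basal_fraction <= 0) || any(basal_fraction >= 1))
    stop("`basal_fraction` must lie strictly between 0 and 1")
  basal_fraction
}

#' Full inference chain over a patient cohort
#'
#' For each patient with enough clones: empirical distribution, cutoff
#' scan and N(t) fit at the default cutoff. Per exposure group (smokers
#' and non-smokers separately): age trend of N(t) giving the slope
#' r*lambda/rho and onset age t0, the loss/replacement rate
#' 2*r*lambda = 2*rho*slope, the mutation rate R from the density-vs-
#' log(N) relation, the per-cell rate R/kappa, and separation statistics
#' at the group's mean clone density.
#'
#' @param datasets List of `patient_dataset` objects (as produced by
#'   [generate_cohort()] or [read_clone_table()]).
#' @param rho Progenitor fraction used for rate conversions.
#' @param kappa Cell density (cells/cm^2).
#' @param method Per-patient estimator passed to [fit_N()]; the default
#'   `"mle"` is the most precise at a few hundred clones per patient.
#' @param n_boot Bootstrap resamples per patient fit (0 to skip ranges).
#' @param min_clones Patients with fewer clones are excluded from fitting
#'   (with a warning).
#' @param weights Age-regression weighting: `"fitted"` (default) iterates
#'   weighted least squares with weights 1/fitted(N)^2, matching the
#'   roughly constant relative error of the per-patient fits without
#'   coupling the weights to their noise; `"none"` for ordinary least
#'   squares.
#' @return An object of class `cohort_fit`: list with `patients` (per-
#'   patient table), `groups` (per-exposure-group estimates), `rho`,
#'   `kappa`.
#' @export
fit_cohort <- function(datasets, rho = 1/3, kappa = 1e6, method = "mle",
                       n_boot = 200, min_clones = 20,
                       weights = c("fitted", "none")) {
  if (inherits(datasets, "patient_dataset")) datasets <- list(datasets)
  if (length(datasets) == 0L) stop("no patient datasets supplied")
  weights <- match.arg(weights)
  rows <- list()
  for (d in datasets) {
    stopifnot(inherits(d, "patient_dataset"))
    m <- nrow(d$clones)
    row <- data.frame(patient_id = d$patient_id, age = d$age,
                      smoker = d$smoker, area = d$area, n_clones = m,
                      density = m / d$area, N_hat = NA_real_,
                      lower = NA_real_, upper = NA_real_,
                      M = NA_integer_, stable = NA)
    if (m >= min_clones) {
      dist <- empirical_distribution(d$clones$n_cells, n_boot = 0)
      fit <- try(fit_N(dist, method = method, n_boot = n_boot),
                 silent = TRUE)
      scan <- try(scan_M(dist, method = method), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        row$N_hat <- fit$N_hat
        row$lower <- fit$lower
        row$upper <- fit$upper
        row$M <- fit$M
      }
      if (!inherits(scan, "try-error")) row$stable <- scan$stable
    } else {
      warning("patient ", d$patient_id, " has fewer than ", min_clones,
              " clones and is excluded from fitting", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- row
  }
  patients <- do.call(rbind, rows)
  rownames(patients) <- NULL

  groups <- list()
  for (grp in c("smoker", "nonsmoker")) {
    sel <- patients$smoker == (grp == "smoker") & !is.na(patients$N_hat)
    g <- patients[sel, , drop = FALSE]
    if (nrow(g) < 2) {
      if (nrow(g) > 0)
        warning("group '", grp, "' has fewer than 2 fitted patients; ",
                "no age trend estimated", call. = FALSE)
      next
    }
    w <- NULL
    if (weights == "fitted") {
      for (it in 1:3) {
        f0 <- lm(g$N_hat ~ g$age, weights = w)
        w <- 1 / pmax(fitted(f0), 5)^2
      }
    }
    ranges <- if (!anyNA(g$lower) && !anyNA(g$upper))
      cbind(g$lower, g$upper) else NULL
    trend <- fit_age_trend(g$age, g$N_hat, weights = w, ranges = ranges)
    two_rlambda <- derive_loss_replacement_rate(trend$slope, rho)
    R <- estimate_mutation_rate(g$density, g$N_hat, trend$slope)
    sigma <- mean(g$density)
    groups[[grp]] <- list(
      n_patients = nrow(g),
      slope = trend$slope, slope_se = trend$slope_se,
      t0 = trend$t0, t0_se = trend$t0_se, t0_range = trend$t0_range,
      two_rlambda = two_rlambda,
      R = as.numeric(R), R_form = attr(R, "form"),
      per_cell_rate = if (as.numeric(R) >= 0)
        per_cell_mutation_rate(as.numeric(R), kappa) else NA_real_,
      mean_density = sigma,
      separation = separation_statistics(sigma, kappa)
    )
  }
  structure(list(patients = patients, groups = groups, rho = rho,
                 kappa = kappa),
            class = "cohort_fit")
}

#' @export
print.cohort_fit <- function(x, ...) {
  cat("Cohort fit (rho =", format(x$rho), ")\n\nPer patient:\n")
  print(x$patients, row.names = FALSE, digits = 3)
  for (grp in names(x$groups)) {
    g <- x$groups[[grp]]
    cat(sprintf(paste0(
      "\n%s (%d patients):\n",
      "  slope r*lambda/rho   : %.2f +/- %.2f cells/year\n",
      "  onset age t0         : %.1f +/- %.1f years\n",
      "  loss/replacement 2rl : %.2f /year\n",
      "  mutation rate R      : %.1f /year/cm^2 (%s form)\n",
      "  per-cell rate        : %.2g /cell/year\n",
      "  separation           : %.0f cell diameters (a = %.3f cm)\n"),
      grp, g$n_patients, g$slope, g$slope_se, g$t0, g$t0_se,
      g$two_rlambda, g$R, g$R_form, g$per_cell_rate,
      g$separation$ratio, g$separation$a_cm))
  }
  invisible(x)
}

#' Write cohort-fit results as JSON
#'
#' @param fit A [fit_cohort()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(fit, path) {
  stopifnot(inherits(fit, "cohort_fit"))
  out <- list(patients = fit$patients, groups = fit$groups,
              settings = list(rho = fit$rho, kappa = fit$kappa))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
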