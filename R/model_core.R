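# Closed-form clone-size theory of the neutral-drift model: survival
# probabilities and size distributions under pulse labelling and ongoing
# induction, the incomplete-moment fitting curves, and the spatial
# merger-risk formulas.

#' Discrete clone-size distribution
#'
#' Light container for a probability mass function over positive integer
#' clone sizes. Tails are truncated where the remaining mass drops below a
#' stated threshold, so masses sum to 1 minus at most that threshold.
#'
#' @param support Strictly increasing positive integer sizes (cells).
#' @param mass Non-negative probabilities, one per support point.
#' @return A data frame of class `clone_size_pmf` with columns `support`
#'   and `mass`.
#' @seealso [progenitor_pmf_pulse()], [ongoing_pmf()]
#' @export
clone_size_pmf <- function(support, mass) {
  support <- as.numeric(support)
  mass <- as.numeric(mass)
  if (length(support) != length(mass) || length(support) == 0L)
    stop("`support` and `mass` must be non-empty and of equal length")
  if (any(support < 1) || any(support != round(support)))
    stop("`support` must contain positive integers")
  if (any(diff(support) <= 0))
    stop("`support` must be strictly increasing")
  if (any(mass < 0)) stop("`mass` must be non-negative")
  if (sum(mass) > 1 + 1e-9) stop("`mass` must not sum to more than 1")
  structure(data.frame(support = support, mass = mass),
            class = c("clone_size_pmf", "data.frame"))
}

#' @export
print.clone_size_pmf <- function(x, ...) {
  cat(sprintf("Clone-size pmf on %d sizes in [%d, %d], total mass %.9f\n",
              nrow(x), as.integer(min(x$support)),
              as.integer(max(x$support)), sum(x$mass)))
  invisible(x)
}

#' Mean of a clone-size pmf
#'
#' @param pmf A [clone_size_pmf] object.
#' @return The mean size over the (truncated, renormalized) support.
#' @export
pmf_mean <- function(pmf) {
  stopifnot(inherits(pmf, "clone_size_pmf"))
  sum(pmf$support * pmf$mass) / sum(pmf$mass)
}

#' Sample clone sizes from a pmf
#'
#' @param pmf A [clone_size_pmf] object.
#' @param n Number of draws.
#' @return Integer vector of sampled sizes.
#' @export
sample_pmf <- function(pmf, n) {
  stopifnot(inherits(pmf, "clone_size_pmf"), n >= 1)
  pmf$support[sample.int(nrow(pmf), n, replace = TRUE, prob = pmf$mass)]
}

#' Clone survival probability after pulse labelling
#'
#' Under critical neutral drift a clone founded by a single progenitor at
#' time zero survives to time `t` with probability 1 / (1 + r*lambda*t).
#'
#' @param rlambda Drift clock r*lambda (per year), non-negative.
#' @param t Time since labelling (years), non-negative. Vectorized.
#' @return Survival probability in (0, 1].
#' @export
survival_probability_pulse <- function(rlambda, t) {
  if (any(rlambda < 0)) stop("`rlambda` must be non-negative")
  if (any(t < 0)) stop("`t` must be non-negative")
  1 / (1 + rlambda * t)
}

#' Progenitor-number distribution of surviving pulse-labelled clones
#'
#' The critical birth-death process started from one progenitor has, at
#' drift time tau = r*lambda*t and conditional on survival, a geometric
#' progenitor-number distribution P(n) = (1/tau) * (1 + 1/tau)^(-n) with
#' mean 1 + tau. The mean of survivors grows to compensate exactly for
#' clone loss, so (mean among survivors) x (survival probability) = 1.
#'
#' @param rlambda Drift clock r*lambda (per year).
#' @param t Time since labelling (years); `rlambda * t` must be positive
#'   (at tau = 0 the distribution is degenerate at one cell and is not
#'   represented as a pmf — handle that case explicitly).
#' @param tail Truncate the support where the remaining tail mass falls
#'   below this value.
#' @return A [clone_size_pmf] over progenitor counts n >= 1.
#' @export
progenitor_pmf_pulse <- function(rlambda, t, tail = 1e-9) {
  tau <- rlambda * t
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`rlambda * t` must be a single positive number")
  q <- tau / (1 + tau)
  # tail mass beyond n is exactly q^n
  n_max <- max(2, ceiling(log(tail) / log(q)))
  n <- seq_len(n_max)
  clone_size_pmf(n, (1 / tau) * q^n) # (1/tau)(1+1/tau)^-n
}

#' Mean total clone size under pulse labelling
#'
#' Each surviving progenitor supports on average a clonal unit of 1/rho
#' total cells, so the mean total size of surviving clones is
#' N(t) = (1 + r*lambda*t) / rho, linear in time with slope r*lambda/rho.
#'
#' @param rlambda Drift clock r*lambda (per year).
#' @param t_since_onset Time since labelling/onset (years), non-negative.
#' @param rho Progenitor fraction, in (0, 1].
#' @return Mean clone size in cells. Vectorized over `t_since_onset`.
#' @export
mean_clone_size <- function(rlambda, t_since_onset, rho) {
  if (any(t_since_onset < 0)) stop("`t_since_onset` must be non-negative")
  if (any(rho <= 0) || any(rho > 1)) stop("`rho` must lie in (0, 1]")
  (1 + rlambda * t_since_onset) / rho
}

#' Scaling-limit clone-size density after pulse labelling
#'
#' In the long-time limit the geometric distribution of surviving clone
#' sizes converges to the exponential density (1/N) * exp(-n/N).
#'
#' @param n Clone size (cells), non-negative; vectorized.
#' @param N Mean clone size (cells), positive.
#' @return Probability density at `n`.
#' @export
scaling_density_pulse <- function(n, N) {
  if (any(N <= 0)) stop("`N` must be positive")
  if (any(n < 0)) stop("`n` must be non-negative")
  exp(-n / N) / N
}

#' Progenitor-number distribution under ongoing clone induction
#'
#' With clones induced uniformly in time since onset, the surviving-clone
#' progenitor count k >= 1 is distributed with mass proportional to
#' exp(-k / (rho*N)) / k, the discrete analogue of the 1/n * exp(-n/N)
#' continuum form; the exact normalization is -log(1 - exp(-1/(rho*N))).
#' `rho * N` equals 1 + r*lambda*t, the mean progenitor count of the
#' oldest surviving clones.
#'
#' @param N Mean size of the oldest clones (cells); `rho * N` must
#'   exceed 1.
#' @param rho Progenitor fraction in (0, 1].
#' @param tail Truncation threshold for the remaining tail mass.
#' @return A [clone_size_pmf] over progenitor counts.
#' @export
ongoing_progenitor_pmf <- function(N, rho, tail = 1e-9) {
  stopifnot(length(N) == 1L, length(rho) == 1L)
  if (rho <= 0 || rho > 1) stop("`rho` must lie in (0, 1]")
  if (rho * N <= 1)
    stop("`rho * N` must exceed 1: the ongoing-induction form is only ",
         "valid once surviving clones have drifted (rho*N = 1 + r*lambda*t)")
  q <- exp(-1 / (rho * N))
  norm <- -log(1 - q)
  # crude upper bound for the support, then trim by the exact tail
  k_max <- max(10, ceiling(-rho * N * log(tail * (1 - q))))
  k <- seq_len(k_max)
  m <- q^k / k / norm
  keep <- rev(cumsum(rev(m))) > tail
  if (!any(keep)) keep[1] <- TRUE
  clone_size_pmf(k[keep], m[keep])
}

#' Total clone-size distribution under ongoing induction
#'
#' Maps the progenitor-count distribution of [ongoing_progenitor_pmf()] to
#' total cells by the deterministic clonal-unit scaling n = k / rho
#' (rounded to the nearest integer, at least 1): each progenitor supports
#' on average 1/rho cells. The continuum form of the result is
#' exp(-n/N) / (n * log(rho*N)), monotonically decreasing in n with the
#' featureless 1/n dependence at small sizes.
#'
#' @inheritParams ongoing_progenitor_pmf
#' @param n_max Optional truncation of the returned support; rejected if
#'   the mass beyond it exceeds 1e-6.
#' @param tail Truncation threshold for the remaining tail mass.
#' @return A [clone_size_pmf] over total clone sizes.
#' @export
ongoing_pmf <- function(N, rho, n_max = NULL, tail = 1e-9) {
  kp <- ongoing_progenitor_pmf(N, rho, tail = tail)
  n <- pmax(1, round(kp$support / rho))
  mass <- as.numeric(tapply(kp$mass, n, sum))
  support <- sort(unique(n))
  if (!is.null(n_max)) {
    drop <- support > n_max
    if (sum(mass[drop]) > 1e-6)
      stop("`n_max` truncates more than 1e-6 of the mass; increase it")
    support <- support[!drop]
    mass <- mass[!drop]
  }
  clone_size_pmf(support, mass)
}

#' Clone survival probability under ongoing induction
#'
#' The fraction of all mutation events since onset that are represented by
#' a surviving clone at time `t`: (rho / (r*lambda*t)) * log(N). Together
#' with the induction rate this gives the clone density, see
#' [clone_density()]; the identity density = R * t * survival holds by
#' construction.
#'
#' @param rlambda Drift clock r*lambda (per year); `rlambda * t` positive.
#' @param t Time since onset (years).
#' @param rho Progenitor fraction.
#' @param N Mean size of the oldest clones (cells), must exceed 1/rho.
#' @return Probability in (0, 1].
#' @export
survival_probability_ongoing <- function(rlambda, t, rho, N) {
  if (any(rlambda * t <= 0)) stop("`rlambda * t` must be positive")
  if (any(N <= 1 / rho)) stop("`N` must exceed 1/rho")
  p <- (rho / (rlambda * t)) * log(N)
  if (any(p > 1))
    stop("parameters outside the model's validity range: ",
         "computed survival probability exceeds 1")
  p
}

#' Surviving clone density under ongoing induction
#'
#' sigma = (rho * R / (r*lambda)) * log(N): the density of surviving
#' clones grows only logarithmically with the mean clone size (and hence
#' with age), the signature of neutral loss of most induced clones.
#'
#' @param R_area Visible-mutation rate (mutations/year/cm^2).
#' @param rho Progenitor fraction.
#' @param rlambda Drift clock r*lambda (per year).
#' @param N Mean size of the oldest clones (cells), at least 1.
#' @return Clone density (clones/cm^2). Vectorized over `N`.
#' @export
clone_density <- function(R_area, rho, rlambda, N) {
  if (any(R_area <= 0) || any(rho <= 0) || any(rlambda <= 0))
    stop("`R_area`, `rho` and `rlambda` must be positive")
  if (any(N < 1)) stop("`N` must be at least 1")
  (rho * R_area / rlambda) * log(N)
}

#' Model first incomplete moment (normalized)
#'
#' Under the exponential size distribution the cumulative size-weighted
#' mass below `n`, normalized by its limit, is 1 - exp(-n/N). Its
#' complement decays purely exponentially with constant 1/N, which is what
#' the fitting chain exploits.
#'
#' @param n Clone size (cells), non-negative; vectorized.
#' @param N Mean clone size (cells), positive.
#' @return Fraction in \[0, 1).
#' @export
incomplete_moment_model <- function(n, N) {
  if (any(n < 0)) stop("`n` must be non-negative")
  if (any(N <= 0)) stop("`N` must be positive")
  1 - exp(-n / N)
}

#' Cutoff-normalized incomplete-moment ratio
#'
#' mu1(n)/mu1(M) = (1 - exp(-n/N)) / (1 - exp(-M/N)) for a large-size
#' cutoff `M` beyond which rare large clones would otherwise dominate the
#' statistic. Reduces to [incomplete_moment_model()] as M grows.
#'
#' @param n Clone size (cells), 0 <= n <= M; vectorized.
#' @param M Cutoff size (cells).
#' @param N Mean clone size (cells), positive.
#' @return Fraction in \[0, 1\].
#' @export
truncated_moment_ratio <- function(n, M, N) {
  if (any(n < 0)) stop("`n` must be non-negative")
  if (any(n > M)) stop("`n` must not exceed the cutoff `M`")
  if (any(N <= 0)) stop("`N` must be positive")
  expm1(-n / N) / expm1(-M / N)
}

#' Nearest-neighbour clone separation density
#'
#' For clones scattered as a 2-D Poisson pattern of intensity `sigma`, the
#' nearest-neighbour separation r has density
#' (2/a) * (r/a) * exp(-(r/a)^2) with scale a = (pi * sigma)^(-1/2).
#'
#' @param separation Separation r (cm), non-negative; vectorized.
#' @param sigma Clone density (clones/cm^2), positive.
#' @return Density per cm.
#' @export
nn_distance_density <- function(separation, sigma) {
  if (any(sigma <= 0)) stop("`sigma` must be positive")
  if (any(separation < 0)) stop("`separation` must be non-negative")
  a <- 1 / sqrt(pi * sigma)
  (2 / a) * (separation / a) * exp(-(separation / a)^2)
}

#' Probability that a clone overlaps a neighbour
#'
#' A clone of `n` cells at cell density `kappa` occupies a disc of radius
#' (n / (pi*kappa))^(1/2); the chance that another clone centre falls
#' within reach on a Poisson background of density `sigma` is
#' 1 - exp(-(r_n/a)^2) = 1 - exp(-n * sigma / kappa), increasing in `n`.
#'
#' @param n Clone size (cells), non-negative; vectorized.
#' @param kappa Cell density (cells/cm^2), positive.
#' @param sigma Clone density (clones/cm^2), positive.
#' @return Merger probability in \[0, 1).
#' @export
merger_probability <- function(n, kappa, sigma) {
  if (any(n < 0)) stop("`n` must be non-negative")
  if (any(kappa <= 0) || any(sigma <= 0))
    stop("`kappa` and `sigma` must be positive")
  -expm1(-n * sigma / kappa)
}
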