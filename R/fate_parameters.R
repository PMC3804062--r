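#' Fate-model parameters
#'
#' Bundle of the constants of the neutral-drift fate model shared by the
#' closed-form theory, the stochastic simulator and the cohort generator.
#' Progenitor cells divide at rate `lambda`; a division is symmetric
#' duplicating (two progenitors) with probability `r`, symmetric
#' differentiating (two post-mitotic cells) with probability `r`, and
#' asymmetric otherwise. Differentiated cells are shed at rate `gamma`,
#' which is not free: homeostasis of the cell composition requires
#' `rho * lambda == (1 - rho) * gamma`, where `rho` is the progenitor
#' fraction of all cells, so `gamma` is derived from the other parameters.
#'
#' @param lambda Progenitor division rate (events/year).
#' @param r Probability of each symmetric division outcome; the key
#'   combination r*lambda sets the neutral-drift clock. Must lie in
#'   (0, 0.5] (at r = 0 every division is asymmetric and clones never
#'   drift; the simulator accepts 0, the parameter object requires > 0
#'   unless `allow_r_zero = TRUE`).
#' @param rho Progenitor fraction of the total cell population, in (0, 1).
#' @param R_area Visible-mutation induction rate (mutations/year/cm^2,
#'   counted over all cells; only the fraction `rho` landing in progenitors
#'   founds persistent clones).
#' @param t0 Patient age at which mutant clones first become visible (years).
#' @param kappa Total cell density of the epithelium (cells/cm^2).
#' @param allow_r_zero Permit r = 0 (invariant asymmetric division), used
#'   for degenerate-limit checks.
#'
#' @return An object of class `fate_parameters`: a list with fields
#'   `lambda`, `r`, `rho`, `gamma`, `R_area`, `t0`, `kappa` and the derived
#'   `rlambda = r * lambda`.
#' @examples
#' p <- fate_parameters(lambda = 9, r = 0.1, rho = 1/3)
#' p$gamma  # derived from the homeostasis condition
#' @export
fate_parameters <- function(lambda = 9, r = 0.1, rho = 1/3,
                            R_area = 100, t0 = 20, kappa = 1e6,
                            allow_r_zero = FALSE) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(rho), length(rho) == 1L, is.finite(rho))
  if (lambda <= 0) stop("`lambda` must be positive")
  if (r < 0 || r > 0.5) stop("`r` must lie in [0, 0.5]")
  if (r == 0 && !allow_r_zero)
    stop("`r` = 0 gives invariant asymmetric division; ",
         "set `allow_r_zero = TRUE` if that limit is intended")
  if (rho <= 0 || rho >= 1)
    stop("`rho` must lie strictly between 0 and 1 (homeostasis requires ",
         "a differentiated compartment)")
  if (R_area <= 0) stop("`R_area` must be positive")
  if (t0 < 0) stop("`t0` must be non-negative")
  if (kappa <= 0) stop("`kappa` must be positive")
  gamma <- rho * lambda / (1 - rho)
  structure(
    list(lambda = lambda, r = r, rho = rho, gamma = gamma,
         R_area = R_area, t0 = t0, kappa = kappa, rlambda = r * lambda),
    class = "fate_parameters"
  )
}

#' Reference parameter sets for the smoker and non-smoker groups
#'
#' The loss/replacement clock differs between exposure groups:
#' r\*lambda = 0.9/year for smokers and 0.5/year for non-smokers,
#' with visible-mutation rates of 100 and 60 mutations/year/cm^2
#' respectively. Both groups share `rho = 1/3`, onset age 20 years and a
#' cell density of 1e6/cm^2. The split of r*lambda into its factors is
#' not identifiable from clone sizes; r = 0.1 is adopted as a typical
#' epithelial value, so `lambda` is 9/year (smokers) or 5/year
#' (non-smokers). Only the product affects any reported statistic.
#'
#' @param smoker Logical; pick the smoker or non-smoker parameter set.
#' @return A [fate_parameters] object.
#' @examples
#' default_parameters(smoker = TRUE)$rlambda   # 0.9 per year
#' default_parameters(smoker = FALSE)$R_area   # 60 per year per cm^2
#' @export
default_parameters <- function(smoker = TRUE) {
  if (smoker) {
    fate_parameters(lambda = 9, r = 0.1, rho = 1/3, R_area = 100,
                    t0 = 20, kappa = 1e6)
  } else {
    fate_parameters(lambda = 5, r = 0.1, rho = 1/3, R_area = 60,
                    t0 = 20, kappa = 1e6)
  }
}

#' @export
print.fate_parameters <- function(x, ...) {
  cat("Neutral-drift fate parameters\n")
  cat(sprintf("  division rate lambda : %g /year\n", x$lambda))
  cat(sprintf("  symmetric prob r     : %g\n", x$r))
  cat(sprintf("  drift clock r*lambda : %g /year\n", x$rlambda))
  cat(sprintf("  progenitor frac rho  : %g\n", x$rho))
  cat(sprintf("  shedding rate gamma  : %g /year (derived)\n", x$gamma))
  cat(sprintf("  mutation rate R      : %g /year/cm^2\n", x$R_area))
  cat(sprintf("  onset age t0         : %g years\n", x$t0))
  cat(sprintf("  cell density kappa   : %g /cm^2\n", x$kappa))
  invisible(x)
}
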