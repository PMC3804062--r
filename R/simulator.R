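# Exact continuous-time (Gillespie) simulation of the fate process, of its
# reduced critical birth-death form, and of whole-tissue realizations with
# Poisson clone induction and optional spatial clone merging. The event
# loops live in src/gillespie.cpp; all randomness flows through R's RNG so
# a single seed makes every realization reproducible.

#' Simulate clones under the two-compartment fate process
#'
#' Each clone starts as a single progenitor. Progenitors divide at rate
#' `lambda` with outcomes S+S (probability `r`), D+D (probability `r`) and
#' S+D (otherwise); differentiated cells are shed at rate `gamma`. Event
#' scheduling is exact Gillespie — clones stay small (tens to a few
#' hundred cells), so no approximate leaping is needed.
#'
#' @param params A [fate_parameters] object.
#' @param duration Simulated time span (years), non-negative.
#' @param n_rep Number of independent clones to simulate.
#' @param seed Optional integer seed set before simulating.
#' @return A data frame with one row per clone and columns `k_S`
#'   (progenitors), `k_D` (differentiated cells) and `n = k_S + k_D`.
#'   A clone is extinct when `n == 0` and surviving (for progenitor-level
#'   statistics) when `k_S >= 1`.
#' @examples
#' p <- default_parameters(smoker = TRUE)
#' clones <- simulate_clone(p, duration = 10, n_rep = 100, seed = 1)
#' mean(clones$k_S == 0)  # most clones drift to extinction
#' @export
simulate_clone <- function(params, duration, n_rep = 1, seed = NULL) {
  stopifnot(inherits(params, "fate_parameters"))
  if (length(duration) != 1L || !is.finite(duration) || duration < 0)
    stop("`duration` must be a single non-negative number")
  if (n_rep < 1) stop("`n_rep` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  m <- cpp_simulate_clones(params$lambda, params$r, params$gamma,
                           rep(duration, n_rep))
  data.frame(k_S = m[, 1], k_D = m[, 2], n = m[, 1] + m[, 2])
}

#' Simulate the reduced critical birth-death process
#'
#' Tracks progenitors only: each is duplicated or lost at equal rates,
#' with total per-cell event rate `2 * rlambda`. Conditional on survival
#' the progenitor count at drift time tau = rlambda * duration is
#' geometric with mean 1 + tau (see [progenitor_pmf_pulse()]), and
#' (mean among survivors) x (survival fraction) = 1.
#'
#' @param rlambda Drift clock r*lambda (per year), non-negative.
#' @param duration Simulated time span (years), non-negative.
#' @param n_rep Number of replicates.
#' @param seed Optional integer seed.
#' @return Integer vector of progenitor counts at `duration`.
#' @export
simulate_reduced <- function(rlambda, duration, n_rep = 1, seed = NULL) {
  if (length(rlambda) != 1L || rlambda < 0)
    stop("`rlambda` must be a single non-negative number")
  if (length(duration) != 1L || duration < 0)
    stop("`duration` must be a single non-negative number")
  if (n_rep < 1) stop("`n_rep` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  cpp_simulate_reduced(rlambda, duration, as.integer(n_rep))
}

#' Simulate a whole-tissue realization with ongoing clone induction
#'
#' Visible mutations arise over the surveyed area as a Poisson process of
#' intensity `params$R_area * area` per year between the onset age
#' `params$t0` and `observation_age`, over all cells; the fraction
#' `params$rho` landing in progenitors founds clones, each evolved by the
#' fate process from its birth time to the observation age. Positions are
#' uniform on a square of the given area. Extinct clones are retained
#' with zero size so survival fractions can be computed; clones with
#' `k_S = 0` but `k_D > 0` are doomed but still visible.
#'
#' @param params A [fate_parameters] object.
#' @param area Surveyed tissue area (cm^2), positive.
#' @param observation_age Patient age at observation (years), at least
#'   `params$t0`.
#' @param seed Optional integer root seed for the realization.
#' @return An object of class `tissue_realization`: a list with fields
#'   `clones` (data frame: `clone_id`, `birth_time`, `k_S`, `k_D`, `n`,
#'   `x`, `y`), `area`, `observation_age`, `onset_age`, `params`, `seed`.
#' @examples
#' p <- default_parameters(smoker = TRUE)
#' tis <- simulate_tissue(p, area = 0.5, observation_age = 60, seed = 7)
#' surviving_density(tis)  # clones per cm^2
#' @export
simulate_tissue <- function(params, area, observation_age, seed = NULL) {
  stopifnot(inherits(params, "fate_parameters"))
  if (length(area) != 1L || area <= 0) stop("`area` must be positive")
  if (observation_age < params$t0)
    stop("`observation_age` must be at least the onset age `t0`")
  if (!is.null(seed)) set.seed(seed)
  span <- observation_age - params$t0
  founding_rate <- params$rho * params$R_area * area
  m <- rpois(1, founding_rate * span)
  side <- sqrt(area)
  if (m > 0) {
    births <- params$t0 + sort(runif(m, 0, span))
    states <- cpp_simulate_clones(params$lambda, params$r, params$gamma,
                                  observation_age - births)
    clones <- data.frame(
      clone_id = seq_len(m),
      birth_time = births,
      k_S = states[, 1],
      k_D = states[, 2],
      n = states[, 1] + states[, 2],
      x = runif(m, 0, side),
      y = runif(m, 0, side)
    )
  } else {
    clones <- data.frame(clone_id = integer(), birth_time = numeric(),
                         k_S = integer(), k_D = integer(), n = integer(),
                         x = numeric(), y = numeric())
  }
  structure(
    list(clones = clones, area = area, observation_age = observation_age,
         onset_age = params$t0, params = params, seed = seed),
    class = "tissue_realization"
  )
}

#' @export
print.tissue_realization <- function(x, ...) {
  surv <- sum(x$clones$n >= 1)
  cat(sprintf(paste0(
    "Tissue realization: %.3g cm^2 at age %g (onset %g)\n",
    "  %d induced clones, %d visible (%.1f /cm^2)\n"),
    x$area, x$observation_age, x$onset_age,
    nrow(x$clones), surv, surv / x$area))
  invisible(x)
}

#' Density of visible clones in a tissue realization
#'
#' @param realization A `tissue_realization`.
#' @param progenitor_only Count only clones that still contain a
#'   progenitor (`k_S >= 1`) rather than all visible clones (`n >= 1`);
#'   the two differ by the short-lived doomed-but-visible clones.
#' @return Clones per cm^2.
#' @export
surviving_density <- function(realization, progenitor_only = FALSE) {
  stopifnot(inherits(realization, "tissue_realization"))
  keep <- if (progenitor_only) realization$clones$k_S >= 1
          else realization$clones$n >= 1
  sum(keep) / realization$area
}

#' Merge spatially overlapping clones
#'
#' Models each visible clone as a disc of radius (n / (pi*kappa))^(1/2)
#' and merges transitively every group of overlapping discs into a single
#' clone with summed cell counts, the size-weighted centroid position and
#' the earliest birth time. Total mutant cell numbers are conserved; the
#' clone count can only decrease. This is the observation-side artefact a
#' whole-mount census cannot undo: two abutting patches are scored as one.
#'
#' @param realization A `tissue_realization` whose visible clones all
#'   carry positions.
#' @param kappa Cell density (cells/cm^2); defaults to the realization's
#'   parameters.
#' @return A new `tissue_realization` with merged visible clones (extinct
#'   clones are carried through unchanged).
#' @export
apply_merger <- function(realization, kappa = NULL) {
  stopifnot(inherits(realization, "tissue_realization"))
  if (is.null(kappa)) kappa <- realization$params$kappa
  cl <- realization$clones
  vis <- cl[cl$n >= 1, , drop = FALSE]
  if (nrow(vis) && (anyNA(vis$x) || anyNA(vis$y)))
    stop("all visible clones must have positions")
  if (nrow(vis) < 2) return(realization)
  radius <- sqrt(vis$n / (pi * kappa))
  comp <- .disc_components(vis$x, vis$y, radius)
  merged <- do.call(rbind, lapply(split(seq_len(nrow(vis)), comp), function(i) {
    w <- vis$n[i] / sum(vis$n[i])
    data.frame(birth_time = min(vis$birth_time[i]),
               k_S = sum(vis$k_S[i]), k_D = sum(vis$k_D[i]),
               n = sum(vis$n[i]),
               x = sum(w * vis$x[i]), y = sum(w * vis$y[i]))
  }))
  ext <- cl[cl$n < 1, c("birth_time", "k_S", "k_D", "n", "x", "y"),
            drop = FALSE]
  out <- rbind(merged, ext)
  out <- out[order(out$birth_time), , drop = FALSE]
  out <- cbind(clone_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  realization$clones <- out
  realization
}

# Connected components of overlapping discs via a spatial grid and
# union-find; discs i, j overlap when dist <= r_i + r_j.
.disc_components <- function(x, y, r) {
  m <- length(x)
  cell <- max(2 * max(r), 1e-12)
  gx <- floor(x / cell)
  gy <- floor(y / cell)
  key <- paste(gx, gy)
  buckets <- split(seq_len(m), key)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (b in names(buckets)) {
    ij <- as.numeric(strsplit(b, " ", fixed = TRUE)[[1]])
    idx <- unlist(lapply(c(-1, 0, 1), function(dx)
      lapply(c(-1, 0, 1), function(dy)
        buckets[[paste(ij[1] + dx, ij[2] + dy)]])), use.names = FALSE)
    here <- buckets[[b]]
    for (i in here) {
      for (j in idx) {
        if (j <= i) next
        d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
        if (d2 <= (r[i] + r[j])^2) unite(i, j)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}
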