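# Synthetic patient cohorts with the statistical structure the inference
# chain assumes: seven patients (three smokers aged 39/55/79, a 25-year-old
# and three further non-smokers aged 47/57/65), clone densities of order
# 100/cm^2 and broad clone-size distributions, exported as tab-separated
# clone tables.

#' Reference cohort layout
#'
#' One row per patient: three smokers (ages 39, 55, 79) and four
#' non-smokers (25, 47, 57, 65). The 25-year-old lies only just past the
#' clone-visibility onset age and is expected to carry few or no visible
#' clones. Surveyed areas are not part of the published patient
#' characteristics; the default of 1.25 cm^2 per patient is calibrated so
#' that the cohort yields on the order of 800-900 patches in total
#' (100-300 per older patient), which keeps the per-patient fits
#' well-conditioned.
#'
#' @param area_cm2 Surveyed area per patient (cm^2).
#' @return Data frame with columns `patient_id`, `age`, `smoker`, `area`.
#' @export
default_patients <- function(area_cm2 = 1.25) {
  data.frame(
    patient_id = paste0("P", 1:7),
    age = c(39, 55, 79, 25, 47, 57, 65),
    smoker = c(1L, 1L, 1L, 0L, 0L, 0L, 0L),
    area = area_cm2
  )
}

#' Cohort generation configuration
#'
#' @param patients Data frame with columns `patient_id`, `age`, `smoker`
#'   (0/1), `area` (cm^2); defaults to [default_patients()].
#' @param smoker_params,nonsmoker_params [fate_parameters] for each
#'   exposure group; defaults to [default_parameters()].
#' @param seed Integer root seed; per-patient streams are split from it
#'   deterministically.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(patients = default_patients(),
                          smoker_params = default_parameters(smoker = TRUE),
                          nonsmoker_params = default_parameters(smoker = FALSE),
                          seed = 1L) {
  req <- c("patient_id", "age", "smoker", "area")
  if (!is.data.frame(patients) || !all(req %in% names(patients)))
    stop("`patients` must be a data frame with columns ",
         paste(req, collapse = ", "))
  if (anyDuplicated(patients$patient_id))
    stop("`patient_id` values must be unique")
  if (any(!is.finite(patients$age)) || any(patients$age <= 0))
    stop("ages must be positive")
  if (any(!is.finite(patients$area)) || any(patients$area <= 0))
    stop("areas must be positive")
  if (!all(patients$smoker %in% c(0, 1)))
    stop("`smoker` must be 0 or 1")
  stopifnot(inherits(smoker_params, "fate_parameters"),
            inherits(nonsmoker_params, "fate_parameters"))
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("`seed` must be a single integer")
  structure(
    list(patients = patients, smoker_params = smoker_params,
         nonsmoker_params = nonsmoker_params, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic patient cohort
#'
#' Runs one whole-tissue realization per patient (see [simulate_tissue()])
#' with the exposure group's parameters and collects the visible clones
#' into per-patient datasets. The basal-cell count column reports the
#' clone's simulated progenitor compartment `k_S`.
#'
#' @param config A [cohort_config].
#' @return A list of `patient_dataset` objects, each a list with fields
#'   `patient_id`, `age`, `smoker`, `area`, `clones` (data frame:
#'   `clone_id`, `n_cells`, `n_basal`, `x_cm`, `y_cm`), and
#'   `total_cells_scanned`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' sapply(cohort, function(d) nrow(d$clones))
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_pat <- nrow(config$patients)
  seeds <- sample.int(.Machine$integer.max - 1L, n_pat)
  out <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    p <- config$patients[i, ]
    params <- if (p$smoker == 1) config$smoker_params else config$nonsmoker_params
    if (p$age < params$t0)
      stop("patient ", p$patient_id, " is younger than the onset age t0")
    tis <- simulate_tissue(params, area = p$area,
                           observation_age = p$age, seed = seeds[i])
    vis <- tis$clones[tis$clones$n >= 1, , drop = FALSE]
    clones <- data.frame(
      clone_id = seq_len(nrow(vis)),
      n_cells = vis$n,
      n_basal = vis$k_S,
      x_cm = vis$x,
      y_cm = vis$y
    )
    out[[i]] <- structure(
      list(patient_id = p$patient_id, age = p$age,
           smoker = as.integer(p$smoker), area = p$area, clones = clones,
           total_cells_scanned = round(p$area * params$kappa),
           seed = seeds[i]),
      class = "patient_dataset"
    )
  }
  names(out) <- config$patients$patient_id
  out
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat(sprintf(
    "Patient %s: age %g, %s, %.3g cm^2 — %d clones (%d mutant cells)\n",
    x$patient_id, x$age, if (x$smoker) "smoker" else "non-smoker",
    x$area, nrow(x$clones), sum(x$clones$n_cells)))
  invisible(x)
}

.clone_table_columns <- c("patient_id", "age_years", "smoker", "area_cm2",
                          "clone_id", "n_cells")

#' Write patient datasets as a clone table
#'
#' Tab-separated UTF-8 text with a header row and columns `patient_id`,
#' `age_years`, `smoker` (0/1), `area_cm2`, `clone_id`, `n_cells`,
#' `n_basal`, `x_cm`, `y_cm`, ordered by patient then clone id. A patient
#' with no visible clones is preserved as a single row with empty
#' `clone_id` and `n_cells` so that the round trip is lossless.
#'
#' @param datasets List of `patient_dataset` objects (or a single one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clone_table <- function(datasets, path) {
  if (inherits(datasets, "patient_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    stopifnot(inherits(d, "patient_dataset"))
    if (nrow(d$clones) == 0L) {
      data.frame(patient_id = d$patient_id, age_years = d$age,
                 smoker = d$smoker, area_cm2 = d$area,
                 clone_id = NA_integer_, n_cells = NA_integer_,
                 n_basal = NA_integer_, x_cm = NA_real_, y_cm = NA_real_)
    } else {
      cl <- d$clones[order(d$clones$clone_id), , drop = FALSE]
      data.frame(patient_id = d$patient_id, age_years = d$age,
                 smoker = d$smoker, area_cm2 = d$area,
                 clone_id = cl$clone_id, n_cells = cl$n_cells,
                 n_basal = if ("n_basal" %in% names(cl)) cl$n_basal else NA_integer_,
                 x_cm = if ("x_cm" %in% names(cl)) cl$x_cm else NA_real_,
                 y_cm = if ("y_cm" %in% names(cl)) cl$y_cm else NA_real_)
    }
  })
  tab <- do.call(rbind, rows)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a clone table
#'
#' Strictly validates the schema written by [write_clone_table()]:
#' mandatory columns must be present, clone sizes must be integers of at
#' least 1 (an empty `n_cells` is only allowed on a zero-clone marker
#' row), and patient metadata must be constant within a patient.
#' Malformed rows are reported with their line numbers.
#'
#' @param path Path to a tab-separated clone table.
#' @return A list of `patient_dataset` objects.
#' @export
read_clone_table <- function(path) {
  tab <- read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.clone_table_columns, names(tab))
  if (length(missing_cols))
    stop("clone table is missing mandatory columns: ",
         paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(tab)) + 1L   # header is line 1
  bad <- !is.na(tab$n_cells) &
    (tab$n_cells < 1 | tab$n_cells != round(tab$n_cells))
  bad <- bad | (is.na(tab$n_cells) & !is.na(tab$clone_id))
  bad <- bad | is.na(tab$patient_id) | is.na(tab$age_years) |
    tab$age_years <= 0 | !(tab$smoker %in% c(0, 1)) |
    is.na(tab$area_cm2) | tab$area_cm2 <= 0
  if (any(bad))
    stop("malformed clone-table rows at line(s): ",
         paste(line[bad], collapse = ", "))
  out <- lapply(split(tab, factor(tab$patient_id, unique(tab$patient_id))),
                function(g) {
    if (length(unique(g$age_years)) != 1L ||
        length(unique(g$smoker)) != 1L ||
        length(unique(g$area_cm2)) != 1L)
      stop("inconsistent metadata for patient ", g$patient_id[1])
    keep <- !is.na(g$clone_id)
    clones <- data.frame(
      clone_id = as.integer(g$clone_id[keep]),
      n_cells = as.integer(g$n_cells[keep]),
      n_basal = if ("n_basal" %in% names(g)) as.integer(g$n_basal[keep])
                else rep(NA_integer_, sum(keep)),
      x_cm = if ("x_cm" %in% names(g)) g$x_cm[keep]
             else rep(NA_real_, sum(keep)),
      y_cm = if ("y_cm" %in% names(g)) g$y_cm[keep]
             else rep(NA_real_, sum(keep))
    )
    structure(
      list(patient_id = g$patient_id[1], age = g$age_years[1],
           smoker = as.integer(g$smoker[1]), area = g$area_cm2[1],
           clones = clones, total_cells_scanned = NA_real_, seed = NA),
      class = "patient_dataset"
    )
  })
  names(out) <- vapply(out, `[[`, "", "patient_id")
  out
}
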