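# Reporting: cumulative-distribution and incomplete-moment figures with
# model overlays, the N(t)-vs-age panel, and the headless pipeline that
# ties generation, fitting and reporting together.

utils::globalVariables(c("n", "C_n", "value", "patient", "age", "N_hat",
                         "lower", "upper", "group"))

.dataset_frame <- function(datasets, fit = NULL) {
  do.call(rbind, lapply(datasets, function(d) {
    if (nrow(d$clones) == 0L) return(NULL)
    dist <- empirical_distribution(d$clones$n_cells, n_boot = 0)
    lab <- sprintf("%s (%s, %g y)", d$patient_id,
                   if (d$smoker) "smoker" else "non-smoker", d$age)
    data.frame(patient = lab, n = dist$n, C_n = dist$C_n,
               one_minus_mu = 1 - dist$mu1 / dist$mu1_total)
  }))
}

#' Cumulative clone-size distributions
#'
#' Plots C_n, the fraction of clones larger than n cells, per patient on
#' a log scale.
#'
#' @param datasets List of `patient_dataset` objects.
#' @return A ggplot object.
#' @export
plot_cumulative_distribution <- function(datasets) {
  df <- .dataset_frame(datasets)
  df <- df[df$C_n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(n, C_n, colour = patient)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone size n (cells)",
                  y = expression(C[n] ~ "(fraction of clones > n)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Incomplete-moment curves with fitted exponentials
#'
#' Plots 1 - mu1(n)/mu1(inf) per patient, which the model predicts to
#' decay as exp(-n/N(t)); overlays the fitted curve where a fit is
#' available.
#'
#' @param datasets List of `patient_dataset` objects.
#' @param fit Optional [fit_cohort()] result supplying per-patient N_hat.
#' @return A ggplot object.
#' @export
plot_incomplete_moment <- function(datasets, fit = NULL) {
  df <- .dataset_frame(datasets)
  df <- df[df$one_minus_mu > 0, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(n, one_minus_mu, colour = patient)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "clone size n (cells)",
                  y = expression(1 - mu[1](n) / mu[1](infinity)),
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    ov <- do.call(rbind, lapply(datasets, function(d) {
      row <- fit$patients[fit$patients$patient_id == d$patient_id, ]
      if (nrow(row) == 0 || is.na(row$N_hat)) return(NULL)
      lab <- sprintf("%s (%s, %g y)", d$patient_id,
                     if (d$smoker) "smoker" else "non-smoker", d$age)
      nn <- seq(0, max(d$clones$n_cells), length.out = 200)
      data.frame(patient = lab, n = nn,
                 one_minus_mu = exp(-nn / row$N_hat))
    }))
    if (!is.null(ov))
      p <- p + ggplot2::geom_line(data = ov, linewidth = 0.4)
  }
  p
}

#' N(t) against age with group trends
#'
#' @param fit A [fit_cohort()] result.
#' @return A ggplot object.
#' @export
plot_age_trend <- function(fit) {
  stopifnot(inherits(fit, "cohort_fit"))
  df <- fit$patients[!is.na(fit$patients$N_hat), ]
  df$group <- ifelse(df$smoker == 1, "smoker", "non-smoker")
  p <- ggplot2::ggplot(df, ggplot2::aes(age, N_hat, colour = group)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = lower, ymax = upper),
                           width = 1) +
    ggplot2::labs(x = "age (years)", y = "fitted N(t) (cells)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  for (grp in names(fit$groups)) {
    g <- fit$groups[[grp]]
    lab <- if (grp == "smoker") "smoker" else "non-smoker"
    xs <- seq(g$t0, max(df$age) + 2, length.out = 50)
    p <- p + ggplot2::geom_line(
      data = data.frame(age = xs, N_hat = g$slope * (xs - g$t0),
                        group = lab),
      linetype = "dashed")
  }
  p
}

#' Write a figure + summary report for a cohort fit
#'
#' Produces three PNG figures (cumulative distributions, incomplete
#' moments with model overlays, N(t) against age) and a markdown summary
#' of the estimates.
#'
#' @param fit A [fit_cohort()] result.
#' @param datasets The patient datasets the fit was computed from.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
report_cohort <- function(fit, datasets, dir) {
  stopifnot(inherits(fit, "cohort_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, c("cumulative_distribution.png",
                            "incomplete_moment.png", "age_trend.png",
                            "summary.md"))
  plots <- list(plot_cumulative_distribution(datasets),
                plot_incomplete_moment(datasets, fit),
                plot_age_trend(fit))
  for (i in 1:3) {
    grDevices::png(files[i], width = 1600, height = 1100, res = 200)
    print(plots[[i]])
    grDevices::dev.off()
  }
  con <- file(files[4], "w")
  on.exit(close(con))
  writeLines("# Cohort fit summary\n", con)
  writeLines("## Per patient\n", con)
  writeLines(paste(utils::capture.output(
    print(fit$patients, row.names = FALSE, digits = 3)), collapse = "\n"),
    con)
  for (grp in names(fit$groups)) {
    g <- fit$groups[[grp]]
    writeLines(sprintf(paste0(
      "\n## %s\n\n",
      "- slope r*lambda/rho: %.2f +/- %.2f cells/year\n",
      "- onset age t0: %.1f +/- %.1f years\n",
      "- loss/replacement rate 2*r*lambda: %.2f /year\n",
      "- mutation rate R: %.1f /year/cm^2 (%s form)\n",
      "- per-cell mutation rate: %.2g /cell/year\n",
      "- clone separation: %.0f cell diameters"),
      grp, g$slope, g$slope_se, g$t0, g$t0_se, g$two_rlambda,
      g$R, g$R_form, g$per_cell_rate, g$separation$ratio), con)
  }
  invisible(files)
}

#' Run the full pipeline headlessly
#'
#' Generate a synthetic cohort, write its clone table and a provenance
#' sidecar, fit the full inference chain, and write results JSON plus the
#' figure report — everything a command-line run produces, as one
#' function call.
#'
#' @param config A [cohort_config]; its seed governs all randomness.
#' @param dir Output directory.
#' @param n_boot Bootstrap resamples per patient fit.
#' @return The [fit_cohort()] result, invisibly.
#' @export
run_pipeline <- function(config = cohort_config(), dir = ".",
                         n_boot = 200) {
  stopifnot(inherits(config, "cohort_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  datasets <- generate_cohort(config)
  write_clone_table(datasets, file.path(dir, "clone_table.tsv"))
  prov <- list(
    seed = config$seed,
    package_version = as.character(packageVersion("clonaldrift")),
    smoker_params = unclass(config$smoker_params),
    nonsmoker_params = unclass(config$nonsmoker_params),
    patients = config$patients
  )
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  rho <- config$smoker_params$rho
  kappa <- config$smoker_params$kappa
  fit <- suppressWarnings(
    fit_cohort(datasets, rho = rho, kappa = kappa, n_boot = n_boot))
  write_results_json(fit, file.path(dir, "results.json"))
  report_cohort(fit, datasets, dir)
  invisible(fit)
}
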