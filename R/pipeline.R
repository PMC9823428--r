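#' Baseline-characteristics summary
#'
#' Mean (SD) of age, body weight, height and BMI plus sex counts per arm and
#' overall — the Table-1 layout.
#'
#' @param subjects The `subjects` element of a simulated trial.
#' @return Tibble `variable, all, intervention, control`.
#' @export
baseline_table <- function(subjects) {
  fmt <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
  one <- function(df) {
    c(n = as.character(nrow(df)),
      age = fmt(df$age),
      male = sprintf("%d (%.1f%%)", sum(df$sex == "male"),
                     100 * mean(df$sex == "male")),
      female = sprintf("%d (%.1f%%)", sum(df$sex == "female"),
                       100 * mean(df$sex == "female")),
      body_weight = fmt(df$body_weight),
      height = fmt(df$height),
      bmi = fmt(df$bmi))
  }
  groups <- split(subjects, subjects$group)
  tibble::tibble(
    variable = names(one(subjects)),
    all = one(subjects),
    intervention = one(groups$intervention),
    control = one(groups$control))
}

#' Descriptive statistics of the component scores
#'
#' Mean (SD) of each HEI-NVS component score and the total per arm and
#' timepoint — the Table-3 layout. For multiply imputed data the means and
#' SDs are averaged across imputations.
#'
#' @param data A `hei_imputed` object or a single complete panel.
#' @return Tibble `variable, group, timepoint, mean, sd`.
#' @export
descriptive_table <- function(data) {
  panels <- if (inherits(data, "hei_imputed")) data$datasets else list(data)
  vars <- c(paste0("hei_", hei_components()), "hei_nvs_total")
  purrr::map_dfr(panels, function(p) {
    p |>
      dplyr::filter(.data$variable %in% vars, !is.na(.data$value)) |>
      dplyr::group_by(.data$variable, .data$group, .data$timepoint) |>
      dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                       .groups = "drop")
  }) |>
    dplyr::group_by(.data$variable, .data$group, .data$timepoint) |>
    dplyr::summarise(mean = mean(.data$mean), sd = mean(.data$sd),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$variable, vars), dplyr::desc(.data$group),
                   .data$timepoint)
}

#' Run the full trial analysis
#'
#' Orchestrates the staged analysis on a synthetic trial: simulate the trial
#' (diaries and outcome panel), re-score the emitted diaries with the
#' scoring engine, analyse either by intention-to-treat (multiple imputation
#' of all randomized subjects, the primary mode) or per protocol (complete
#' cases only), fit the pooled robust mixed model of the HEI-NVS total,
#' compute the within-group effect sizes, and bootstrap the change-score
#' correlation table. Every random stage consumes a sub-seed derived from
#' `seed`, recorded in the provenance.
#'
#' @param config Generator configuration ([sim_config()]).
#' @param seed Master seed.
#' @param mode `"ITT"` (default) or `"PP"`.
#' @param m Imputations (ITT mode).
#' @param maxit Chained-equation sweeps per imputation.
#' @param B Bootstrap replicates per correlation cell.
#' @param accelerated Use BCa bootstrap endpoints.
#' @param out_dir Optional directory: the five result tables and a
#'   provenance manifest are written there as CSV/YAML.
#' @return A list of class `hei_run`: `sim`, `imputed` (ITT only),
#'   `baseline` (Table-1 shape), `model` (Table-2 shape), `descriptives`
#'   (Table-3 shape), `effect_sizes` (Table-4 shape), `correlations`
#'   (Table-5 shape), `provenance`.
#' @export
run_trial_analysis <- function(config = sim_config(), seed = 1,
                               mode = c("ITT", "PP"), m = 50, maxit = 5,
                               B = 5000, accelerated = FALSE,
                               out_dir = NULL) {
  mode <- match.arg(mode)
  seeds <- list(simulate = seed, impute = seed + 101L, bootstrap = seed + 202L)

  sim <- simulate_trial(config, seed = seeds$simulate)

  # the scoring engine recomputes the diet variables from the raw diaries
  scored <- score_diaries(sim$diaries)
  diet_long <- scores_to_panel(scored) |>
    dplyr::rename(scored_value = "value") |>
    dplyr::select(-"group")
  panel <- sim$panel |>
    dplyr::left_join(diet_long,
                     by = c("subject_id", "timepoint", "variable")) |>
    dplyr::mutate(value = dplyr::if_else(
      !is.na(.data$scored_value) & !is.na(.data$value),
      .data$scored_value, .data$value)) |>
    dplyr::select(-"scored_value")

  if (mode == "PP") {
    complete_subjects <- panel |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(complete = !anyNA(.data$value)) |>
      dplyr::filter(.data$complete)
    analysis_panel <- dplyr::semi_join(panel, complete_subjects,
                                       by = "subject_id")
    imputed <- NULL
    model <- fit_robust_lmm(analysis_panel)
    effect_sizes <- effect_size_table(analysis_panel)
    correlations <- correlation_table(analysis_panel, B = B,
                                      seed = seeds$bootstrap,
                                      accelerated = accelerated)
    descriptives <- descriptive_table(analysis_panel)
    model_tab <- model$coefficients
  } else {
    if (anyNA(panel$value)) {
      imputed <- impute_trial(panel, m = m, maxit = maxit,
                              seed = seeds$impute)
    } else {
      # nothing to impute: analyse the complete panel directly
      imputed <- structure(list(datasets = rep(list(panel), 2), m = 2,
                                method = "none", maxit = 0,
                                seed = seeds$impute),
                           class = "hei_imputed")
    }
    pooled <- fit_pooled(imputed)
    model <- pooled
    model_tab <- pooled$coefficients
    effect_sizes <- effect_size_table(imputed)
    correlations <- correlation_table(imputed, B = B,
                                      seed = seeds$bootstrap,
                                      accelerated = accelerated)
    descriptives <- descriptive_table(imputed)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("heinvs")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    mode = mode, seed = seed, sub_seeds = seeds, m = if (mode == "ITT") m,
    maxit = maxit, bootstrap_B = B, accelerated = accelerated,
    n_total = config$n_total,
    n_dropouts = nrow(sim$dropout_log),
    n_energy_targets_adjusted = sim$n_energy_adjusted)

  run <- structure(list(sim = sim, imputed = imputed,
                        baseline = baseline_table(sim$subjects),
                        model = model, model_table = model_tab,
                        descriptives = descriptives,
                        effect_sizes = effect_sizes,
                        correlations = correlations,
                        provenance = provenance),
                   class = "hei_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(run$baseline, file.path(out_dir, "table1_baseline.csv"))
    readr::write_csv(run$model_table, file.path(out_dir, "table2_model.csv"))
    readr::write_csv(run$descriptives,
                     file.path(out_dir, "table3_descriptives.csv"))
    readr::write_csv(run$effect_sizes,
                     file.path(out_dir, "table4_effect_sizes.csv"))
    readr::write_csv(run$correlations,
                     file.path(out_dir, "table5_correlations.csv"))
    yaml::write_yaml(provenance, file.path(out_dir, "provenance.yaml"))
  }
  run
}

#' @export
print.hei_run <- function(x, ...) {
  cat("HEI-NVS trial analysis (", x$provenance$mode, " mode, seed ",
      x$provenance$seed, ")\n\n", sep = "")
  cat("Model of the HEI-NVS total:\n")
  print(as.data.frame(x$model_table), digits = 3, row.names = FALSE)
  cat("\nEffect sizes (within-group standardized change):\n")
  print(as.data.frame(x$effect_sizes), digits = 3, row.names = FALSE)
  cat("\nChange-score correlations with the HEI-NVS total:\n")
  print(as.data.frame(x$correlations), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Plot the outcome course per arm
#'
#' Group means with 95% confidence intervals over the four timepoints.
#'
#' @param panel Long trial table.
#' @param outcome Variable to plot.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(panel, outcome = "hei_nvs_total") {
  df <- panel |>
    dplyr::filter(.data$variable == outcome, !is.na(.data$value)) |>
    dplyr::group_by(.data$group, .data$timepoint) |>
    dplyr::summarise(mean = mean(.data$value),
                     se = stats::sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$mean,
                                   colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - 1.96 * .data$se,
                                        ymax = .data$mean + 1.96 * .data$se),
                           width = 0.1) +
    ggplot2::labs(x = "Timepoint", y = outcome, colour = "Group") +
    ggplot2::theme_minimal()
}
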