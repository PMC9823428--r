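#' @importFrom rlang .data
NULL

diary_cols <- c("subject_id", "timepoint", "day", "component",
                "amount_g", "energy_kcal", "is_beverage")

#' Validate a table of food-diary entries
#'
#' A diary is a tibble with one logged food item per row and columns
#' `subject_id`, `timepoint` (t0--t3), `day` (1--7), `component` (one of the
#' ten HEI-NVS components or `"other"`), `amount_g`, `energy_kcal` and
#' `is_beverage`. Beverages and alcohol are recorded in grams with an assumed
#' density of 1 g/mL. An optional `group` column is carried through untouched.
#'
#' @param diary Data frame of food entries.
#' @param require_seven_days If `TRUE` (the default), every subject-timepoint
#'   record must cover all seven diary days; shorter records raise an error.
#'   If `FALSE`, shorter records are accepted with a warning and later
#'   averaged over the days actually observed.
#' @return The validated diary as a tibble.
#' @export
validate_diary <- function(diary, require_seven_days = TRUE) {
  diary <- tibble::as_tibble(diary)
  missing_cols <- setdiff(diary_cols, names(diary))
  if (length(missing_cols) > 0) {
    stop("diary is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(diary) == 0) {
    return(diary)
  }
  vocab <- c(hei_components(), "other")
  bad <- which(!diary$component %in% vocab)
  if (length(bad) > 0) {
    stop(sprintf("unknown component label '%s' in diary row %d",
                 diary$component[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(!(diary$day %in% 1:7))
  if (length(bad) > 0) {
    stop(sprintf("diary row %d has day %s outside 1..7",
                 bad[1], diary$day[bad[1]]), call. = FALSE)
  }
  bad <- which(diary$amount_g < 0 | diary$energy_kcal < 0)
  if (length(bad) > 0) {
    stop(sprintf("diary row %d has a negative amount or energy", bad[1]),
         call. = FALSE)
  }
  if (!all(diary$timepoint %in% hei_timepoints())) {
    stop("timepoint must be one of ", paste(hei_timepoints(), collapse = ", "),
         call. = FALSE)
  }
  n_days <- diary |>
    dplyr::distinct(.data$subject_id, .data$timepoint, .data$day) |>
    dplyr::count(.data$subject_id, .data$timepoint)
  short <- n_days$n < 7
  if (any(short)) {
    msg <- sprintf(
      "%d diary record(s) cover fewer than 7 days (e.g. %s at %s: %d days)",
      sum(short), n_days$subject_id[short][1], n_days$timepoint[short][1],
      n_days$n[short][1])
    if (require_seven_days) stop(msg, call. = FALSE) else warning(msg,
                                                                 call. = FALSE)
  }
  diary
}

#' Read seven-day food diaries from CSV
#'
#' The CSV dialect is UTF-8, comma-separated, with a header row and one food
#' entry per row; columns `subject_id, group, timepoint, day, component,
#' amount_g, energy_kcal, is_beverage` (`group` optional).
#'
#' @inheritParams validate_diary
#' @param path Path to the diary CSV.
#' @return A validated diary tibble; an empty file yields an empty tibble with
#'   a warning.
#' @export
read_food_records <- function(path, require_seven_days = TRUE) {
  diary <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             subject_id = readr::col_character(),
                             timepoint = readr::col_character(),
                             day = readr::col_integer(),
                             component = readr::col_character(),
                             amount_g = readr::col_double(),
                             energy_kcal = readr::col_double(),
                             is_beverage = readr::col_logical(),
                             .default = readr::col_guess()
                           ))
  if (nrow(diary) == 0) {
    warning("diary file '", path, "' contains no entries", call. = FALSE)
  }
  validate_diary(diary, require_seven_days = require_seven_days)
}

#' @rdname read_food_records
#' @param diary Diary tibble to write.
#' @export
write_food_records <- function(diary, path) {
  readr::write_csv(tibble::as_tibble(diary), path)
  invisible(path)
}

#' Mean daily intake per component
#'
#' Averages the logged amounts of each HEI-NVS component over the diary days
#' of each subject-timepoint record: the summed grams of a component divided
#' by the number of distinct days the record covers. Components never logged
#' map to 0 g/day; `"other"` entries are ignored here (they only matter for
#' energy). This is the quantity the component scores are computed from.
#'
#' @inheritParams validate_diary
#' @return A tibble `subject_id, timepoint, component, grams_per_day` with all
#'   ten components present for every record.
#' @export
mean_daily_amounts <- function(diary, require_seven_days = TRUE) {
  diary <- validate_diary(diary, require_seven_days = require_seven_days)
  if (nrow(diary) == 0) {
    stop("cannot average an empty diary (0 observed days)", call. = FALSE)
  }
  days <- diary |>
    dplyr::distinct(.data$subject_id, .data$timepoint, .data$day) |>
    dplyr::count(.data$subject_id, .data$timepoint, name = "n_days")
  totals <- diary |>
    dplyr::filter(.data$component != "other") |>
    dplyr::group_by(.data$subject_id, .data$timepoint, .data$component) |>
    dplyr::summarise(total_g = sum(.data$amount_g), .groups = "drop")
  days |>
    tidyr::crossing(component = hei_components()) |>
    dplyr::left_join(totals, by = c("subject_id", "timepoint", "component")) |>
    dplyr::mutate(
      grams_per_day = dplyr::coalesce(.data$total_g, 0) / .data$n_days) |>
    dplyr::select("subject_id", "timepoint", "component", "grams_per_day")
}

#' Trial outcome-variable vocabulary
#'
#' The long-format trial panel's variable names: the HEI-NVS total, the ten
#' component scores (prefixed `hei_`), the two dietary variables, and the
#' anthropometric and cardiometabolic measurements.
#'
#' @return Character vector of variable names.
#' @export
trial_variables <- function() {
  c("hei_nvs_total", paste0("hei_", hei_components()),
    "energy_density", "energy_intake",
    "body_weight", "waist_circumference", "fat_mass", "fat_free_mass",
    "total_cholesterol", "hdl", "ldl", "fasting_glucose", "hba1c",
    "systolic_bp", "diastolic_bp")
}

#' Validate a long-format trial outcome table
#'
#' The panel has one row per (subject, timepoint, variable) with columns
#' `subject_id, group, timepoint, variable, value`; `NA` values mark missing
#' measurements. Enforced invariants: no duplicated cells, a single group per
#' subject, groups in \{intervention, control\}, and a complete baseline (t0)
#' row set for every subject (baseline was examined before any dropout).
#'
#' @param trial Data frame in the long panel layout.
#' @return The validated panel as a tibble.
#' @export
validate_trial_table <- function(trial) {
  trial <- tibble::as_tibble(trial)
  needed <- c("subject_id", "group", "timepoint", "variable", "value")
  missing_cols <- setdiff(needed, names(trial))
  if (length(missing_cols) > 0) {
    stop("trial table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(trial$group %in% c("intervention", "control"))) {
    stop("group must be 'intervention' or 'control'", call. = FALSE)
  }
  if (!all(trial$timepoint %in% hei_timepoints())) {
    stop("timepoint must be one of ", paste(hei_timepoints(), collapse = ", "),
         call. = FALSE)
  }
  dup <- trial |>
    dplyr::count(.data$subject_id, .data$timepoint, .data$variable) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf("duplicate cell for subject %s, %s, %s",
                 dup$subject_id[1], dup$timepoint[1], dup$variable[1]),
         call. = FALSE)
  }
  two_groups <- trial |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(two_groups) > 0) {
    stop("subject ", two_groups$subject_id[1],
         " is listed in more than one group", call. = FALSE)
  }
  at_t0 <- trial |>
    dplyr::filter(.data$timepoint == "t0", !is.na(.data$value)) |>
    dplyr::distinct(.data$subject_id)
  orphans <- setdiff(unique(trial$subject_id), at_t0$subject_id)
  if (length(orphans) > 0) {
    stop("subject ", orphans[1], " has no observed baseline (t0) values",
         call. = FALSE)
  }
  trial
}

#' Read or write the long-format trial table
#'
#' CSV columns `subject_id, group, timepoint, variable, value`; an empty
#' `value` cell is read as an explicit missing measurement.
#'
#' @param path Path to the trial-table CSV.
#' @return `read_trial_table()` returns a validated panel tibble.
#' @export
read_trial_table <- function(path) {
  trial <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             subject_id = readr::col_character(),
                             group = readr::col_character(),
                             timepoint = readr::col_character(),
                             variable = readr::col_character(),
                             value = readr::col_double()
                           ))
  validate_trial_table(trial)
}

#' @rdname read_trial_table
#' @param trial Panel tibble to write.
#' @export
write_trial_table <- function(trial, path) {
  readr::write_csv(tibble::as_tibble(trial), path)
  invisible(path)
}

#' Pivot the trial panel to one column per variable-timepoint
#'
#' Internal workhorse layout for the imputer and models: one row per subject,
#' columns `<variable>.<timepoint>`.
#'
#' @param trial Validated long panel.
#' @return A wide tibble with `subject_id`, `group`, then value columns.
#' @keywords internal
trial_to_wide <- function(trial) {
  trial |>
    dplyr::mutate(col = paste(.data$variable, .data$timepoint, sep = ".")) |>
    dplyr::select("subject_id", "group", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value")
}

#' @rdname trial_to_wide
#' @param wide Wide tibble produced by [trial_to_wide()].
#' @keywords internal
wide_to_trial <- function(wide) {
  wide |>
    tidyr::pivot_longer(cols = -c("subject_id", "group"),
                        names_to = c("variable", "timepoint"),
                        names_sep = "\\.", values_to = "value") |>
    dplyr::select("subject_id", "group", "timepoint", "variable", "value") |>
    dplyr::arrange(.data$subject_id, .data$timepoint, .data$variable)
}
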