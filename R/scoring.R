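#' Score one HEI-NVS component
#'
#' Piecewise-linear scoring of a mean daily intake against one component's
#' standard. Adequacy components earn points proportionally up to the
#' reference amount and are capped there:
#' \deqn{points = max\_points \times \min(1, intake / reference)}
#' Moderation components keep the full score at or below the reference and
#' lose points linearly until the intake reaches `zero_point_multiple` times
#' the reference, beyond which the score is 0. Both branches are continuous
#' in the intake.
#'
#' @param intake Mean daily intake in grams (vectorised; must be >= 0).
#' @param max_points Component maximum (10 or 15).
#' @param reference_amount Reference intake in g/day.
#' @param direction `"adequacy"` or `"moderation"`.
#' @param zero_point_multiple For moderation components, the multiple of the
#'   reference at which the score hits zero (default 2).
#' @return Numeric score(s) in `[0, max_points]`.
#' @examples
#' score_component(200, max_points = 15, reference_amount = 400,
#'                 direction = "adequacy")  # 7.5
#' @export
score_component <- function(intake, max_points, reference_amount, direction,
                            zero_point_multiple = 2) {
  if (any(intake < 0)) {
    stop("intake must be non-negative", call. = FALSE)
  }
  n <- length(intake)
  direction <- rep_len(direction, n)
  max_points <- rep_len(max_points, n)
  reference_amount <- rep_len(reference_amount, n)
  k <- rep_len(ifelse(is.na(zero_point_multiple), 2, zero_point_multiple), n)
  adequacy <- max_points * pmin(1, intake / reference_amount)
  moderation <- ifelse(
    intake <= reference_amount,
    max_points,
    max_points * pmax(0, (k * reference_amount - intake) /
                        ((k - 1) * reference_amount)))
  ifelse(direction == "adequacy", adequacy, moderation)
}

#' Score food diaries
#'
#' Computes the ten HEI-NVS component scores, their 0--110 total, the dietary
#' energy density and the mean daily energy intake for every subject-timepoint
#' record in a diary table. Component intakes are the seven-day mean daily
#' amounts ([mean_daily_amounts()]); the total is the plain sum of the
#' component scores.
#'
#' @inheritParams validate_diary
#' @param refs Reference table ([default_reference_table()]).
#' @param include_beverages Passed to [energy_density()].
#' @return A tibble with one row per subject-timepoint: `subject_id`,
#'   `timepoint`, one score column per component (named `hei_<component>`),
#'   `hei_nvs_total`, `energy_density` (kcal/g) and `energy_intake`
#'   (kcal/day). A `group` column is carried through when present.
#' @export
score_diaries <- function(diary, refs = default_reference_table(),
                          require_seven_days = TRUE,
                          include_beverages = FALSE) {
  refs <- validate_reference_table(refs)
  diary <- validate_diary(diary, require_seven_days = require_seven_days)
  intakes <- mean_daily_amounts(diary, require_seven_days = require_seven_days)
  scored <- intakes |>
    dplyr::left_join(refs, by = "component") |>
    dplyr::mutate(score = score_component(
      .data$grams_per_day, .data$max_points, .data$reference_amount,
      .data$direction, .data$zero_point_multiple))
  wide <- scored |>
    dplyr::mutate(variable = paste0("hei_", .data$component)) |>
    dplyr::select("subject_id", "timepoint", "variable", "score") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "score") |>
    dplyr::mutate(hei_nvs_total = rowSums(
      dplyr::pick(dplyr::all_of(paste0("hei_", hei_components())))))
  energy <- dplyr::left_join(
    energy_intake(diary),
    energy_density(diary, include_beverages = include_beverages),
    by = c("subject_id", "timepoint"))
  out <- dplyr::left_join(wide, energy, by = c("subject_id", "timepoint"))
  if ("group" %in% names(diary)) {
    groups <- dplyr::distinct(diary, .data$subject_id, .data$group)
    out <- dplyr::left_join(out, groups, by = "subject_id") |>
      dplyr::relocate("group", .after = "subject_id")
  }
  out
}

#' Score a single dietary record
#'
#' Convenience wrapper around [score_diaries()] for a diary containing exactly
#' one subject-timepoint record.
#'
#' @inheritParams score_diaries
#' @param record Diary tibble holding one subject-timepoint.
#' @return A list with `component_scores` (named numeric vector over the ten
#'   components), `total`, `energy_density` and `energy_intake`.
#' @export
score_record <- function(record, refs = default_reference_table(),
                         require_seven_days = TRUE) {
  key <- unique(record[c("subject_id", "timepoint")])
  if (nrow(key) != 1) {
    stop("score_record() expects exactly one subject-timepoint record",
         call. = FALSE)
  }
  row <- score_diaries(record, refs = refs,
                       require_seven_days = require_seven_days)
  scores <- as.numeric(row[paste0("hei_", hei_components())])
  names(scores) <- hei_components()
  list(component_scores = scores, total = row$hei_nvs_total,
       energy_density = row$energy_density, energy_intake = row$energy_intake)
}

#' Dietary energy density
#'
#' Energy per unit mass of consumed food, kcal/g, computed over the whole
#' diary record. Following the usual convention in energy-density research,
#' beverages (rows with `is_beverage = TRUE`) are excluded from both the
#' energy numerator and the mass denominator by default.
#'
#' @inheritParams validate_diary
#' @param include_beverages Count beverage rows in the computation.
#' @return Tibble `subject_id, timepoint, energy_density`.
#' @export
energy_density <- function(diary, include_beverages = FALSE,
                           require_seven_days = TRUE) {
  diary <- validate_diary(diary, require_seven_days = require_seven_days)
  eligible <- if (include_beverages) diary else
    dplyr::filter(diary, !.data$is_beverage)
  out <- eligible |>
    dplyr::group_by(.data$subject_id, .data$timepoint) |>
    dplyr::summarise(kcal = sum(.data$energy_kcal),
                     grams = sum(.data$amount_g), .groups = "drop")
  if (nrow(out) == 0 || any(out$grams <= 0)) {
    stop("energy density is undefined: a record has no eligible food mass",
         call. = FALSE)
  }
  dplyr::transmute(out, .data$subject_id, .data$timepoint,
                   energy_density = .data$kcal / .data$grams)
}

#' Mean daily energy intake
#'
#' Total diary energy divided by the number of observed diary days, kcal/day.
#'
#' @inheritParams validate_diary
#' @return Tibble `subject_id, timepoint, energy_intake`. An empty diary
#'   yields an empty tibble with a warning.
#' @export
energy_intake <- function(diary, require_seven_days = TRUE) {
  diary <- validate_diary(diary, require_seven_days = require_seven_days)
  if (nrow(diary) == 0) {
    warning("empty diary: no energy intake to compute", call. = FALSE)
    return(tibble::tibble(subject_id = character(), timepoint = character(),
                          energy_intake = numeric()))
  }
  days <- diary |>
    dplyr::distinct(.data$subject_id, .data$timepoint, .data$day) |>
    dplyr::count(.data$subject_id, .data$timepoint, name = "n_days")
  diary |>
    dplyr::group_by(.data$subject_id, .data$timepoint) |>
    dplyr::summarise(kcal = sum(.data$energy_kcal), .groups = "drop") |>
    dplyr::left_join(days, by = c("subject_id", "timepoint")) |>
    dplyr::transmute(.data$subject_id, .data$timepoint,
                     energy_intake = .data$kcal / .data$n_days)
}

#' Convert scored diaries to the long trial panel
#'
#' Reshapes the wide output of [score_diaries()] into the long-format trial
#' table used by the imputation and modelling stages.
#'
#' @param scores Output of [score_diaries()]; must carry a `group` column.
#' @return A validated long panel ([validate_trial_table()]).
#' @export
scores_to_panel <- function(scores) {
  if (!"group" %in% names(scores)) {
    stop("scores must carry a 'group' column to form a trial panel",
         call. = FALSE)
  }
  panel <- scores |>
    tidyr::pivot_longer(cols = -c("subject_id", "group", "timepoint"),
                        names_to = "variable", values_to = "value") |>
    dplyr::arrange(.data$subject_id, .data$timepoint, .data$variable)
  validate_trial_table(panel)
}
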