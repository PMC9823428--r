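#' Permuted-block randomization
#'
#' Allocates `n` subjects to intervention and control in a 1:1 ratio using
#' randomly ordered balanced blocks of variable size: each block's size is
#' drawn from `block_sizes`, half its slots are intervention and half control,
#' and the within-block order is shuffled. Arm totals can therefore differ by
#' at most the largest block size (the final block may be truncated).
#'
#' @param n Number of subjects.
#' @param block_sizes Candidate block sizes; all must be even.
#' @param seed Optional integer seed for reproducible allocation.
#' @return Character vector of length `n` with values `"intervention"` /
#'   `"control"`.
#' @export
permuted_block_randomize <- function(n, block_sizes = c(2, 4, 6),
                                     seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (any(block_sizes %% 2 != 0)) {
    stop("block sizes must be even for 1:1 allocation within blocks",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- character(0)
  while (length(out) < n) {
    b <- if (length(block_sizes) == 1) block_sizes else sample(block_sizes, 1)
    block <- sample(rep(c("intervention", "control"), b / 2))
    out <- c(out, block)
  }
  out[seq_len(n)]
}

# Per-arm, per-timepoint component score means and SDs used as the
# generator's default trajectories (intervention improves mainly in the
# vegetables, fish and meat components; control drifts slightly down).
default_component_trajectories <- function() {
  tp <- hei_timepoints()
  traj <- tibble::tribble(
    ~component, ~group, ~m0, ~m1, ~m2, ~m3, ~s0, ~s1, ~s2, ~s3,
    "vegetables", "intervention", 6.24, 7.71, 7.36, 7.60, 3.41, 4.06, 3.01, 3.51,
    "vegetables", "control",      6.15, 6.67, 5.72, 6.57, 3.15, 3.10, 2.54, 3.08,
    "fruits", "intervention",     7.95, 7.89, 7.75, 7.34, 4.37, 4.36, 3.96, 4.41,
    "fruits", "control",          7.31, 7.20, 6.42, 6.77, 4.69, 4.63, 3.61, 3.99,
    "grains", "intervention",     6.67, 6.42, 6.98, 6.56, 2.35, 2.19, 2.05, 2.05,
    "grains", "control",          6.71, 6.35, 7.00, 6.84, 2.33, 2.04, 1.94, 2.30,
    "dairy", "intervention",      7.08, 6.80, 7.14, 7.01, 2.15, 1.95, 1.75, 2.05,
    "dairy", "control",           7.15, 7.33, 7.27, 7.14, 1.82, 1.57, 1.66, 1.55,
    "fish", "intervention",       3.29, 3.87, 4.07, 4.15, 3.90, 3.85, 3.36, 3.39,
    "fish", "control",            4.31, 3.18, 3.52, 3.13, 3.93, 3.53, 3.24, 3.33,
    "beverages", "intervention",  8.93, 8.97, 8.87, 8.75, 2.08, 2.17, 2.00, 2.09,
    "beverages", "control",       8.19, 8.10, 8.24, 8.22, 2.52, 2.84, 2.48, 2.59,
    "eggs", "intervention",       8.79, 8.91, 8.89, 8.84, 1.92, 1.82, 1.62, 1.75,
    "eggs", "control",            8.72, 8.31, 8.90, 8.62, 2.10, 2.31, 1.75, 2.10,
    "spreadable_fats", "intervention", 9.83, 9.92, 9.94, 9.95, 0.82, 0.43, 0.37, 0.22,
    "spreadable_fats", "control",      9.76, 9.91, 9.93, 9.90, 1.03, 0.57, 0.24, 0.41,
    "alcohol", "intervention",    9.23, 9.29, 9.57, 9.45, 1.79, 1.54, 1.17, 1.17,
    "alcohol", "control",         9.04, 9.11, 9.30, 9.18, 1.93, 1.75, 1.57, 1.65,
    "meat", "intervention",       7.96, 8.52, 8.85, 8.15, 2.43, 1.98, 1.51, 1.94,
    "meat", "control",            7.95, 8.13, 8.08, 7.83, 2.31, 2.14, 1.94, 2.26
  )
  means <- traj |>
    dplyr::select("component", "group", dplyr::starts_with("m")) |>
    tidyr::pivot_longer(dplyr::starts_with("m"), names_to = "timepoint",
                        values_to = "mean") |>
    dplyr::mutate(timepoint = tp[as.integer(sub("m", "", .data$timepoint)) + 1])
  sds <- traj |>
    dplyr::select("component", "group", dplyr::starts_with("s")) |>
    tidyr::pivot_longer(dplyr::starts_with("s"), names_to = "timepoint",
                        values_to = "sd") |>
    dplyr::mutate(timepoint = tp[as.integer(sub("s", "", .data$timepoint)) + 1])
  dplyr::left_join(means, sds, by = c("component", "group", "timepoint"))
}

aux_variables <- function() {
  setdiff(trial_variables(),
          c("hei_nvs_total", paste0("hei_", hei_components())))
}

# Baseline means/SDs of the non-score outcome variables (identical in both
# arms by randomization). Units: kcal/g, kcal/d, kg, cm, kg, kg, mg/dL (x4),
# %, mmHg (x2). Body weight is derived from simulated BMI and height instead.
default_aux_baseline <- function() {
  tibble::tribble(
    ~variable,             ~mean, ~sd,
    "energy_density",      1.65,  0.30,
    "energy_intake",       2100,  500,
    "waist_circumference", 102,   10,
    "fat_mass",            33,    8,
    "fat_free_mass",       55,    10,
    "total_cholesterol",   210,   38,
    "hdl",                 55,    14,
    "ldl",                 132,   33,
    "fasting_glucose",     95,    10,
    "hba1c",               5.5,   0.35,
    "systolic_bp",         130,   13,
    "diastolic_bp",        83,    9
  )
}

# Mean change from baseline per arm and follow-up timepoint, and the SD of
# the individual change scores, for the non-score variables. A modest weight
# loss with partial regain, slightly larger under the interactive program.
default_aux_changes <- function() {
  ch <- tibble::tribble(
    ~variable, ~i1, ~i2, ~i3, ~c1, ~c2, ~c3, ~sd,
    "energy_density",      -0.12, -0.10, -0.08, -0.04, -0.03, -0.02, 0.35,
    "energy_intake",       -250,  -200,  -150,  -100,  -80,   -60,   550,
    "body_weight",         -2.3,  -2.6,  -2.0,  -1.0,  -1.2,  -0.8,  4.0,
    "waist_circumference", -2.5,  -2.8,  -2.2,  -1.0,  -1.2,  -0.9,  4.0,
    "fat_mass",            -1.8,  -2.0,  -1.6,  -0.8,  -0.9,  -0.6,  3.0,
    "fat_free_mass",       -0.5,  -0.6,  -0.4,  -0.2,  -0.3,  -0.2,  2.5,
    "total_cholesterol",   -4,    -5,    -3,    -1,    -2,    -1,    25,
    "hdl",                 1,     1.5,   1,     0,     0.5,   0,     7,
    "ldl",                 -3,    -4,    -2,    -1,    -1,    -1,    22,
    "fasting_glucose",     -1,    -1.5,  -1,    0,     -0.5,  0,     8,
    "hba1c",               -0.05, -0.06, -0.04, -0.01, -0.02, -0.01, 0.25,
    "systolic_bp",         -3,    -4,    -3,    -1,    -1.5,  -1,    10,
    "diastolic_bp",        -2,    -2.5,  -2,    -1,    -1,    -1,    7
  )
  tp <- hei_timepoints()[-1]
  purrr::map_dfr(seq_along(tp), function(k) {
    tibble::tibble(
      variable = rep(ch$variable, 2),
      group = rep(c("intervention", "control"), each = nrow(ch)),
      timepoint = tp[k],
      mean = c(ch[[paste0("i", k)]], ch[[paste0("c", k)]]),
      sd = rep(ch$sd, 2))
  })
}

# Correlation between each variable's change score and the change in the
# HEI-NVS total, applied at every follow-up interval. The energy-density
# entry is negative by design; the remaining defaults are weak.
default_delta_cor <- function() {
  vars <- c("hei_nvs_total", aux_variables())
  r <- diag(length(vars))
  dimnames(r) <- list(vars, vars)
  with_hei <- c(energy_density = -0.30, energy_intake = 0.08,
                body_weight = -0.06, waist_circumference = 0.03,
                fat_mass = 0.04, fat_free_mass = -0.15,
                total_cholesterol = -0.03, hdl = 0, ldl = -0.04,
                fasting_glucose = 0.10, hba1c = -0.07,
                systolic_bp = 0.03, diastolic_bp = 0.03)
  r["hei_nvs_total", names(with_hei)] <- with_hei
  r[names(with_hei), "hei_nvs_total"] <- with_hei
  r
}

# Typical energy densities (kcal/g) of the diary food groups, used when
# synthesising diary entries; the residual "other" food absorbs whatever
# energy and mass are needed to hit a record's energy targets.
default_component_energy_density <- function() {
  c(vegetables = 0.25, fruits = 0.55, grains = 1.8, dairy = 0.65,
    fish = 1.35, beverages = 0, meat = 2.0, eggs = 1.55,
    spreadable_fats = 7.0, alcohol = 0.5)
}

#' Configuration of the synthetic trial generator
#'
#' Collects every tunable of the generator with defaults emulating the study
#' conditions: 153 subjects allocated 1:1 by permuted blocks of variable
#' size, four timepoints, monotone dropout calibrated to a cumulative 22.9%
#' over the three follow-up stages, per-arm component-score trajectories,
#' baseline anthropometrics (mean BMI 30.71, SD 2.13), and a change-score
#' correlation matrix whose ΔHEI-total row induces the configured
#' associations (energy density −0.30 by default).
#'
#' @param n_total Number of randomized subjects.
#' @param block_sizes Permuted-block sizes (even).
#' @param target_dropout Cumulative probability that a subject misses at
#'   least one follow-up; converted to a constant per-stage hazard.
#' @param dropout_mechanism `"MAR"` (hazard depends on baseline BMI and
#'   group) or `"MCAR"`.
#' @param dropout_bmi_coef,dropout_group_coef Log-odds shifts per SD of
#'   baseline BMI and between arms under MAR; the per-stage intercept is
#'   recalibrated so the marginal hazard always matches `target_dropout`.
#' @param within_subject_cor Correlation of a subject's component score
#'   across timepoints (shared subject-level deviation).
#' @param component_trajectories Per-arm/timepoint component means and SDs.
#' @param aux_baseline,aux_changes Baseline and change-score distributions of
#'   the non-score variables.
#' @param delta_cor Change-score correlation matrix (symmetric, unit
#'   diagonal, positive semi-definite) over `hei_nvs_total` and the
#'   non-score variables.
#' @param component_energy_density Energy densities used to synthesise diary
#'   entries.
#' @param day_shape Gamma shape controlling day-to-day variation of diary
#'   amounts (larger = more even days).
#' @param bmi_mean,bmi_sd,age_mean,age_sd,height_mean,height_sd,prop_female
#'   Baseline characteristics of the simulated cohort.
#' @return A list of class `hei_sim_config`.
#' @export
sim_config <- function(n_total = 153,
                       block_sizes = c(2, 4, 6),
                       target_dropout = 0.229,
                       dropout_mechanism = c("MAR", "MCAR"),
                       dropout_bmi_coef = 0.3,
                       dropout_group_coef = 0.2,
                       within_subject_cor = 0.5,
                       component_trajectories = default_component_trajectories(),
                       aux_baseline = default_aux_baseline(),
                       aux_changes = default_aux_changes(),
                       delta_cor = default_delta_cor(),
                       component_energy_density = default_component_energy_density(),
                       day_shape = 20,
                       bmi_mean = 30.71, bmi_sd = 2.13,
                       age_mean = 48.92, age_sd = 11.17,
                       height_mean = 1.69, height_sd = 0.08,
                       prop_female = 0.712) {
  dropout_mechanism <- match.arg(dropout_mechanism)
  if (target_dropout < 0 || target_dropout >= 1) {
    stop("target_dropout must lie in [0, 1)", call. = FALSE)
  }
  if (any(aux_changes$sd < 0) || any(aux_baseline$sd < 0) ||
      any(component_trajectories$sd < 0)) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  check_delta_cor(delta_cor)
  structure(as.list(environment()), class = "hei_sim_config")
}

check_delta_cor <- function(delta_cor) {
  if (!isSymmetric(unname(delta_cor)) ||
      any(abs(diag(delta_cor) - 1) > 1e-12)) {
    stop("delta_cor must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(delta_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("delta_cor is not positive semi-definite (smallest eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  invisible(delta_cor)
}

# Solve the per-stage logistic intercept so the marginal hazard over the
# realised linear predictors equals the target stage probability.
calibrate_intercept <- function(eta, p_target) {
  if (p_target <= 0) return(-Inf)
  stats::uniroot(function(a) mean(stats::plogis(a + eta)) - p_target,
                 interval = c(-20, 20))$root
}

#' Simulate the trial outcome panel
#'
#' Draws one synthetic trial: subjects with baseline characteristics, a
#' permuted-block allocation, component scores following the configured
#' per-arm trajectories (Gaussian draws with a shared subject-level deviation,
#' clamped to each component's score range), the HEI-NVS total as their sum,
#' and the non-score variables as baseline plus change scores whose
#' correlation with the change in HEI-NVS total follows `delta_cor`. Monotone
#' dropout then blanks all variables from a subject's dropout stage onward;
#' baseline is always complete.
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A list of class `hei_sim` with elements `panel` (long trial
#'   table), `subjects` (baseline characteristics incl. BMI), `allocation`,
#'   `dropout_log` (subject, stage dropped), `scores_wide` (the complete
#'   pre-dropout wide outcome table, for diary synthesis), and `n_clamped`
#'   (component draws truncated into their score range).
#' @export
simulate_outcomes <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_delta_cor(config$delta_cor)
  n <- config$n_total
  tp <- hei_timepoints()
  comps <- hei_components()
  refs <- default_reference_table()

  ids <- sprintf("S%03d", seq_len(n))
  group <- permuted_block_randomize(n, config$block_sizes)
  subjects <- tibble::tibble(
    subject_id = ids,
    group = group,
    age = round(stats::rnorm(n, config$age_mean, config$age_sd), 1),
    sex = ifelse(stats::runif(n) < config$prop_female, "female", "male"),
    height = stats::rnorm(n, config$height_mean, config$height_sd),
    bmi = stats::rnorm(n, config$bmi_mean, config$bmi_sd))
  subjects$body_weight <- subjects$bmi * subjects$height^2

  # component scores: shared subject deviation + timepoint noise, clamped
  rho <- config$within_subject_cor
  traj <- config$component_trajectories |>
    dplyr::left_join(refs[c("component", "max_points")], by = "component")
  z_subj <- matrix(stats::rnorm(n * length(comps)), n,
                   dimnames = list(ids, comps))
  score_tab <- tidyr::crossing(subject_id = ids, timepoint = tp) |>
    dplyr::left_join(subjects[c("subject_id", "group")], by = "subject_id") |>
    tidyr::crossing(component = comps) |>
    dplyr::left_join(traj, by = c("component", "group", "timepoint"))
  zi <- z_subj[cbind(score_tab$subject_id, score_tab$component)]
  raw <- score_tab$mean + score_tab$sd *
    (sqrt(rho) * zi + sqrt(1 - rho) * stats::rnorm(nrow(score_tab)))
  clamped <- pmin(pmax(raw, 0), score_tab$max_points)
  n_clamped <- sum(clamped != raw)
  score_tab$score <- clamped

  scores_wide <- score_tab |>
    dplyr::mutate(variable = paste0("hei_", .data$component)) |>
    dplyr::select("subject_id", "group", "timepoint", "variable", "score") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "score") |>
    dplyr::mutate(hei_nvs_total = rowSums(
      dplyr::pick(dplyr::all_of(paste0("hei_", comps)))))

  # change in HEI total, standardised over the pooled sample per interval
  hei_wide <- scores_wide |>
    dplyr::select("subject_id", "timepoint", "hei_nvs_total") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "hei_nvs_total")
  hei_wide <- hei_wide[match(ids, hei_wide$subject_id), ]

  aux <- aux_variables()
  r_ah <- config$delta_cor["hei_nvs_total", aux]
  r_aa <- config$delta_cor[aux, aux]
  cond <- r_aa - tcrossprod(r_ah)
  ev <- eigen(cond, symmetric = TRUE)
  l_cond <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(aux))

  base_mean <- c(stats::setNames(config$aux_baseline$mean,
                                 config$aux_baseline$variable),
                 body_weight = NA)
  base_sd <- c(stats::setNames(config$aux_baseline$sd,
                               config$aux_baseline$variable),
               body_weight = NA)
  baseline <- sapply(aux, function(v) {
    if (v == "body_weight") subjects$body_weight else
      stats::rnorm(n, base_mean[[v]], base_sd[[v]])
  })

  aux_rows <- list(tibble::tibble(
    subject_id = rep(ids, length(aux)), timepoint = "t0",
    variable = rep(aux, each = n), value = as.vector(baseline)))
  for (t in tp[-1]) {
    dh <- hei_wide[[t]] - hei_wide[["t0"]]
    s <- (dh - mean(dh)) / stats::sd(dh)
    dev <- tcrossprod(s, r_ah) +
      matrix(stats::rnorm(n * length(aux)), n) %*% t(l_cond)
    ch <- config$aux_changes |> dplyr::filter(.data$timepoint == t)
    chm <- sapply(aux, function(v) {
      rows <- ch[ch$variable == v, ]
      rows$mean[match(group, rows$group)]
    })
    chs <- sapply(aux, function(v) ch$sd[ch$variable == v][1])
    delta <- chm + sweep(dev, 2, chs, `*`)
    vals <- baseline + delta
    aux_rows[[t]] <- tibble::tibble(
      subject_id = rep(ids, length(aux)), timepoint = t,
      variable = rep(aux, each = n), value = as.vector(vals))
  }
  aux_long <- dplyr::bind_rows(aux_rows)

  score_long <- scores_wide |>
    tidyr::pivot_longer(cols = -c("subject_id", "group", "timepoint"),
                        names_to = "variable", values_to = "value") |>
    dplyr::select(-"group")
  panel <- dplyr::bind_rows(score_long, aux_long) |>
    dplyr::left_join(subjects[c("subject_id", "group")], by = "subject_id") |>
    dplyr::select("subject_id", "group", "timepoint", "variable", "value") |>
    dplyr::arrange(.data$subject_id, .data$timepoint, .data$variable)

  # monotone dropout over the three follow-up stages
  p_stage <- 1 - (1 - config$target_dropout)^(1 / (length(tp) - 1))
  eta <- if (config$dropout_mechanism == "MAR") {
    config$dropout_bmi_coef * (subjects$bmi - config$bmi_mean) / config$bmi_sd +
      config$dropout_group_coef * (group == "control") -
      config$dropout_group_coef / 2
  } else {
    rep(0, n)
  }
  drop_stage <- rep(NA_integer_, n)
  at_risk <- rep(TRUE, n)
  for (s in seq_len(length(tp) - 1)) {
    if (!any(at_risk)) break
    a <- calibrate_intercept(eta[at_risk], p_stage)
    drops <- at_risk & (stats::runif(n) < stats::plogis(a + eta))
    drop_stage[drops] <- s
    at_risk <- at_risk & !drops
  }
  dropout_log <- tibble::tibble(subject_id = ids, drop_stage = drop_stage) |>
    dplyr::filter(!is.na(.data$drop_stage)) |>
    dplyr::mutate(first_missing = tp[.data$drop_stage + 1])

  tp_index <- match(panel$timepoint, tp) - 1L
  subj_drop <- drop_stage[match(panel$subject_id, ids)]
  panel$value[!is.na(subj_drop) & tp_index >= subj_drop] <- NA_real_

  structure(list(panel = validate_trial_table(panel), subjects = subjects,
                 allocation = group, dropout_log = dropout_log,
                 scores_wide = scores_wide, n_clamped = n_clamped,
                 config = config),
            class = "hei_sim")
}

invert_component_score <- function(score, max_points, reference_amount,
                                   direction, zero_point_multiple) {
  k <- ifelse(is.na(zero_point_multiple), 2, zero_point_multiple)
  adequacy <- reference_amount * score / max_points
  moderation <- ifelse(
    score >= max_points, reference_amount,
    reference_amount * (k - (k - 1) * score / max_points))
  ifelse(direction == "adequacy", adequacy, moderation)
}

#' Synthesise seven-day diaries from target scores
#'
#' Inverts the scoring rules: each target component score is mapped back to a
#' mean daily intake (adequacy components proportionally; moderation
#' components through the piecewise-linear inverse, with full-score intakes
#' placed at the reference), the weekly amount is spread over the seven days
#' with Gamma-weighted day-to-day variation that preserves the weekly total
#' exactly, and a residual `"other"` food entry per day absorbs the energy
#' and mass needed to hit the record's energy-intake and energy-density
#' targets. Re-scoring the emitted diary reproduces the target component
#' scores to floating-point accuracy.
#'
#' @param scores Wide tibble with `subject_id`, `timepoint`, the ten
#'   `hei_<component>` target scores and optionally `energy_intake`
#'   (kcal/day) and `energy_density` (kcal/g) targets.
#' @param refs Reference table.
#' @param component_energy_density Named kcal/g vector for the food groups.
#' @param day_shape Gamma shape for day weights.
#' @param seed Optional integer seed.
#' @return A diary tibble (see [validate_diary()]).
#' @export
diaries_from_scores <- function(scores, refs = default_reference_table(),
                                component_energy_density =
                                  default_component_energy_density(),
                                day_shape = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  refs <- validate_reference_table(refs)
  comps <- hei_components()
  score_cols <- paste0("hei_", comps)
  missing_cols <- setdiff(score_cols, names(scores))
  if (length(missing_cols) > 0) {
    stop("scores is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- purrr::map_lgl(seq_len(nrow(scores)), function(i) {
    s <- as.numeric(scores[i, score_cols])
    any(s < 0) || any(s > refs$max_points[match(comps, refs$component)])
  })
  if (any(bad)) {
    stop("target scores outside [0, max_points] for record ",
         scores$subject_id[which(bad)[1]], call. = FALSE)
  }

  ref_idx <- match(comps, refs$component)
  out <- purrr::map_dfr(seq_len(nrow(scores)), function(i) {
    row <- scores[i, ]
    s <- as.numeric(row[score_cols])
    intake <- invert_component_score(
      s, refs$max_points[ref_idx], refs$reference_amount[ref_idx],
      refs$direction[ref_idx], refs$zero_point_multiple[ref_idx])
    is_bev <- comps %in% c("beverages", "alcohol")
    ed_comp <- component_energy_density[comps]
    kcal <- intake * ed_comp

    ei_target <- if ("energy_intake" %in% names(row)) row$energy_intake else NA
    ed_target <- if ("energy_density" %in% names(row)) row$energy_density else NA
    other_kcal_day <- 0
    other_g_day <- 0
    if (!is.na(ei_target)) {
      other_kcal_day <- ei_target - sum(kcal)
      if (other_kcal_day < -1e-9) {
        stop("energy-intake target unattainable for record ",
             row$subject_id, " at ", row$timepoint,
             ": component foods already supply ", round(sum(kcal)),
             " kcal/day", call. = FALSE)
      }
      other_kcal_day <- max(other_kcal_day, 0)
    }
    if (!is.na(ed_target)) {
      food_kcal <- sum(kcal[!is_bev]) + other_kcal_day
      food_g <- sum(intake[!is_bev])
      if (ed_target <= 0) {
        stop("energy-density target must be positive for record ",
             row$subject_id, call. = FALSE)
      }
      other_g_day <- food_kcal / ed_target - food_g
      if (other_g_day < -1e-9) {
        stop("energy-density target unattainable for record ",
             row$subject_id, " at ", row$timepoint,
             ": component foods alone are below ", signif(ed_target, 3),
             " kcal/g", call. = FALSE)
      }
      other_g_day <- max(other_g_day, 0)
    }

    labels <- c(comps, "other")
    day_amount <- c(intake, other_g_day)
    day_kcal <- c(kcal, other_kcal_day)
    bev <- c(is_bev, FALSE)
    entries <- purrr::map_dfr(seq_along(labels), function(j) {
      w <- stats::rgamma(7, shape = day_shape)
      w <- w / sum(w)
      tibble::tibble(
        subject_id = row$subject_id, timepoint = row$timepoint, day = 1:7,
        component = labels[j],
        amount_g = 7 * day_amount[j] * w,
        energy_kcal = 7 * day_kcal[j] * w,
        is_beverage = bev[j])
    })
    entries
  })
  out
}

#' Simulate a complete synthetic trial
#'
#' Runs [simulate_outcomes()] and then synthesises a seven-day diary for
#' every observed (non-missing) subject-timepoint via
#' [diaries_from_scores()]. Energy targets that a record's component foods
#' make unattainable (energy intake below the component foods' energy, or an
#' energy-density target above what the foods can reach) are nudged to the
#' nearest attainable value in both the diaries and the panel, and counted in
#' `n_energy_adjusted`.
#'
#' @inheritParams simulate_outcomes
#' @return The [simulate_outcomes()] list augmented with `diaries` and
#'   `n_energy_adjusted`.
#' @export
simulate_trial <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_outcomes(config)

  obs <- sim$panel |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::distinct(.data$subject_id, .data$timepoint)
  energy <- sim$panel |>
    dplyr::filter(.data$variable %in% c("energy_intake", "energy_density")) |>
    tidyr::pivot_wider(names_from = "variable", values_from = "value")
  targets <- sim$scores_wide |>
    dplyr::inner_join(obs, by = c("subject_id", "timepoint")) |>
    dplyr::left_join(energy[c("subject_id", "timepoint", "energy_intake",
                              "energy_density")],
                     by = c("subject_id", "timepoint"))

  # clamp energy targets into the attainable region
  comps <- hei_components()
  refs <- default_reference_table()
  idx <- match(comps, refs$component)
  intake <- sapply(seq_len(nrow(targets)), function(i) {
    invert_component_score(
      as.numeric(targets[i, paste0("hei_", comps)]),
      refs$max_points[idx], refs$reference_amount[idx],
      refs$direction[idx], refs$zero_point_multiple[idx])
  })
  ed_comp <- config$component_energy_density[comps]
  is_bev <- comps %in% c("beverages", "alcohol")
  comp_kcal <- colSums(intake * ed_comp)
  ei_min <- comp_kcal + 1
  ei_adj <- pmax(targets$energy_intake, ei_min)
  food_kcal <- colSums(intake * ed_comp * !is_bev) + (ei_adj - comp_kcal)
  food_g <- colSums(intake * !is_bev)
  ed_max <- food_kcal / pmax(food_g, 1)
  ed_adj <- pmin(pmax(targets$energy_density, 0.2), ed_max)
  n_adj <- sum(ei_adj != targets$energy_intake |
                 ed_adj != targets$energy_density)
  targets$energy_intake <- ei_adj
  targets$energy_density <- ed_adj

  sim$diaries <- diaries_from_scores(
    targets, refs = refs,
    component_energy_density = config$component_energy_density,
    day_shape = config$day_shape)
  if ("group" %in% names(targets)) {
    grp <- sim$subjects[c("subject_id", "group")]
    sim$diaries <- dplyr::left_join(sim$diaries, grp, by = "subject_id")
  }
  adj_long <- targets |>
    dplyr::select("subject_id", "timepoint", "energy_intake",
                  "energy_density") |>
    tidyr::pivot_longer(cols = c("energy_intake", "energy_density"),
                        names_to = "variable", values_to = "new_value")
  sim$panel <- sim$panel |>
    dplyr::left_join(adj_long,
                     by = c("subject_id", "timepoint", "variable")) |>
    dplyr::mutate(value = dplyr::if_else(
      !is.na(.data$new_value) & !is.na(.data$value),
      .data$new_value, .data$value)) |>
    dplyr::select(-"new_value")
  sim$n_energy_adjusted <- n_adj
  sim
}
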