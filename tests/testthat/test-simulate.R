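test_that("permuted blocks balance arms and are seed-reproducible", {
  expect_equal(table(permuted_block_randomize(4, 4, seed = 1))[["control"]],
               2)
  alloc <- permuted_block_randomize(152, 4, seed = 2)
  expect_equal(sum(alloc == "intervention"), 76)
  expect_identical(permuted_block_randomize(153, c(2, 4, 6), seed = 3),
                   permuted_block_randomize(153, c(2, 4, 6), seed = 3))
  # arm imbalance never exceeds the largest block size
  for (s in 1:10) {
    a <- permuted_block_randomize(153, c(2, 4, 6), seed = s)
    expect_lte(abs(sum(a == "intervention") - sum(a == "control")), 6)
  }
  expect_error(permuted_block_randomize(10, 3), "even")
})

test_that("simulated outcomes honour the design invariants", {
  cfg <- sim_config(n_total = 60)
  sim1 <- simulate_outcomes(cfg, seed = 5)
  sim2 <- simulate_outcomes(cfg, seed = 5)
  expect_identical(sim1$panel, sim2$panel)

  # baseline complete even with dropout
  t0 <- dplyr::filter(sim1$panel, timepoint == "t0")
  expect_false(anyNA(t0$value))
  # dropout is monotone: missing at t implies missing at later t
  wide <- sim1$panel |>
    dplyr::filter(variable == "hei_nvs_total") |>
    tidyr::pivot_wider(names_from = timepoint, values_from = value)
  expect_true(all(!(is.na(wide$t1) & !is.na(wide$t2))))
  expect_true(all(!(is.na(wide$t2) & !is.na(wide$t3))))

  none <- simulate_outcomes(sim_config(n_total = 40, target_dropout = 0),
                            seed = 6)
  expect_false(anyNA(none$panel$value))

  bad <- default_delta_cor()
  bad["hei_nvs_total", "energy_density"] <- 0.999
  bad["energy_density", "hei_nvs_total"] <- 0.999
  bad["hei_nvs_total", "fat_free_mass"] <- -0.999
  bad["fat_free_mass", "hei_nvs_total"] <- -0.999
  bad["energy_density", "fat_free_mass"] <- 0.9
  bad["fat_free_mass", "energy_density"] <- 0.9
  expect_error(sim_config(delta_cor = bad), "positive semi-definite")
})

test_that("large-sample draws match the configured moments", {
  # n chosen so the Monte-Carlo error sits well inside the 0.03 band
  n <- 40000
  cfg <- sim_config(n_total = n, target_dropout = 0)
  sim <- simulate_outcomes(cfg, seed = 8)
  # baseline BMI within 3 SE of the configured mean
  expect_lt(abs(mean(sim$subjects$bmi) - cfg$bmi_mean),
            3 * cfg$bmi_sd / sqrt(n))
  # configured change-score correlation recovered within 0.03
  d <- change_scores(sim$panel, to = "t1")
  expect_lt(abs(pearson_r(d$hei_nvs_total, d$energy_density) - (-0.30)),
            0.03)
  d3 <- change_scores(sim$panel, to = "t3")
  expect_lt(abs(pearson_r(d3$hei_nvs_total, d3$energy_density) - (-0.30)),
            0.03)
})

test_that("cumulative dropout matches the configured 22.9% on average", {
  set.seed(9)
  fracs <- purrr::map_dbl(1:8, function(i) {
    sim <- simulate_outcomes(sim_config(n_total = 1000))
    incomplete <- sim$panel |>
      dplyr::group_by(subject_id) |>
      dplyr::summarise(missing = anyNA(value))
    mean(incomplete$missing)
  })
  expect_lt(abs(mean(fracs) - 0.229), 0.02)
})

test_that("diaries invert the scoring rules exactly", {
  refs <- default_reference_table()
  targets <- tibble::tibble(subject_id = c("A", "B"), timepoint = "t0",
                            hei_vegetables = c(15, 6), hei_fruits = c(15, 3),
                            hei_grains = c(10, 5), hei_dairy = c(10, 7),
                            hei_fish = c(10, 0), hei_beverages = c(10, 9),
                            hei_meat = c(10, 4), hei_eggs = c(10, 8),
                            hei_spreadable_fats = c(10, 9.5),
                            hei_alcohol = c(10, 2))
  diary <- diaries_from_scores(targets, seed = 10)
  m <- mean_daily_amounts(diary)
  # full adequacy score implies intake at (or above) the reference
  expect_gte(m$grams_per_day[m$component == "vegetables" &
                               m$subject_id == "A"], 400 - 1e-9)
  # full moderation score implies intake at or below the reference
  expect_lte(m$grams_per_day[m$component == "alcohol" &
                               m$subject_id == "A"],
             refs$reference_amount[refs$component == "alcohol"] + 1e-9)
  rescored <- score_diaries(diary)
  for (col in paste0("hei_", hei_components())) {
    expect_equal(rescored[[col]][match(c("A", "B"), rescored$subject_id)],
                 targets[[col]], tolerance = 1e-12)
  }
})

test_that("unattainable targets and invalid scores are refused", {
  targets <- tibble::tibble(subject_id = "A", timepoint = "t0",
                            hei_vegetables = 15, hei_fruits = 15,
                            hei_grains = 10, hei_dairy = 10, hei_fish = 10,
                            hei_beverages = 10, hei_meat = 10, hei_eggs = 10,
                            hei_spreadable_fats = 10, hei_alcohol = 10)
  low_energy <- dplyr::mutate(targets, energy_intake = 200)
  expect_error(diaries_from_scores(low_energy, seed = 1), "unattainable")
  out_of_range <- dplyr::mutate(targets, hei_vegetables = 16)
  expect_error(diaries_from_scores(out_of_range), "outside")
})

test_that("a simulated trial's diaries reproduce its panel scores", {
  sim <- simulate_trial(sim_config(n_total = 30), seed = 12)
  scored <- score_diaries(sim$diaries)
  joined <- dplyr::inner_join(scored, sim$scores_wide,
                              by = c("subject_id", "timepoint"),
                              suffix = c("", ".target"))
  expect_gt(nrow(joined), 0)
  expect_lt(max(abs(joined$hei_nvs_total - joined$hei_nvs_total.target)),
            1e-9)
  # diaries exist exactly for the observed subject-timepoints
  observed <- sim$panel |>
    dplyr::filter(variable == "hei_nvs_total", !is.na(value)) |>
    dplyr::transmute(key = paste(subject_id, timepoint))
  diary_keys <- unique(paste(sim$diaries$subject_id, sim$diaries$timepoint))
  expect_setequal(diary_keys, observed$key)
})
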