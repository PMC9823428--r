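test_that("component scoring follows the piecewise-linear standards", {
  # adequacy: proportional up to the reference, capped at the maximum
  expect_equal(score_component(400, 15, 400, "adequacy"), 15)
  expect_equal(score_component(600, 15, 400, "adequacy"), 15)
  expect_equal(score_component(200, 15, 400, "adequacy"), 7.5)
  expect_equal(score_component(0, 15, 400, "adequacy"), 0)
  # moderation: plateau at max, linear to zero at k * reference
  expect_equal(score_component(0, 10, 80, "moderation"), 10)
  expect_equal(score_component(80, 10, 80, "moderation"), 10)
  expect_equal(score_component(120, 10, 80, "moderation", 2), 5)
  expect_equal(score_component(160, 10, 80, "moderation", 2), 0)
  expect_equal(score_component(500, 10, 80, "moderation", 2), 0)
  # continuity at the breakpoints
  eps <- 1e-9
  expect_equal(score_component(400 + eps, 15, 400, "adequacy"), 15,
               tolerance = 1e-6)
  expect_equal(score_component(80 + eps, 10, 80, "moderation", 2), 10,
               tolerance = 1e-6)
  expect_error(score_component(-1, 10, 80, "moderation"), "non-negative")
})

test_that("reference table invariants hold and survive the YAML round trip", {
  refs <- default_reference_table()
  expect_equal(sum(refs$max_points), 110)
  expect_setequal(refs$component[refs$max_points == 15],
                  c("vegetables", "fruits"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_reference_table(refs, path)
  expect_equal(as.data.frame(read_reference_table(path)),
               as.data.frame(refs))
  bad <- refs
  bad$max_points[bad$component == "grains"] <- 15
  expect_error(validate_reference_table(bad), "110|two components")
})

test_that("a fully compliant diary scores 110 and an all-worst diary 0", {
  refs <- default_reference_table()
  best <- constant_diary(full_compliance_amounts(refs))
  res <- score_record(best)
  expect_equal(res$total, 110)
  expect_length(res$component_scores, 10)
  expect_equal(res$component_scores[["vegetables"]], 15)
  expect_equal(res$component_scores[["fruits"]], 15)
  expect_equal(res$component_scores[["alcohol"]], 10)

  moderation <- refs[refs$direction == "moderation", ]
  worst <- constant_diary(stats::setNames(
    moderation$reference_amount * moderation$zero_point_multiple,
    moderation$component))
  expect_equal(score_record(worst)$total, 0)
})

test_that("the full score does not depend on the diary's energy content", {
  amounts <- full_compliance_amounts()
  lean <- constant_diary(amounts,
                         energy_per_g = stats::setNames(rep(0.2, 10),
                                                        hei_components())[names(amounts)])
  rich <- constant_diary(amounts,
                         energy_per_g = stats::setNames(rep(5, 10),
                                                        hei_components())[names(amounts)])
  expect_equal(score_record(lean)$total, 110)
  expect_equal(score_record(rich)$total, 110)
})

test_that("energy density follows the beverage-exclusion convention", {
  solid <- tibble::tibble(subject_id = "S1", timepoint = "t0", day = 1:7,
                          component = "grains", amount_g = 1600,
                          energy_kcal = 2000, is_beverage = FALSE)
  ed <- energy_density(solid)
  expect_equal(ed$energy_density, 14000 / 11200)

  with_bev <- dplyr::bind_rows(solid, tibble::tibble(
    subject_id = "S1", timepoint = "t0", day = 1:7, component = "beverages",
    amount_g = 1000, energy_kcal = 0, is_beverage = TRUE))
  expect_equal(energy_density(with_bev)$energy_density, 14000 / 11200)
  expect_lt(energy_density(with_bev,
                           include_beverages = TRUE)$energy_density,
            14000 / 11200)

  zero_kcal <- dplyr::mutate(solid, energy_kcal = 0)
  expect_equal(energy_density(zero_kcal)$energy_density, 0)
  only_bev <- dplyr::mutate(solid, is_beverage = TRUE)
  expect_error(energy_density(only_bev), "no eligible food mass")
})

test_that("energy intake averages total diary energy over observed days", {
  flat <- tibble::tibble(subject_id = "S1", timepoint = "t0", day = 1:7,
                         component = "grains", amount_g = 500,
                         energy_kcal = 2000, is_beverage = FALSE)
  expect_equal(energy_intake(flat)$energy_intake, 2000)
  uneven <- dplyr::mutate(flat,
                          energy_kcal = c(1500, 2500, 2000, 2200, 1800,
                                          2400, 2300))
  expect_equal(energy_intake(uneven)$energy_intake, 14700 / 7)
  expect_warning(out <- energy_intake(flat[0, ]), "empty")
  expect_equal(nrow(out), 0)
})

test_that("random diaries never break the caps, additivity or monotonicity", {
  set.seed(21)
  refs <- default_reference_table()
  n_diaries <- 1000
  scores <- score_diaries(purrr::map_dfr(seq_len(n_diaries), function(i) {
    amounts <- stats::setNames(stats::runif(10, 0, 2.5) *
                                 refs$reference_amount[match(hei_components(),
                                                             refs$component)],
                               hei_components())
    constant_diary(amounts, subject = sprintf("R%04d", i))
  }))
  score_cols <- paste0("hei_", hei_components())
  maxima <- refs$max_points[match(hei_components(), refs$component)]
  for (j in seq_along(score_cols)) {
    expect_true(all(scores[[score_cols[j]]] >= 0))
    expect_true(all(scores[[score_cols[j]]] <= maxima[j] + 1e-12))
  }
  expect_true(all(scores$hei_nvs_total <= 110 + 1e-9))
  expect_equal(scores$hei_nvs_total,
               rowSums(scores[score_cols]))

  # monotonicity of the component rule itself
  intakes <- sort(stats::runif(200, 0, 1000))
  adequacy <- score_component(intakes, 15, 400, "adequacy")
  expect_true(all(diff(adequacy) >= 0))
  moderation <- score_component(intakes, 10, 80, "moderation", 2)
  expect_true(all(diff(moderation) <= 0))
})
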