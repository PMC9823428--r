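test_that("the design matrix has the 8 contracted coefficients", {
  set.seed(41)
  fit <- fit_robust_lmm(lmm_panel(n = 30), outcome = "y")
  expect_equal(fit$coefficients$term,
               c("(Intercept)", "time_t0_t1", "time_t0_t2", "time_t0_t3",
                 "group_control", "time_t0_t1:group_control",
                 "time_t0_t2:group_control", "time_t0_t3:group_control"))
  expect_true(all(fit$weights > 0 & fit$weights <= 1))
})

test_that("noise-free data are interpolated exactly", {
  set.seed(42)
  beta <- c(77, 5, 9, 6, -1, -3, -5, -3.5)
  panel <- lmm_panel(n = 40, beta = beta, sigma_u = 0, sigma_e = 0)
  fit <- suppressWarnings(fit_robust_lmm(panel, outcome = "y"))
  expect_equal(fit$coefficients$estimate, beta, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("with unit weights the fit equals the lme4 maximum-likelihood fit", {
  skip_if_not_installed("lme4")
  set.seed(43)
  panel <- lmm_panel(n = 100)
  mine <- fit_robust_lmm(panel, outcome = "y", robust = FALSE)
  ref <- lme4::lmer(value ~ timepoint * I(group == "control") +
                      (1 | subject_id), data = panel, REML = FALSE)
  expect_equal(mine$coefficients$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-6)
  expect_equal(mine$sigma_e, stats::sigma(ref), tolerance = 1e-5)
  expect_equal(mine$sigma_u, sqrt(unname(unlist(lme4::VarCorr(ref)))),
               tolerance = 1e-4)
})

test_that("a known interaction is recovered on complete data", {
  set.seed(44)
  ests <- purrr::map_dbl(1:20, function(i) {
    panel <- lmm_panel(n = 150)
    fit <- fit_robust_lmm(panel, outcome = "y")
    fit$coefficients$estimate[7]
  })
  expect_lt(abs(mean(ests) - (-5)), 3 * stats::sd(ests) / sqrt(20))
})

test_that("degenerate model inputs are refused", {
  panel <- lmm_panel(n = 10)
  expect_error(fit_robust_lmm(panel, outcome = "missing_var"), "not found")
  one_tp <- dplyr::filter(panel, timepoint == "t0")
  expect_error(fit_robust_lmm(one_tp, outcome = "y"), "two or more")
  one_group <- dplyr::filter(panel, group == "control")
  expect_error(fit_robust_lmm(one_group, outcome = "y"), "each group")
})

test_that("Cohen's d matches hand arithmetic and is scale invariant", {
  make_change_panel <- function(delta, base = 70) {
    n <- length(delta)
    ids <- sprintf("C%02d", 1:n)
    dplyr::bind_rows(
      tibble::tibble(subject_id = ids, group = "intervention",
                     timepoint = "t0", variable = "y", value = base),
      tibble::tibble(subject_id = ids, group = "intervention",
                     timepoint = "t1", variable = "y", value = base + delta))
  }
  res <- cohens_d(make_change_panel(c(1, 2, 3)), "intervention", "t1", "y")
  expect_equal(res$d, 2)
  z <- stats::qnorm(0.975)
  expect_equal(res$ci_low, 2 - z * sqrt(1 / 3 + 4 / 6), tolerance = 1e-9)
  expect_equal(res$ci_high, 2 + z * sqrt(1 / 3 + 4 / 6), tolerance = 1e-9)

  sym <- cohens_d(make_change_panel(c(-2, -1, 0, 1, 2)), "intervention",
                  "t1", "y")
  expect_equal(sym$d, 0)

  set.seed(45)
  panel <- lmm_panel(n = 40)
  d1 <- cohens_d(panel, "control", "t2", "y")$d
  scaled <- dplyr::mutate(panel, value = value * 3.7)
  expect_equal(cohens_d(scaled, "control", "t2", "y")$d, d1)

  expect_error(cohens_d(make_change_panel(c(1, 1, 1)), "intervention",
                        "t1", "y"), "zero standardizing SD")
})

test_that("within-group d is recovered at the trial's effect magnitude", {
  set.seed(46)
  n <- 78
  d_hat <- purrr::map_dbl(1:200, function(i) {
    delta <- rnorm(n, 0.38 * 6, 6)
    ids <- sprintf("D%02d", 1:n)
    panel <- dplyr::bind_rows(
      tibble::tibble(subject_id = ids, group = "intervention",
                     timepoint = "t0", variable = "y", value = 70),
      tibble::tibble(subject_id = ids, group = "intervention",
                     timepoint = "t2", variable = "y", value = 70 + delta))
    cohens_d(panel, "intervention", "t2", "y")$d
  })
  expect_lt(abs(mean(d_hat) - 0.38), 3 * stats::sd(d_hat) / sqrt(200))
})

test_that("pooling m identical complete datasets equals the single fit", {
  set.seed(47)
  panel <- lmm_panel(n = 50)
  imp <- structure(list(datasets = rep(list(panel), 3), m = 3,
                        method = "none", maxit = 0, seed = NULL),
                   class = "hei_imputed")
  pooled <- fit_pooled(imp, outcome = "y")
  single <- fit_robust_lmm(panel, outcome = "y")
  expect_equal(pooled$coefficients$estimate, single$coefficients$estimate)
  expect_equal(pooled$coefficients$se, single$coefficients$se)

  es_pooled <- effect_size_table(imp, outcome = "y")
  es_single <- effect_size_table(panel, outcome = "y")
  expect_equal(es_pooled$d, es_single$d)
  expect_equal(es_pooled$ci_low, es_single$ci_low, tolerance = 1e-12)
})
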