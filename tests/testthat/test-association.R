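test_that("change scores subtract baseline per subject and variable", {
  panel <- tibble::tibble(
    subject_id = rep(c("A", "B"), each = 4),
    group = "intervention",
    timepoint = rep(c("t0", "t1"), 4),
    variable = rep(rep(c("hei_nvs_total", "energy_density"), each = 2), 2),
    value = c(77, 80, 1.6, 1.4, 70, 70, 1.8, 1.8))
  d <- change_scores(panel, to = "t1")
  expect_equal(d$hei_nvs_total[d$subject_id == "A"], 3)
  expect_equal(d$energy_density[d$subject_id == "A"], -0.2)
  expect_equal(d$hei_nvs_total[d$subject_id == "B"], 0)
  expect_equal(nrow(d), 2)
})

test_that("pearson_r matches hand product-moment results", {
  x <- c(1, 2, 3)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2)), 0.5)
  # affine invariance and sign flip
  set.seed(51)
  a <- rnorm(30)
  b <- rnorm(30)
  expect_equal(pearson_r(3 * a + 2, b), pearson_r(a, b))
  expect_equal(pearson_r(-a, b), -pearson_r(a, b))
  expect_error(pearson_r(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson_r(c(1, 1, 1), x), "zero variance")
})

test_that("the BC bootstrap interval is reproducible and well-formed", {
  set.seed(52)
  x <- rnorm(60)
  y <- 0.4 * x + rnorm(60)
  ci1 <- bc_bootstrap_ci(x, y, B = 1000, seed = 7)
  ci2 <- bc_bootstrap_ci(x, y, B = 1000, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1$ci_low, ci1$r)
  expect_gte(ci1$ci_high, ci1$r)
  expect_gte(ci1$ci_low, -1)
  expect_lte(ci1$ci_high, 1)

  for (i in 1:10) {
    x <- rnorm(40)
    y <- rnorm(40, 0.3 * x)
    ci <- bc_bootstrap_ci(x, y, B = 1000)
    expect_true(ci$ci_low <= ci$r && ci$r <= ci$ci_high)
  }

  expect_error(bc_bootstrap_ci(rnorm(5), rnorm(5), B = 1000), "at least 10")
  expect_error(bc_bootstrap_ci(rnorm(20), rnorm(20), B = 500),
               "at least 1000")
  expect_warning(out <- bc_bootstrap_ci(1:20, 2 * (1:20), B = 1000),
                 "linear")
  expect_equal(out$ci_low, 1)
  expect_equal(out$ci_high, 1)
})

test_that("BCa endpoints agree with the boot package on a fixture", {
  skip_if_not_installed("boot")
  set.seed(53)
  x <- rnorm(60)
  y <- 0.5 * x + rnorm(60)
  mine <- bc_bootstrap_ci(x, y, B = 5000, seed = 11, accelerated = TRUE)
  b <- boot::boot(data.frame(x, y),
                  function(d, i) stats::cor(d$x[i], d$y[i]), R = 5000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  expect_equal(c(mine$ci_low, mine$ci_high), ref, tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("with a symmetric bootstrap distribution BC is plain percentile", {
  # near-zero bias correction: the BC endpoints must sit at the ordinary
  # percentile positions of the same bootstrap draw
  set.seed(54)
  x <- rnorm(200)
  y <- rnorm(200)
  ci <- bc_bootstrap_ci(x, y, B = 4000, seed = 9)
  set.seed(9)
  r_star <- heinvs:::boot_cor_replicates(x, y, 4000)
  probs <- stats::pnorm(ci$z0 + (ci$z0 + stats::qnorm(c(0.025, 0.975))))
  expect_equal(c(ci$ci_low, ci$ci_high),
               heinvs:::norm_inter_quantile(r_star, probs))
  expect_lt(abs(ci$z0), 0.1)
  plain <- unname(stats::quantile(r_star, c(0.025, 0.975), type = 6))
  expect_lt(max(abs(c(ci$ci_low, ci$ci_high) - plain)), 0.02)
})

test_that("the correlation table flags the configured association", {
  set.seed(55)
  sim <- simulate_outcomes(sim_config(n_total = 153, target_dropout = 0))
  tab <- correlation_table(sim$panel, variables = c("energy_density",
                                                    "energy_intake"),
                           B = 1000, seed = 3)
  expect_equal(nrow(tab), 4)
  ed <- dplyr::filter(tab, variable == "energy_density")
  expect_true(all(ed$r < 0))
  expect_true(all(ed$significant))
})

test_that("m identical complete datasets reproduce the single-dataset table", {
  set.seed(56)
  sim <- simulate_outcomes(sim_config(n_total = 60, target_dropout = 0))
  imp <- structure(list(datasets = rep(list(sim$panel), 3), m = 3,
                        method = "none", maxit = 0, seed = NULL),
                   class = "hei_imputed")
  tab_m <- correlation_table(imp, variables = c("energy_density", "hdl"),
                             B = 1000, seed = 13)
  tab_1 <- correlation_table(sim$panel,
                             variables = c("energy_density", "hdl"),
                             B = 1000, seed = 13)
  expect_equal(tab_m$r, tab_1$r)
  expect_equal(tab_m$ci_low, tab_1$ci_low, tolerance = 1e-12)
  expect_equal(tab_m$ci_high, tab_1$ci_high, tolerance = 1e-12)
})
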