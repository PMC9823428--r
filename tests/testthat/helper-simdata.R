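# Shared builders for small synthetic inputs used across the suite.

# A diary with one entry per component per day at fixed daily amounts.
constant_diary <- function(amounts, days = 7, subject = "S1",
                           timepoint = "t0", energy_per_g = NULL) {
  if (is.null(energy_per_g)) {
    energy_per_g <- stats::setNames(rep(1, length(amounts)), names(amounts))
  }
  purrr::map_dfr(names(amounts), function(comp) {
    tibble::tibble(
      subject_id = subject, timepoint = timepoint, day = seq_len(days),
      component = comp, amount_g = amounts[[comp]],
      energy_kcal = amounts[[comp]] * energy_per_g[[comp]],
      is_beverage = comp %in% c("beverages", "alcohol"))
  })
}

# Daily amounts meeting every adequacy reference with zero moderation intake.
full_compliance_amounts <- function(refs = default_reference_table()) {
  adequacy <- refs[refs$direction == "adequacy", ]
  stats::setNames(adequacy$reference_amount, adequacy$component)
}

# A long outcome panel from the time-by-group fixed-effect model with a
# subject random intercept; optional gross outliers and monotone MAR dropout.
lmm_panel <- function(n = 150, beta = c(77, 5, 9, 6, -5, -3, -5, -3.5),
                      sigma_u = 5, sigma_e = 5, outlier_frac = 0,
                      outcome = "y") {
  ids <- sprintf("P%04d", seq_len(n))
  grp <- rep(c("intervention", "control"), length.out = n)
  df <- tidyr::crossing(subject_id = ids,
                        timepoint = c("t0", "t1", "t2", "t3"))
  df$group <- grp[match(df$subject_id, ids)]
  x <- heinvs:::lmm_design(df$timepoint, df$group)
  u <- stats::rnorm(n, 0, sigma_u)
  df$value <- as.vector(x %*% beta) + u[match(df$subject_id, ids)] +
    stats::rnorm(nrow(df), 0, sigma_e)
  if (outlier_frac > 0) {
    k <- sample(nrow(df), round(outlier_frac * nrow(df)))
    df$value[k] <- df$value[k] + 50
  }
  df$variable <- outcome
  df[c("subject_id", "group", "timepoint", "variable", "value")]
}

# Monotone MAR dropout: the per-stage hazard increases with the subject's
# baseline outcome; `target` is the cumulative dropout fraction.
add_mar_dropout <- function(panel, target = 0.3, slope = 0.5) {
  ids <- unique(panel$subject_id)
  n <- length(ids)
  t0 <- panel[panel$timepoint == "t0", ]
  y0 <- t0$value[match(ids, t0$subject_id)]
  z <- as.vector(scale(y0))
  p_stage <- 1 - (1 - target)^(1 / 3)
  stage <- rep(NA_integer_, n)
  at_risk <- rep(TRUE, n)
  for (s in 1:3) {
    d <- at_risk & (stats::runif(n) <
                      stats::plogis(stats::qlogis(p_stage) + slope * z))
    stage[d] <- s
    at_risk <- at_risk & !d
  }
  tp_index <- match(panel$timepoint, c("t0", "t1", "t2", "t3")) - 1L
  subj_stage <- stage[match(panel$subject_id, ids)]
  panel$value[!is.na(subj_stage) & tp_index >= subj_stage] <- NA_real_
  panel
}
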