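lmm_terms <- function() {
  c("(Intercept)", "time_t0_t1", "time_t0_t2", "time_t0_t3",
    "group_control", "time_t0_t1:group_control",
    "time_t0_t2:group_control", "time_t0_t3:group_control")
}

# Design matrix for the time-by-group model with reference levels t0 and
# intervention: intercept, three time contrasts, the control main effect,
# and the three time-by-control interactions (8 columns).
lmm_design <- function(timepoint, group) {
  t1 <- as.numeric(timepoint == "t1")
  t2 <- as.numeric(timepoint == "t2")
  t3 <- as.numeric(timepoint == "t3")
  g <- as.numeric(group == "control")
  x <- cbind(1, t1, t2, t3, g, t1 * g, t2 * g, t3 * g)
  colnames(x) <- lmm_terms()
  x
}

# Weighted ML fit of a random-intercept mixed model. The marginal
# covariance of subject j is sigma2 * (diag(1/w_j) + lambda * J) with
# lambda = sigma_u^2 / sigma2; the per-subject inverse is available in
# closed form (Woodbury), so the profile deviance in log(lambda) is cheap
# and is minimised with Brent's method. Weights w are fixed case weights.
wlmm_ml <- function(y, x, subject, w = rep(1, length(y)), lambda = NULL) {
  subject <- as.integer(factor(subject))
  n <- length(y)
  p <- ncol(x)
  sw <- rowsum(w, subject)[, 1]
  sqw <- sqrt(w)
  xw <- x * sqw
  xtwx <- crossprod(xw)
  a_x <- rowsum(x * w, subject)           # per-subject sums of w * x
  a_y <- rowsum(y * w, subject)[, 1]
  xtwy <- crossprod(x, w * y)
  sum_wy2 <- sum(w * y^2)

  profile <- function(log_lambda) {
    lambda <- exp(log_lambda)
    f <- lambda / (1 + lambda * sw)
    xtvx <- xtwx - crossprod(a_x * sqrt(f))
    xtvy <- xtwy - crossprod(a_x, f * a_y)
    beta <- solve(xtvx, xtvy)
    # r' V^{-1} r with r = y - x beta, using the same aggregates
    quad <- sum_wy2 - 2 * sum(beta * xtwy) + sum(beta * (xtwx %*% beta)) -
      sum(f * (a_y - a_x %*% beta)^2)
    logdet <- -sum(log(w)) + sum(log1p(lambda * sw))
    dev <- n * log(max(quad, 1e-300)) + logdet
    list(dev = dev, beta = beta, quad = quad, lambda = lambda,
         xtvx = xtvx, f = f)
  }
  fit <- if (is.null(lambda)) {
    opt <- stats::optimize(function(ll) profile(ll)$dev,
                           interval = c(-15, 10), tol = 1e-10)
    profile(opt$minimum)
  } else {
    profile(log(lambda))
  }
  sigma2 <- fit$quad / n
  beta <- fit$beta[, 1]
  names(beta) <- colnames(x)
  vcov_beta <- solve(fit$xtvx) * sigma2
  u <- fit$f * (a_y - (a_x %*% fit$beta)[, 1])   # BLUP random intercepts
  resid_cond <- y - (x %*% fit$beta)[, 1] - u[subject]
  list(beta = beta, vcov = vcov_beta, sigma2 = sigma2,
       sigma_u2 = fit$lambda * sigma2, lambda = fit$lambda, u = u,
       resid = resid_cond, loglik = -0.5 * (fit$dev + n * log(2 * pi) + n))
}

#' Robust linear mixed model of a longitudinal outcome
#'
#' Fits the time-by-group model
#' \deqn{y_{ij} = \beta_0 + \sum_t \beta_t [time=t] + \beta_g [control] +
#'   \sum_t \beta_{tg} [time=t][control] + u_i + \epsilon_{ij}}
#' with a subject random intercept, robustified by iteratively reweighted
#' maximum likelihood: after each weighted fit the conditional residuals are
#' scaled by their MAD and converted to Huber case weights
#' \eqn{w = \min(1, k s / |e|)} (tuning constant `huber_k = 1.345`), until
#' the largest coefficient change (relative to the coefficient's magnitude,
#' or absolute below magnitude 1) falls below `tol` or `max_iter` iterations
#' are reached. With all weights forced to 1 (`robust = FALSE`) the fit is
#' the ordinary ML solution. Inference is Wald with a normal reference
#' (robust mixed models have no exact small-sample df).
#'
#' @param data A long trial panel or any data frame with columns
#'   `subject_id`, `group`, `timepoint` and either a `value`/`variable` pair
#'   or the outcome as its own column.
#' @param outcome Outcome variable name (default `"hei_nvs_total"`).
#' @param robust Apply Huber reweighting (default) or plain ML.
#' @param huber_k Huber tuning constant.
#' @param tol Convergence tolerance on the coefficients.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `hei_lmm`: list with `coefficients` (tibble
#'   `term, estimate, se, statistic, p_value`), `sigma_u`, `sigma_e`,
#'   `lambda`, `weights`, `iterations`, `converged`, `n_obs`, `n_subjects`.
#' @export
fit_robust_lmm <- function(data, outcome = "hei_nvs_total", robust = TRUE,
                           huber_k = 1.345, tol = 1e-8, max_iter = 100) {
  df <- extract_outcome(data, outcome)
  if (dplyr::n_distinct(df$timepoint) < 2) {
    stop("outcome must be observed at two or more timepoints", call. = FALSE)
  }
  n_per_group <- df |>
    dplyr::distinct(.data$subject_id, .data$group) |>
    dplyr::count(.data$group)
  if (nrow(n_per_group) < 2 || any(n_per_group$n < 2)) {
    stop("need at least 2 subjects in each group", call. = FALSE)
  }
  x <- lmm_design(df$timepoint, df$group)
  y <- df$value
  subject <- df$subject_id
  n <- length(y)

  w <- rep(1, n)
  fit <- wlmm_ml(y, x, subject, w)
  iterations <- 0L
  converged <- TRUE
  trace <- numeric(0)
  if (robust) {
    converged <- FALSE
    s <- NA_real_
    for (it in seq_len(max_iter)) {
      # the MAD is an order statistic and would keep the weights jittering at
      # the 1e-8 level forever; once it has stabilised, freeze it so the
      # smooth beta/weight iteration can converge to full precision
      if (it <= 20) s <- stats::mad(fit$resid, center = 0)
      if (s < 1e-12) {
        converged <- TRUE
        break
      }
      r <- abs(fit$resid) / s
      w <- pmin(1, huber_k / pmax(r, 1e-300))
      beta_old <- fit$beta
      # the profiled variance ratio is re-optimised while it still moves and
      # then held, so its optimiser noise cannot mask coefficient convergence
      fit <- wlmm_ml(y, x, subject, w,
                     lambda = if (it > 25) fit$lambda)
      delta <- max(abs(fit$beta - beta_old) / pmax(abs(beta_old), 1))
      trace <- c(trace, delta)
      iterations <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      stop("robust IRLS did not converge in ", max_iter,
           " iterations; last coefficient changes: ",
           paste(signif(utils::tail(trace, 5), 3), collapse = ", "),
           call. = FALSE)
    }
  }
  if (fit$lambda < 1e-8) {
    warning("random-intercept variance is essentially zero; ",
            "the fit reduces to a fixed-effects model", call. = FALSE)
  }
  se <- unname(sqrt(diag(fit$vcov)))
  z <- unname(fit$beta) / se
  coefs <- tibble::tibble(term = lmm_terms(), estimate = unname(fit$beta),
                          se = se,
                          statistic = z,
                          p_value = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = coefs, sigma_u = sqrt(fit$sigma_u2),
                 sigma_e = sqrt(fit$sigma2), lambda = fit$lambda,
                 weights = w, iterations = iterations, converged = converged,
                 n_obs = n, n_subjects = dplyr::n_distinct(subject),
                 outcome = outcome, robust = robust),
            class = "hei_lmm")
}

# Accept either the long panel (variable/value) or a flat data frame with
# the outcome as a column; return complete rows of subject, group,
# timepoint, value.
extract_outcome <- function(data, outcome) {
  data <- tibble::as_tibble(data)
  if (all(c("variable", "value") %in% names(data))) {
    df <- data |>
      dplyr::filter(.data$variable == outcome) |>
      dplyr::select("subject_id", "group", "timepoint", "value")
  } else if (outcome %in% names(data)) {
    df <- data |>
      dplyr::select("subject_id", "group", "timepoint",
                    value = dplyr::all_of(outcome))
  } else {
    stop("outcome '", outcome, "' not found in data", call. = FALSE)
  }
  df <- dplyr::filter(df, !is.na(.data$value))
  if (nrow(df) == 0) {
    stop("outcome '", outcome, "' not found in data (no observed values)",
         call. = FALSE)
  }
  df
}

#' @export
print.hei_lmm <- function(x, ...) {
  cat(sprintf("%s linear mixed model of %s (%d obs, %d subjects)\n",
              if (x$robust) "Robust (Huber IRLS)" else "ML",
              x$outcome, x$n_obs, x$n_subjects))
  cat(sprintf("sigma_u = %.3f, sigma_e = %.3f, %d IRLS iterations\n\n",
              x$sigma_u, x$sigma_e, x$iterations))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Within-group Cohen's d of the change from baseline
#'
#' Standardized within-group change: per subject the change score
#' \eqn{\Delta = y(t) - y(t_0)} is formed and
#' \eqn{d = \bar{\Delta} / SD(\Delta)}, with the normal-approximation
#' confidence interval \eqn{d \pm z_{1-\alpha/2}\sqrt{1/n + d^2/(2n)}}.
#' Bands: |d| = 0.2 small, 0.5 medium, 0.8 large. Standardizing by the
#' baseline SD instead is available via `standardizer`.
#'
#' @param data Long panel or flat data frame (see [fit_robust_lmm()]).
#' @param group `"intervention"` or `"control"`.
#' @param to Endpoint timepoint (`"t1"`, `"t2"` or `"t3"`).
#' @param outcome Outcome variable name.
#' @param standardizer `"change"` (SD of the change scores, default) or
#'   `"baseline"` (SD of the baseline values).
#' @param level Confidence level.
#' @return Tibble `group, interval, n, d, ci_low, ci_high`.
#' @export
cohens_d <- function(data, group, to, outcome = "hei_nvs_total",
                     standardizer = c("change", "baseline"), level = 0.95) {
  standardizer <- match.arg(standardizer)
  df <- extract_outcome(data, outcome) |>
    dplyr::filter(.data$group == !!group,
                  .data$timepoint %in% c("t0", to)) |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value") |>
    dplyr::filter(!is.na(.data$t0), !is.na(.data[[to]]))
  n <- nrow(df)
  if (n < 2) stop("need at least 2 subjects with both endpoints",
                  call. = FALSE)
  delta <- df[[to]] - df$t0
  denom <- if (standardizer == "change") stats::sd(delta) else
    stats::sd(df$t0)
  if (denom == 0) stop("zero standardizing SD: effect size undefined",
                       call. = FALSE)
  d <- mean(delta) / denom
  se <- sqrt(1 / n + d^2 / (2 * n))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(group = group, interval = paste0("t0_", to), n = n, d = d,
                 ci_low = d - z * se, ci_high = d + z * se)
}

#' Table of pooled effect sizes
#'
#' Cohen's d per group and interval (the Table-4 layout), pooled across
#' imputations by Rubin's rules on the d scale with the
#' normal-approximation SE as the within-imputation SE.
#'
#' @param data A `hei_imputed` object or a single (complete) panel.
#' @inheritParams cohens_d
#' @return Tibble `group, interval, n, d, ci_low, ci_high`.
#' @export
effect_size_table <- function(data, outcome = "hei_nvs_total",
                              standardizer = c("change", "baseline"),
                              level = 0.95) {
  standardizer <- match.arg(standardizer)
  panels <- if (inherits(data, "hei_imputed")) data$datasets else list(data)
  z <- stats::qnorm(1 - (1 - level) / 2)
  grid <- tidyr::crossing(group = c("intervention", "control"),
                          to = c("t1", "t2", "t3"))
  purrr::pmap_dfr(grid, function(group, to) {
    per_imp <- purrr::map_dfr(panels, cohens_d, group = group, to = to,
                              outcome = outcome, standardizer = standardizer,
                              level = level)
    if (nrow(per_imp) == 1) return(per_imp)
    se_within <- (per_imp$ci_high - per_imp$ci_low) / (2 * z)
    pooled <- pool_rubin(per_imp$d, se_within)
    tibble::tibble(group = group, interval = paste0("t0_", to),
                   n = round(mean(per_imp$n)), d = pooled$estimate,
                   ci_low = pooled$estimate - z * pooled$se,
                   ci_high = pooled$estimate + z * pooled$se)
  }) |>
    dplyr::arrange(dplyr::desc(.data$group), .data$interval)
}

#' Fit the robust mixed model on every imputation and pool
#'
#' Runs [fit_robust_lmm()] on each completed dataset and combines the
#' coefficients and standard errors with Rubin's rules
#' ([pool_rubin()], Barnard–Rubin df with the complete-data df);
#' p-values come from the pooled t statistics.
#'
#' @param imputed A `hei_imputed` object.
#' @inheritParams fit_robust_lmm
#' @param max_failures Largest tolerated fraction of per-imputation fit
#'   failures before the pooled fit errors.
#' @return A list of class `hei_pooled_lmm` with `coefficients` (tibble
#'   `term, estimate, se, statistic, df, p_value`), `m_used`, `failures`.
#' @export
fit_pooled <- function(imputed, outcome = "hei_nvs_total", robust = TRUE,
                       huber_k = 1.345, max_failures = 0.2) {
  stopifnot(inherits(imputed, "hei_imputed"))
  fits <- purrr::map(imputed$datasets, function(d) {
    tryCatch(fit_robust_lmm(d, outcome = outcome, robust = robust,
                            huber_k = huber_k),
             error = function(e) e)
  })
  failed <- purrr::map_lgl(fits, inherits, "error")
  if (mean(failed) > max_failures) {
    stop("more than ", round(100 * max_failures),
         "% of per-imputation fits failed; first error: ",
         conditionMessage(fits[[which(failed)[1]]]), call. = FALSE)
  }
  if (any(failed)) {
    warning(sum(failed), " per-imputation fit(s) failed and were dropped",
            call. = FALSE)
  }
  fits <- fits[!failed]
  est <- sapply(fits, function(f) f$coefficients$estimate)
  ses <- sapply(fits, function(f) f$coefficients$se)
  dfcom <- fits[[1]]$n_obs - length(lmm_terms())
  coefs <- purrr::map_dfr(seq_along(lmm_terms()), function(j) {
    pooled <- pool_rubin(est[j, ], ses[j, ], dfcom = dfcom)
    stat <- pooled$estimate / pooled$se
    tibble::tibble(term = lmm_terms()[j], estimate = pooled$estimate,
                   se = pooled$se, statistic = stat, df = pooled$df,
                   p_value = 2 * stats::pt(-abs(stat), df = pooled$df))
  })
  structure(list(coefficients = coefs, m_used = length(fits),
                 failures = sum(failed), outcome = outcome),
            class = "hei_pooled_lmm")
}

#' @export
print.hei_pooled_lmm <- function(x, ...) {
  cat(sprintf("Pooled robust mixed model of %s over %d imputations\n\n",
              x$outcome, x$m_used))
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}
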