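#' Multiple imputation of the trial panel by chained equations
#'
#' Imputes the missing follow-up cells of a long-format trial table with
#' single-level chained equations on the subject-wide layout (one column per
#' variable-timepoint). Each incomplete column is regressed on the treatment
#' group, the same variable at the other timepoints (in particular its
#' complete baseline), and the concurrent diet-quality context
#' (`hei_nvs_total` and `energy_density` at the same timepoint); draws are
#' either predictive-mean-matching (`"pmm"`, the default: a Bayesian
#' regression draw followed by donor matching among the `k` closest observed
#' predictions, robust to the bounded score margins) or fully parametric
#' Bayesian-normal draws (`"norm"`). Imputed component scores are clamped to
#' their score range.
#'
#' @param trial Validated long panel ([validate_trial_table()]); baseline
#'   must be complete.
#' @param m Number of imputations (>= 2; the trial analysis used 50).
#' @param maxit Chained-equation sweeps per imputation.
#' @param method `"pmm"` or `"norm"`.
#' @param k Donor-pool size for PMM.
#' @param seed Optional integer seed.
#' @param refs Reference table used to clamp imputed component scores.
#' @return An object of class `hei_imputed`: a list with `datasets` (a list
#'   of `m` completed long panels), `m`, `method` and `seed`.
#' @export
impute_trial <- function(trial, m = 50, maxit = 5,
                         method = c("pmm", "norm"), k = 5, seed = NULL,
                         refs = default_reference_table()) {
  method <- match.arg(method)
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  trial <- validate_trial_table(trial)
  wide <- trial_to_wide(trial)
  value_cols <- setdiff(names(wide), c("subject_id", "group"))
  x_group <- as.numeric(wide$group == "control")

  n_obs_per_col <- colSums(!is.na(wide[value_cols]))
  if (any(n_obs_per_col == 0)) {
    stop("variable with zero observed values: ",
         value_cols[which(n_obs_per_col == 0)[1]], call. = FALSE)
  }
  incomplete <- value_cols[colSums(is.na(wide[value_cols])) > 0]

  clamp_limits <- function(col) {
    v <- sub("\\.[^.]+$", "", col)
    if (!startsWith(v, "hei_") || v == "hei_nvs_total") return(NULL)
    comp <- sub("^hei_", "", v)
    c(0, refs$max_points[refs$component == comp])
  }

  predictors_for <- function(col, cols) {
    v <- sub("\\.[^.]+$", "", col)
    t <- sub("^.*\\.", "", col)
    same_var <- setdiff(grep(paste0("^", v, "\\."), cols, value = TRUE), col)
    concurrent <- intersect(
      paste(setdiff(c("hei_nvs_total", "energy_density"), v), t, sep = "."),
      cols)
    unique(c(same_var, concurrent))
  }
  pred_sets <- lapply(stats::setNames(incomplete, incomplete),
                      predictors_for, cols = value_cols)

  datasets <- vector("list", m)
  for (imp in seq_len(m)) {
    dat <- as.matrix(wide[value_cols])
    miss <- is.na(dat)
    # initial fill: random draws from each column's observed values
    for (col in incomplete) {
      obs <- dat[!miss[, col], col]
      dat[miss[, col], col] <- sample(obs, sum(miss[, col]), replace = TRUE)
    }
    for (iter in seq_len(maxit)) {
      for (col in incomplete) {
        mis_rows <- miss[, col]
        x <- cbind(1, x_group, dat[, pred_sets[[col]], drop = FALSE])
        y_obs <- dat[!mis_rows, col]
        draw <- bayes_lm_draw(x[!mis_rows, , drop = FALSE], y_obs)
        if (method == "norm") {
          imp_vals <- x[mis_rows, , drop = FALSE] %*% draw$beta_star +
            stats::rnorm(sum(mis_rows), 0, draw$sigma_star)
        } else {
          yhat_obs <- x[!mis_rows, , drop = FALSE] %*% draw$beta_hat
          yhat_mis <- x[mis_rows, , drop = FALSE] %*% draw$beta_star
          imp_vals <- pmm_match(yhat_obs, yhat_mis, y_obs, k)
        }
        lim <- clamp_limits(col)
        if (!is.null(lim)) imp_vals <- pmin(pmax(imp_vals, lim[1]), lim[2])
        dat[mis_rows, col] <- imp_vals
      }
    }
    completed <- wide
    completed[value_cols] <- as.data.frame(dat)
    datasets[[imp]] <- wide_to_trial(completed)
  }
  structure(list(datasets = datasets, m = m, method = method,
                 maxit = maxit, seed = seed),
            class = "hei_imputed")
}

# Posterior draw for a normal linear model with the standard noninformative
# prior: sigma*^2 = SS/chisq(df), beta* ~ N(beta_hat, sigma*^2 (X'X)^-1).
# A small ridge keeps near-collinear predictor sets workable.
bayes_lm_draw <- function(x, y) {
  p <- ncol(x)
  xtx <- crossprod(x) + diag(1e-8 * max(diag(crossprod(x))), p)
  xty <- crossprod(x, y)
  r_chol <- chol(xtx)
  beta_hat <- backsolve(r_chol, forwardsolve(t(r_chol), xty))
  resid <- y - x %*% beta_hat
  df <- max(length(y) - p, 1)
  sigma_star <- sqrt(sum(resid^2) / stats::rchisq(1, df))
  beta_star <- beta_hat +
    backsolve(r_chol, stats::rnorm(p)) * sigma_star
  list(beta_hat = beta_hat, beta_star = beta_star, sigma_star = sigma_star)
}

# Type-1 predictive mean matching: each missing case receives the observed
# outcome of one donor drawn among the k observed cases whose predictions
# (under beta_hat) are closest to the case's prediction under beta_star.
pmm_match <- function(yhat_obs, yhat_mis, y_obs, k) {
  k <- min(k, length(y_obs))
  vapply(yhat_mis, function(yh) {
    d <- abs(yhat_obs - yh)
    donors <- order(d)[seq_len(k)]
    y_obs[donors[sample.int(k, 1)]]
  }, numeric(1))
}

#' Extract one completed dataset
#'
#' @param imputed A `hei_imputed` object.
#' @param i Which imputation.
#' @return The i-th completed long panel.
#' @export
complete_panel <- function(imputed, i = 1) {
  stopifnot(inherits(imputed, "hei_imputed"))
  imputed$datasets[[i]]
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and standard errors: the pooled
#' point is the mean, the total variance is the within-imputation variance
#' plus `(1 + 1/m)` times the between-imputation variance, and the degrees
#' of freedom follow Barnard–Rubin's small-sample formula when a
#' complete-data df is supplied (classic Rubin df otherwise).
#'
#' @param estimates Per-imputation point estimates (length m >= 2).
#' @param ses Per-imputation standard errors (positive).
#' @param dfcom Complete-data degrees of freedom (default `Inf`).
#' @return A list with `estimate`, `se`, `within`, `between`, `total`, `df`,
#'   `m`.
#' @examples
#' pool_rubin(c(0, 2), c(1, 1))  # point 1, total variance 4
#' @export
pool_rubin <- function(estimates, ses, dfcom = Inf) {
  if (length(estimates) < 2) {
    stop("pooling requires at least 2 per-imputation estimates",
         call. = FALSE)
  }
  if (length(estimates) != length(ses)) {
    stop("estimates and ses must have equal length", call. = FALSE)
  }
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  m <- length(estimates)
  qbar <- mean(estimates)
  w <- mean(ses^2)
  b <- if (m > 1) stats::var(estimates) else 0
  t_var <- w + (1 + 1 / m) * b
  if (b == 0 || m == 1) {
    df <- dfcom
  } else {
    lambda <- (1 + 1 / m) * b / t_var
    df_old <- (m - 1) / lambda^2
    df <- if (is.finite(dfcom)) {
      df_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      1 / (1 / df_old + 1 / df_obs)
    } else {
      df_old
    }
  }
  list(estimate = qbar, se = sqrt(t_var), within = w, between = b,
       total = t_var, df = df, m = m)
}
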