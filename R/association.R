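#' Change scores from baseline
#'
#' For every subject and variable, the change `value(to) - value(t0)`.
#' Groups are pooled: the association analysis is run independently of study
#' arm. Subjects missing either endpoint keep an `NA` change (complete-case
#' callers drop them; after imputation none remain).
#'
#' @param panel Long trial table.
#' @param to Endpoint timepoint.
#' @return Wide tibble: `subject_id`, then one change-score column per
#'   variable.
#' @export
change_scores <- function(panel, to = c("t1", "t3", "t2")) {
  to <- match.arg(to)
  panel <- tibble::as_tibble(panel)
  panel |>
    dplyr::filter(.data$timepoint %in% c("t0", to)) |>
    dplyr::select("subject_id", "timepoint", "variable", "value") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "value") |>
    dplyr::mutate(delta = .data[[to]] - .data$t0) |>
    dplyr::select("subject_id", "variable", "delta") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "delta")
}

#' Pearson product-moment correlation
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs, both with
#'   positive variance).
#' @return The correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a variable has zero variance",
         call. = FALSE)
  }
  stats::cor(x, y)
}

# Bootstrap quantiles with interpolation on the normal-quantile scale, the
# convention of bootstrap CI practice: order statistic k = (B + 1) * p,
# interpolating between neighbours linearly in qnorm(p).
norm_inter_quantile <- function(t, probs) {
  t <- sort(t)
  b <- length(t)
  vapply(probs, function(p) {
    k <- (b + 1) * p
    if (k <= 1) return(t[1])
    if (k >= b) return(t[b])
    lo <- floor(k)
    frac <- (stats::qnorm(p) - stats::qnorm(lo / (b + 1))) /
      (stats::qnorm((lo + 1) / (b + 1)) - stats::qnorm(lo / (b + 1)))
    t[lo] + frac * (t[lo + 1] - t[lo])
  }, numeric(1))
}

# Bootstrap correlations for B resamples at once: indices are drawn as an
# n x B matrix and the product-moment formula is evaluated column-wise.
boot_cor_replicates <- function(x, y, B) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  mx <- colMeans(xb)
  my <- colMeans(yb)
  sxy <- colMeans(xb * yb) - mx * my
  sxx <- colMeans(xb * xb) - mx^2
  syy <- colMeans(yb * yb) - my^2
  sxy / sqrt(sxx * syy)
}

#' Bias-corrected bootstrap confidence interval for a Pearson correlation
#'
#' Resamples the `n` pairs with replacement `B` times, computes the
#' bootstrap distribution of r, and forms the bias-corrected (BC) percentile
#' interval: with \eqn{z_0 = \Phi^{-1}(\#\{r^* < \hat r\}/B)} the endpoints
#' sit at the bootstrap quantiles \eqn{\Phi(z_0 + (z_0 \pm z_{\alpha}) /
#' (1 - a(z_0 \pm z_{\alpha})))}; the acceleration `a` is 0 for plain BC
#' (the default) or the jackknife skewness estimate for BCa.
#'
#' @inheritParams pearson_r
#' @param B Number of bootstrap replicates (>= 1000).
#' @param seed Optional integer seed.
#' @param accelerated Use BCa instead of plain BC.
#' @param level Confidence level.
#' @return Tibble `r, ci_low, ci_high, B, z0, accel, significant`
#'   (`significant` = the interval excludes 0).
#' @export
bc_bootstrap_ci <- function(x, y, B = 5000, seed = NULL,
                            accelerated = FALSE, level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 10) stop("need at least 10 complete pairs", call. = FALSE)
  if (B < 1000) stop("B must be at least 1000", call. = FALSE)
  r_hat <- pearson_r(x, y)
  if (abs(r_hat) >= 1 - 1e-12) {
    warning("perfectly linear data: interval collapsed to the point",
            call. = FALSE)
    return(tibble::tibble(r = r_hat, ci_low = r_hat, ci_high = r_hat,
                          B = B, z0 = 0, accel = 0,
                          significant = r_hat != 0))
  }
  r_star <- boot_cor_replicates(x, y, B)
  r_star <- r_star[is.finite(r_star)]
  if (length(unique(r_star)) < 2) {
    stop("degenerate bootstrap distribution: all replicates equal",
         call. = FALSE)
  }
  prop_below <- mean(r_star < r_hat)
  if (prop_below <= 0 || prop_below >= 1) {
    stop("degenerate bootstrap distribution: the observed correlation lies ",
         "outside the bootstrap range", call. = FALSE)
  }
  z0 <- stats::qnorm(prop_below)
  a <- 0
  if (accelerated) {
    r_jack <- vapply(seq_len(n), function(i) {
      stats::cor(x[-i], y[-i])
    }, numeric(1))
    u <- mean(r_jack) - r_jack
    denom <- 6 * sum(u^2)^1.5
    a <- if (denom > 0) sum(u^3) / denom else 0
  }
  z_alpha <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha))
  probs <- stats::pnorm(adj)
  ci <- norm_inter_quantile(r_star, probs)
  tibble::tibble(r = r_hat, ci_low = ci[1], ci_high = ci[2], B = B,
                 z0 = z0, accel = a,
                 significant = ci[1] > 0 | ci[2] < 0)
}

#' Bootstrapped correlations between change in HEI-NVS and other variables
#'
#' For each variable and each interval (t1 − t0 and t3 − t0 by default), the
#' Pearson correlation between the subjects' change in the HEI-NVS total and
#' their change in the variable, with a bias-corrected bootstrap confidence
#' interval, across all imputed datasets. Per cell, the per-imputation
#' estimates are combined on the Fisher-z scale: the pooled point is the
#' mean z, per-imputation BC endpoint offsets are averaged and inflated by
#' the Rubin total-to-within variance ratio (bootstrap interval width as the
#' within-imputation variance), then back-transformed. The same resampling
#' indices are used for every imputation of a cell, so `m` identical
#' datasets reproduce the single-dataset interval exactly.
#'
#' @param data A `hei_imputed` object or a single complete panel.
#' @param variables Variables to correlate with the HEI-NVS total change
#'   (default: the Table-5 set, dietary then anthropometric then
#'   cardiometabolic).
#' @param intervals Endpoints of the change scores.
#' @param B Bootstrap replicates per cell.
#' @param seed Optional integer seed (each cell uses an independent
#'   sub-stream derived from it).
#' @param accelerated Use BCa endpoints.
#' @param level Confidence level.
#' @return Tibble `variable, interval, r, ci_low, ci_high, significant`,
#'   ordered as requested.
#' @export
correlation_table <- function(data, variables = aux_variables(),
                              intervals = c("t1", "t3"), B = 5000,
                              seed = NULL, accelerated = FALSE,
                              level = 0.95) {
  panels <- if (inherits(data, "hei_imputed")) data$datasets else list(data)
  m <- length(panels)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  deltas <- purrr::map(intervals, function(to) {
    purrr::map(panels, change_scores, to = to)
  })
  names(deltas) <- intervals
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  cell <- 0L
  out <- purrr::map_dfr(intervals, function(to) {
    purrr::map_dfr(variables, function(v) {
      cell <<- cell + 1L
      per_imp <- purrr::map_dfr(seq_len(m), function(i) {
        d <- deltas[[to]][[i]]
        bc_bootstrap_ci(d$hei_nvs_total, d[[v]], B = B,
                        seed = (seed + cell) %% .Machine$integer.max,
                        accelerated = accelerated, level = level)
      })
      clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      z <- atanh(clamp(per_imp$r))
      z_lo <- atanh(clamp(per_imp$ci_low))
      z_hi <- atanh(clamp(per_imp$ci_high))
      w_within <- mean(((z_hi - z_lo) / (2 * z_crit))^2)
      b_between <- if (m > 1) stats::var(z) else 0
      t_total <- w_within + (1 + 1 / m) * b_between
      inflate <- if (w_within > 0) sqrt(t_total / w_within) else 1
      z_bar <- mean(z)
      lo <- tanh(z_bar + mean(z_lo - z) * inflate)
      hi <- tanh(z_bar + mean(z_hi - z) * inflate)
      tibble::tibble(variable = v, interval = paste0("t0_", to),
                     r = tanh(z_bar), ci_low = lo, ci_high = hi,
                     significant = lo > 0 | hi < 0)
    })
  })
  dplyr::arrange(out, .data$interval,
                 match(.data$variable, variables))
}
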