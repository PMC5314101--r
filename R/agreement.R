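#' Per-participant error metrics against a reference
#'
#' Error is `device - reference`; percentage error is `100 * error /
#' reference`. Each participant's samples are averaged first, and the cohort
#' summary is the mean and SD of those per-participant means — the
#' aggregation order used when a validation study reports "mean (SD)" error
#' columns across participants.
#'
#' @param paired A data.frame with columns `participant_id`, `device`,
#'   `reference` (one row per paired observation).
#' @param percentage Compute percentage metrics (requires strictly positive
#'   references).
#' @return A list of class `agreement_summary`: `mean_error`, `sd_error`,
#'   `mean_abs_error`, `sd_abs_error`, `mean_pct_error`, `sd_pct_error`,
#'   `mape`, `sd_mape`, `n_participants`, plus the per-participant table in
#'   `$by_participant`.
#' @examples
#' df <- data.frame(participant_id = "a", device = c(90, 220),
#'                  reference = c(100, 200))
#' error_metrics(df)$mape   # 10
#' @export
error_metrics <- function(paired, percentage = TRUE) {
  need <- c("participant_id", "device", "reference")
  if (!all(need %in% names(paired))) {
    stop("`paired` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  paired <- paired[!is.na(paired$device) & !is.na(paired$reference), ]
  if (nrow(paired) == 0L) stop("no complete paired observations", call. = FALSE)
  if (percentage && any(paired$reference <= 0)) {
    stop("percentage metrics require strictly positive reference values", call. = FALSE)
  }
  err <- paired$device - paired$reference
  per <- do.call(rbind, lapply(split(seq_len(nrow(paired)), paired$participant_id),
    function(idx) {
      e <- err[idx]
      r <- paired$reference[idx]
      data.frame(
        participant_id = paired$participant_id[idx[1]],
        me = mean(e), mae = mean(abs(e)),
        mpe = if (percentage) mean(100 * e / r) else NA_real_,
        mape = if (percentage) mean(100 * abs(e) / r) else NA_real_,
        n_obs = length(e), stringsAsFactors = FALSE)
    }))
  rownames(per) <- NULL
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(
    list(mean_error = mean(per$me), sd_error = sd0(per$me),
         mean_abs_error = mean(per$mae), sd_abs_error = sd0(per$mae),
         mean_pct_error = mean(per$mpe), sd_pct_error = sd0(per$mpe),
         mape = mean(per$mape), sd_mape = sd0(per$mape),
         n_participants = nrow(per), by_participant = per),
    class = "agreement_summary"
  )
}

#' @export
print.agreement_summary <- function(x, digits = 3, ...) {
  cat(sprintf("agreement over %d participants:\n", x$n_participants))
  cat(sprintf("  ME  %8.3g (SD %.3g)    MAE  %8.3g (SD %.3g)\n",
              x$mean_error, x$sd_error, x$mean_abs_error, x$sd_abs_error))
  if (!is.na(x$mean_pct_error)) {
    cat(sprintf("  MPE %7.3g%% (SD %.3g)   MAPE %7.3g%% (SD %.3g)\n",
                x$mean_pct_error, x$sd_pct_error, x$mape, x$sd_mape))
  }
  invisible(x)
}

#' Epoch coverage within absolute and relative limits
#'
#' Percentage of valid epochs whose device-reference difference lies within
#' `abs_limit` (absolute units) and within `rel_limit` of the reference
#' (relative); the boundary counts as within.
#'
#' @param epochs An `epoch_series` from [epoch_means()] (or any data.frame
#'   with `device_mean`, `reference_mean`, `valid`).
#' @param abs_limit Absolute limit in quantity units (default 10, i.e. 10
#'   bpm for heart rate).
#' @param rel_limit Relative limit as a fraction (default 0.10).
#' @return A list of class `coverage_result`: `coverage_abs`, `coverage_rel`
#'   (percent), `abs_limit`, `rel_limit`, `n_epochs`.
#' @export
coverage <- function(epochs, abs_limit = 10, rel_limit = 0.10) {
  ok <- epochs$valid & !is.na(epochs$device_mean) & !is.na(epochs$reference_mean)
  if (!any(ok)) stop("no valid epochs to assess coverage on", call. = FALSE)
  d <- abs(epochs$device_mean[ok] - epochs$reference_mean[ok])
  r <- abs(epochs$reference_mean[ok])
  structure(
    list(coverage_abs = 100 * mean(d <= abs_limit),
         coverage_rel = 100 * mean(d / r <= rel_limit),
         abs_limit = abs_limit, rel_limit = rel_limit, n_epochs = sum(ok)),
    class = "coverage_result"
  )
}

#' @export
print.coverage_result <- function(x, ...) {
  cat(sprintf("coverage over %d epochs: %.1f%% within %g (abs), %.1f%% within %.0f%% (rel)\n",
              x$n_epochs, x$coverage_abs, x$abs_limit, x$coverage_rel,
              100 * x$rel_limit))
  invisible(x)
}

#' Paired log-ratio TOST equivalence test
#'
#' Tests whether the geometric-mean ratio of paired positive measurements
#' `x` (device) and `y` (reference) lies inside a ratio margin: the paired
#' differences `d = log(x) - log(y)` are submitted to two one-sided paired t
#' tests against `log(margin_low_ratio)` and `log(margin_high_ratio)`, and
#' equivalence is declared when both one-sided p-values fall below `alpha`.
#' Both the conventional two-sided 95% CI and the TOST-dual `1 - 2*alpha`
#' interval of the ratio are returned.
#'
#' @param x,y Paired strictly positive values (one per participant).
#' @param margin_low_ratio,margin_high_ratio Ratio margins with
#'   `margin_low_ratio < 1 < margin_high_ratio`, e.g. 0.85 and 1.15 for a
#'   +/-15% margin.
#' @param alpha One-sided significance level (default .05).
#' @return A list of class `equivalence_result` with elements `n`,
#'   `mean_log_diff`, `sd_log_diff`, `geo_mean_ratio`, `ci_low_ratio`,
#'   `ci_high_ratio` (two-sided 95%), `ci_tost_low_ratio`,
#'   `ci_tost_high_ratio` (the `1 - 2*alpha` interval), `margin_low_ratio`,
#'   `margin_high_ratio`, `p_lower`, `p_upper`, `equivalent`, `degenerate`.
#' @examples
#' y <- c(100, 110, 120, 130)
#' x <- y * exp(c(0, 0, 0.02, -0.02))
#' tost_log_ratio(x, y, 0.85, 1.15)$equivalent
#' @export
tost_log_ratio <- function(x, y, margin_low_ratio, margin_high_ratio,
                           alpha = 0.05) {
  if (length(x) != length(y)) stop("`x` and `y` must be paired", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0)) {
    stop("log-ratio analysis requires strictly positive values", call. = FALSE)
  }
  if (!(margin_low_ratio < 1 && 1 < margin_high_ratio)) {
    stop("margins must satisfy margin_low_ratio < 1 < margin_high_ratio", call. = FALSE)
  }
  d <- log(x) - log(y)
  m <- mean(d); s <- stats::sd(d); df <- n - 1L
  lm_lo <- log(margin_low_ratio); lm_hi <- log(margin_high_ratio)
  degenerate <- s < .Machine$double.eps^0.5
  if (degenerate) {
    warning("zero variance of log-differences; equivalence decided by direct margin comparison")
    p_lower <- p_upper <- NA_real_
    equivalent <- (m > lm_lo) && (m < lm_hi)
    ci <- c(m, m); ci_tost <- c(m, m)
  } else {
    se <- s / sqrt(n)
    p_lower <- stats::pt((m - lm_lo) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((m - lm_hi) / se, df, lower.tail = TRUE)
    equivalent <- (p_lower < alpha) && (p_upper < alpha)
    ci <- m + c(-1, 1) * stats::qt(0.975, df) * se
    ci_tost <- m + c(-1, 1) * stats::qt(1 - alpha, df) * se
  }
  structure(
    list(n = n, mean_log_diff = m, sd_log_diff = s,
         geo_mean_ratio = exp(m),
         ci_low_ratio = exp(ci[1]), ci_high_ratio = exp(ci[2]),
         ci_tost_low_ratio = exp(ci_tost[1]), ci_tost_high_ratio = exp(ci_tost[2]),
         margin_low_ratio = margin_low_ratio, margin_high_ratio = margin_high_ratio,
         p_lower = p_lower, p_upper = p_upper, alpha = alpha,
         equivalent = equivalent, degenerate = degenerate),
    class = "equivalence_result"
  )
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf("paired log-ratio TOST, n = %d\n", x$n))
  cat(sprintf("  geometric mean ratio %.4f (95%% CI %.4f-%.4f)\n",
              x$geo_mean_ratio, x$ci_low_ratio, x$ci_high_ratio))
  cat(sprintf("  margins [%.3f, %.3f], p_lower = %.4g, p_upper = %.4g -> %s\n",
              x$margin_low_ratio, x$margin_high_ratio, x$p_lower, x$p_upper,
              if (isTRUE(x$equivalent)) "EQUIVALENT" else "not equivalent"))
  invisible(x)
}

#' Bland-Altman bias and limits of agreement
#'
#' @param x,y Paired measurements; differences are `x - y`.
#' @return A list of class `bland_altman_result`: `bias`, `loa_low`,
#'   `loa_high` (bias +/- 1.96 sample SD), `sd_diff`, `n`, and `means` /
#'   `diffs` for plotting.
#' @export
bland_altman <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d); s <- stats::sd(d)
  structure(
    list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         sd_diff = s, n = length(d), means = (x + y) / 2, diffs = d),
    class = "bland_altman_result"
  )
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.4g, 95%% LoA [%.4g, %.4g]\n",
              x$n, x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

# Exact power of the paired TOST at sample size n, for log-differences
# d ~ N(theta, sigma^2): P(reject both one-sided nulls). Integrates the joint
# rejection probability over the chi-square distribution of the sample SD.
tost_power_exact <- function(n, theta, sigma, log_margin_low, log_margin_high,
                             alpha = 0.05) {
  df <- n - 1
  tc <- stats::qt(1 - alpha, df)
  se_mean <- sigma / sqrt(n)
  f <- function(u) {
    s <- sigma * sqrt(u / df)
    lo <- (log_margin_low + tc * s / sqrt(n) - theta) / se_mean
    hi <- (log_margin_high - tc * s / sqrt(n) - theta) / se_mean
    pmax(0, stats::pnorm(hi) - stats::pnorm(lo)) * stats::dchisq(u, df)
  }
  stats::integrate(f, 0, stats::qchisq(1 - 1e-12, df), rel.tol = 1e-9)$value
}

# Monte-Carlo power of the paired TOST (fallback / cross-check)
tost_power_mc <- function(n, theta, sigma, log_margin_low, log_margin_high,
                          alpha = 0.05, n_rep = 10000, seed = 1) {
  with_seed(seed, {
    d <- matrix(stats::rnorm(n * n_rep, theta, sigma), nrow = n)
    m <- colMeans(d)
    se <- sqrt((colMeans(d^2) - m^2) * n / (n - 1)) / sqrt(n)
    tc <- stats::qt(1 - alpha, n - 1)
    mean((m - log_margin_low) / se > tc & (m - log_margin_high) / se < -tc)
  })
}

#' Sample size for a paired equivalence (TOST) test on the ratio scale
#'
#' Smallest number of pairs for which the paired log-ratio TOST achieves the
#' target power, assuming the log-differences are normal with mean
#' `log(assumed_geo_ratio)` and SD `sigma_log`, with ratio margins
#' `(1 - margin, 1 + margin)`. Power is computed exactly by integrating the
#' joint one-sided t rejection region over the sampling distribution of the
#' SD; `method = "mc"` provides a simulation fallback. The recruitment count
#' inflates the requirement for anticipated dropout.
#'
#' @param assumed_geo_ratio Expected geometric-mean ratio device/reference.
#' @param sigma_log SD of the paired log-differences.
#' @param margin Equivalence margin as a fraction (0.15 for +/-15%).
#' @param alpha One-sided significance level (default .05).
#' @param power Target power (default .8).
#' @param dropout Anticipated dropout fraction (default 0.10).
#' @param method `"exact"` or `"mc"`.
#' @param n_max Search cap.
#' @return A list: `n_required`, `n_recruit`, `power_at_n`, plus the inputs.
#' @examples
#' sample_size_equivalence(0.925, 0.173, margin = 0.15)
#' @export
sample_size_equivalence <- function(assumed_geo_ratio, sigma_log, margin,
                                    alpha = 0.05, power = 0.8, dropout = 0.10,
                                    method = c("exact", "mc"), n_max = 10000) {
  method <- match.arg(method)
  stop_if_not_scalar_number(assumed_geo_ratio, "assumed_geo_ratio", positive = TRUE)
  stop_if_not_scalar_number(sigma_log, "sigma_log", positive = TRUE)
  stop_if_not_scalar_number(margin, "margin", positive = TRUE)
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1)) {
    stop("`alpha` and `power` must be in (0, 1)", call. = FALSE)
  }
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)", call. = FALSE)
  theta <- log(assumed_geo_ratio)
  lm_lo <- log(1 - margin); lm_hi <- log(1 + margin)
  if (theta <= lm_lo || theta >= lm_hi) {
    stop(sprintf(paste0("equivalence unattainable: assumed ratio %.4g lies on or ",
                        "outside the margins (%.4g, %.4g)"),
                 assumed_geo_ratio, 1 - margin, 1 + margin), call. = FALSE)
  }
  pw <- function(n) {
    if (method == "exact") tost_power_exact(n, theta, sigma_log, lm_lo, lm_hi, alpha)
    else tost_power_mc(n, theta, sigma_log, lm_lo, lm_hi, alpha, seed = n)
  }
  n <- 3L
  while (n <= n_max && pw(n) < power) n <- n + 1L
  if (n > n_max) stop("no sample size up to `n_max` reaches the target power", call. = FALSE)
  structure(
    list(n_required = n, n_recruit = as.integer(ceiling(n / (1 - dropout))),
         power_at_n = pw(n), assumed_geo_ratio = assumed_geo_ratio,
         sigma_log = sigma_log, margin = margin, alpha = alpha,
         power_target = power, dropout = dropout, method = method),
    class = "sample_size_result"
  )
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(paste0("equivalence sample size: n_required = %d pairs (power %.3f, ",
                     "target %.2f), recruit %d at %.0f%% dropout\n"),
              x$n_required, x$power_at_n, x$power_target, x$n_recruit,
              100 * x$dropout))
  invisible(x)
}
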