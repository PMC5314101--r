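test_that("error metrics follow hand arithmetic and per-participant-first aggregation", {
  same <- data.frame(participant_id = rep("a", 4), device = 1:4, reference = 1:4)
  em0 <- error_metrics(same)
  expect_equal(c(em0$mean_error, em0$mean_abs_error, em0$mean_pct_error, em0$mape),
               c(0, 0, 0, 0))

  one <- data.frame(participant_id = "a", device = c(90, 220), reference = c(100, 200))
  em <- error_metrics(one)
  expect_equal(em$mean_error, 5)
  expect_equal(em$mean_abs_error, 15)
  expect_equal(em$mean_pct_error, 0)
  expect_equal(em$mape, 10)

  two <- data.frame(participant_id = c("a", "b"),
                    device = c(105, 115), reference = c(100, 100))
  expect_equal(error_metrics(two)$mape, 10)   # mean of per-participant MAPEs

  set.seed(77)
  rand <- data.frame(participant_id = rep(letters[1:6], each = 20),
                     device = runif(120, 50, 150), reference = runif(120, 50, 150))
  emr <- error_metrics(rand)
  expect_gte(emr$mean_abs_error, abs(emr$mean_error))
  expect_gte(emr$mape, abs(emr$mean_pct_error))
  expect_true(all(c(emr$sd_error, emr$sd_abs_error, emr$sd_mape) >= 0))

  expect_error(error_metrics(data.frame(participant_id = "a", device = 1,
                                        reference = 0)), "positive")
})

test_that("coverage counts valid epochs inside inclusive limits", {
  ep <- data.frame(device_mean = c(rep(105, 5), rep(115, 5)),
                   reference_mean = rep(100, 10), valid = TRUE)
  cv <- coverage(ep, abs_limit = 10, rel_limit = 0.10)
  expect_equal(cv$coverage_abs, 50)
  expect_equal(cv$coverage_rel, 50)

  at_limit <- data.frame(device_mean = rep(110, 4), reference_mean = rep(100, 4),
                         valid = TRUE)
  cvb <- coverage(at_limit, 10, 0.10)
  expect_equal(cvb$coverage_abs, 100)   # boundary counts as within
  expect_equal(cvb$coverage_rel, 100)

  set.seed(5)
  for (i in 1:30) {
    n <- sample(5:60, 1)
    ep2 <- data.frame(device_mean = runif(n, 60, 140),
                      reference_mean = runif(n, 80, 120),
                      valid = runif(n) > 0.2)
    if (!any(ep2$valid)) next
    cv2 <- coverage(ep2, 10, 0.10)
    want <- oracle_coverage(ep2$device_mean[ep2$valid], ep2$reference_mean[ep2$valid],
                            10, 0.10)
    expect_equal(cv2$coverage_abs, unname(want["abs"]))
    expect_equal(cv2$coverage_rel, unname(want["rel"]))
  }
  expect_error(coverage(data.frame(device_mean = 1, reference_mean = 1,
                                   valid = FALSE)), "valid")
})

test_that("log-ratio TOST matches the t-distribution and declares sanely", {
  y <- c(100, 120, 140, 160)
  x <- y * exp(c(0, 0, 0.02, -0.02))
  res <- tost_log_ratio(x, y, 0.85, 1.15)
  expect_equal(res$geo_mean_ratio, 1)
  expect_lt(res$p_lower, 1e-3)
  expect_lt(res$p_upper, 1e-3)
  expect_true(res$equivalent)

  # mean log-difference exactly at the upper margin: t = 0, p_upper = 1/2
  d <- log(1.15) + c(-0.01, 0, 0.01)
  res_m <- tost_log_ratio(exp(d), rep(1, 3), 0.85, 1.15)
  expect_equal(res_m$p_upper, 0.5)
  expect_false(res_m$equivalent)

  # independent oracle: one-sided paired t tests via t.test
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    dd <- rnorm(n, rnorm(1, 0, 0.05), runif(1, 0.02, 0.3))
    xo <- exp(dd) * 100; yo <- rep(100, n)
    got <- tost_log_ratio(xo, yo, 0.85, 1.15)
    p_lo <- t.test(dd, mu = log(0.85), alternative = "greater")$p.value
    p_hi <- t.test(dd, mu = log(1.15), alternative = "less")$p.value
    expect_equal(got$p_lower, p_lo, tolerance = 1e-12)
    expect_equal(got$p_upper, p_hi, tolerance = 1e-12)
    expect_equal(got$geo_mean_ratio, exp(mean(dd)))
    ci <- t.test(dd, conf.level = 0.95)$conf.int
    expect_equal(c(got$ci_low_ratio, got$ci_high_ratio), exp(as.numeric(ci)),
                 tolerance = 1e-12)
  }

  expect_error(tost_log_ratio(c(1, -1, 2), c(1, 1, 1), 0.85, 1.15), "positive")
  expect_error(tost_log_ratio(1:3, 1:3, 1.05, 1.15), "margins")
})

test_that("TOST decision coincides with the 1-2alpha CI lying inside the margins", {
  set.seed(99)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    dd <- rnorm(n, rnorm(1, 0, 0.1), runif(1, 0.01, 0.25))
    got <- tost_log_ratio(exp(dd), rep(1, n), 0.85, 1.15)
    inside <- got$ci_tost_low_ratio > 0.85 && got$ci_tost_high_ratio < 1.15
    expect_identical(got$equivalent, inside)
  }
})

test_that("swapping device and reference mirrors the TOST", {
  set.seed(123)
  d <- rnorm(12, 0.03, 0.1)
  x <- exp(d) * 50; y <- rep(50, 12)
  fwd <- tost_log_ratio(x, y, 0.85, 1.15)
  bwd <- tost_log_ratio(y, x, 1 / 1.15, 1 / 0.85)
  expect_equal(bwd$geo_mean_ratio, 1 / fwd$geo_mean_ratio)
  expect_equal(bwd$p_lower, fwd$p_upper)
  expect_equal(bwd$p_upper, fwd$p_lower)
  expect_identical(bwd$equivalent, fwd$equivalent)
})

test_that("degenerate zero-variance input is decided by direct margin comparison", {
  x <- rep(102, 5); y <- rep(100, 5)
  expect_warning(res <- tost_log_ratio(x, y, 0.85, 1.15), "zero variance")
  expect_true(res$degenerate)
  expect_true(res$equivalent)
  expect_warning(res2 <- tost_log_ratio(rep(80, 5), rep(100, 5), 0.85, 1.15))
  expect_false(res2$equivalent)
})

test_that("Bland-Altman bias and limits of agreement", {
  expect_equal(unlist(bland_altman(1:5, 1:5)[c("bias", "loa_low", "loa_high")]),
               c(bias = 0, loa_low = 0, loa_high = 0))
  off <- bland_altman(6:10, 1:5)
  expect_equal(c(off$bias, off$loa_low, off$loa_high), c(5, 5, 5))
  tri <- bland_altman(c(0, 1, 2), c(1, 1, 1))
  expect_equal(tri$bias, 0)
  expect_equal(tri$loa_high, 1.96)
  expect_equal(tri$loa_low, -1.96)
  expect_lte(tri$loa_low, tri$bias)
  expect_error(bland_altman(1, 1), "2 complete pairs")
})

test_that("equivalence sample-size solver is validated by simulated power", {
  expect_error(sample_size_equivalence(1.15, 0.1, 0.15), "unattainable")

  ss <- sample_size_equivalence(1.0, 0.10, margin = 0.15)
  expect_lte(ss$n_required, 8)   # near the normal-approximation handful
  mc <- wearagree:::tost_power_mc(ss$n_required, 0, 0.10, log(0.85), log(1.15),
                                  n_rep = 5000, seed = 1)
  se <- sqrt(0.8 * 0.2 / 5000)
  expect_gte(mc, 0.8 - 2 * se)

  # a tight resting-HR-style outcome needs far fewer pairs than a wide
  # energy-expenditure-style outcome; the wider one drives recruitment
  tee <- sample_size_equivalence(0.925, 0.173, margin = 0.15)
  rhr <- sample_size_equivalence(1.032, 0.055, margin = 0.10)
  expect_lt(rhr$n_required, tee$n_required / 2)
  expect_gte(tee$n_recruit, tee$n_required)

  # exact and Monte-Carlo evaluations of the same design agree
  pe <- wearagree:::tost_power_exact(20, log(0.95), 0.15, log(0.85), log(1.15))
  pm <- wearagree:::tost_power_mc(20, log(0.95), 0.15, log(0.85), log(1.15),
                                  n_rep = 20000, seed = 2)
  expect_lt(abs(pe - pm), 3 * sqrt(pe * (1 - pe) / 20000) + 0.005)
})
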