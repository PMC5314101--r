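test_that("cohort generation is seeded, converges to configured means, and validates input", {
  c1 <- generate_cohort(5, seed = 42)
  c2 <- generate_cohort(5, seed = 42)
  expect_identical(c1, c2)
  expect_false(identical(c1, generate_cohort(5, seed = 43)))

  big <- generate_cohort(1000, seed = 1)
  expect_lt(abs(mean(big$resting_hr_true) - 64), 1)
  expect_equal(big$bmi, big$weight / big$height^2)
  expect_true(all(big$resting_hr_true >= 30 & big$resting_hr_true <= 120))
  expect_true(all(unlist(big[-1]) > 0))

  cfg0 <- demographics_config(age_sd = 0, weight_sd = 0, height_sd = 0,
                              rhr_sd = 0, bmr_sd = 0)
  deg <- generate_cohort(50, cfg0, seed = 9)
  expect_true(all(deg$resting_hr_true == 64))
  expect_true(all(deg$weight == 77.2))

  expect_error(generate_cohort(0, seed = 1), "n_participants")
  expect_error(demographics_config(rhr_sd = -1), "SD")
})

test_that("protocol schedule lays out contiguous half-open intervals", {
  sched <- build_protocol_schedule()
  expect_equal(max(sched$end_s), 81 * 60)
  expect_equal(sched$label[1], "rest_tv")
  expect_equal(sched$start_s[-1], sched$end_s[-nrow(sched)])  # contiguous
  expect_equal(sum(!sched$is_rest), 11)
  expect_equal(anyDuplicated(sched$interval_id), 0L)

  one <- data.frame(label = "walkabout", mapped_class = "walk", duration_s = 60,
                    hr_offset = 30, cadence_spm = 100, ee_met_factor = 3)
  s1 <- build_protocol_schedule(one, rest_between_s = 0)
  expect_equal(nrow(s1), 1L)
  expect_equal(c(s1$start_s, s1$end_s), c(0, 60))

  two <- rbind(one, one)
  s2 <- build_protocol_schedule(two, rest_between_s = 180, rest_after_last = FALSE)
  expect_equal(s2$start_s, c(0, 60, 240))
  expect_equal(s2$end_s, c(60, 240, 300))

  bad <- one; bad$duration_s <- 0
  expect_error(build_protocol_schedule(bad), "duration")
})

test_that("identity error models give device == reference sample for sample", {
  cohort <- generate_cohort(2, seed = 3)
  sched <- build_protocol_schedule()
  rec <- generate_session(cohort[1, ], sched, identity_error_model(),
                          identity_error_model(), seed = 11)
  for (q in names(rec$traces$device)) {
    expect_identical(rec$traces$device[[q]]$value, rec$traces$reference[[q]]$value)
  }
  # seeded determinism of the whole record
  rec2 <- generate_session(cohort[1, ], sched, identity_error_model(),
                           identity_error_model(), seed = 11)
  expect_identical(rec, rec2)
  expect_error(generate_session(cohort[1, ], sched), "seed")
})

test_that("multiplicative bias and per-sample noise are faithfully realised", {
  cohort <- generate_cohort(1, seed = 5)
  sched <- build_protocol_schedule()
  biased <- device_error_model(ratio_bias = c(ee_rate = 0.9))
  rec <- generate_session(cohort[1, ], sched, biased, seed = 21)
  tee_ratio <- sum(rec$traces$device$ee_rate$value) /
    sum(rec$traces$reference$ee_rate$value)
  expect_equal(tee_ratio, 0.9, tolerance = 1e-12)

  # 10 000-sample session: realised SD of log(device/reference) matches config
  long <- build_protocol_schedule(
    data.frame(label = "rest_tv", mapped_class = "other", duration_s = 10000,
               hr_offset = 0, cadence_spm = 0, ee_met_factor = 1),
    rest_between_s = 0)
  noisy <- device_error_model(noise_sd_log = c(hr = 0.05))
  recn <- generate_session(cohort[1, ], long, noisy, seed = 8, quantities = "hr")
  d <- log(recn$traces$device$hr$value) - log(recn$traces$reference$hr$value)
  expect_lt(abs(sd(d) - 0.05), 0.002)
})

test_that("cumulative traces never decrease, with and without artifacts", {
  cohort <- generate_cohort(1, seed = 2)
  sched <- build_protocol_schedule()
  arty <- device_error_model(noise_sd_log = c(steps_cum = 0.1, hr = 0.05),
                             artifact_rate = 20, artifact_duration_s = 15)
  rec <- generate_session(cohort[1, ], sched, arty, seed = 31)
  expect_true(all(diff(rec$traces$device$steps_cum$value) >= -1e-9))
  expect_true(all(diff(rec$traces$reference$steps_cum$value) >= -1e-9))
})

test_that("free-living simulation has recoverable resting structure", {
  demog <- generate_cohort(1, seed = 4)[1, ]
  fl <- generate_free_living(demog, days = 1, seed = 6)
  expect_identical(fl, generate_free_living(demog, days = 1, seed = 6))
  ann <- fl$annotations
  expect_true(all(c("sleep", "awake_inactive", "active") %in% ann$label))
  # daily minimum of awake heart rate sits at the true resting rate (+ noise)
  hr <- fl$traces$device$hr
  awake <- ann[ann$label != "sleep", ]
  awake_idx <- unlist(lapply(seq_len(nrow(awake)), function(i) {
    which(hr$t_s >= awake$start_s[i] & hr$t_s < awake$end_s[i])
  }))
  expect_lt(abs(min(hr$value[awake_idx]) - demog$resting_hr_true),
            0.15 * demog$resting_hr_true)

  # a known awake-inactive plateau is recovered by the lowest 5-min median scan
  fl3 <- generate_free_living(demog, days = 3, seed = 7)
  res <- free_living_resting_hr(fl3)
  expect_equal(nrow(res), 3L)
  expect_false(any(res$flagged))
  expect_true(all(abs(res$resting_hr_bpm - demog$resting_hr_true) <
                    0.05 * demog$resting_hr_true))
})
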