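test_that("reference label mapping classifies, masks the cross trainer and rests", {
  sched <- build_protocol_schedule()
  lab <- map_reference_labels(sched)
  expect_equal(nrow(lab), max(sched$end_s))
  ct <- sched[sched$label == "cross_trainer", ]
  expect_true(all(lab$masked[lab$t_s >= ct$start_s & lab$t_s < ct$end_s]))
  # inter-activity rests masked by default, scored as other on request
  r2 <- sched[sched$interval_id == "rest", ]
  expect_true(all(lab$masked[lab$t_s >= r2$start_s & lab$t_s < r2$end_s]))
  lab2 <- map_reference_labels(sched, score_rests = TRUE)
  expect_true(all(lab2$class[lab2$t_s >= r2$start_s & lab2$t_s < r2$end_s] == "other"))
  expect_false(any(lab2$masked[lab2$t_s >= r2$start_s & lab2$t_s < r2$end_s]))
  # the leading 15-min rest is an annotated activity: scored as other
  expect_true(all(lab$class[lab$t_s < 900] == "other"))
  expect_false(any(lab$masked[lab$t_s < 900]))
  # walking family maps to walk, cycling family to cycle, running to run
  for (spec in list(c("treadmill", "walk"), c("treadmill_5pct", "walk"),
                    c("outdoor_walking", "walk"), c("ergometer_bike", "cycle"),
                    c("outdoor_cycling", "cycle"), c("outdoor_running", "run"))) {
    row <- sched[sched$label == spec[1], ]
    expect_true(all(lab$class[lab$t_s >= row$start_s & lab$t_s < row$end_s] == spec[2]),
                info = spec[1])
  }
  cyc <- sched[sched$label == "outdoor_cycling", ]
  expect_equal(sum(lab$class == "cycle" & !lab$masked &
                     lab$t_s >= cyc$start_s & lab$t_s < cyc$end_s), 180L)

  bad <- sched; bad$mapped_class[bad$label == "treadmill_5pct"] <- "juggling"
  expect_error(map_reference_labels(bad), "no class mapping")
  ok <- map_reference_labels(bad, extra_mapping = c(treadmill_5pct = "walk"))
  expect_true(is.data.frame(ok))
})

test_that("confusion matrix counts second-by-second agreement", {
  ref <- rep("walk", 100)
  pred <- c(rep("walk", 94), rep("other", 5), "run")
  cm <- confusion_matrix(pred, ref)
  expect_equal(unname(cm$percentages["walk", ]), c(5, 94, 1, 0))
  expect_equal(unname(cm$support_s["walk"]), 100)
  expect_equal(sum(cm$percentages["walk", ]), 100)

  ident <- confusion_matrix(c("other", "walk", "run", "cycle"),
                            c("other", "walk", "run", "cycle"))
  expect_equal(unname(diag(ident$percentages)), rep(100, 4))

  set.seed(555)
  classes <- c("other", "walk", "run", "cycle")
  for (i in 1:30) {
    n <- sample(50:400, 1)
    ref_i <- sample(classes, n, replace = TRUE)
    pred_i <- sample(classes, n, replace = TRUE)
    mask_i <- runif(n) < 0.2
    if (all(mask_i)) next
    got <- confusion_matrix(pred_i, ref_i, mask_i)
    want <- oracle_confusion_counts(pred_i, ref_i, mask_i)
    expect_equal(got$counts, want)
    sup <- rowSums(want)
    for (k in which(sup > 0)) {
      expect_equal(got$percentages[k, ], 100 * want[k, ] / sup[k])
    }
  }
  expect_error(confusion_matrix("walk", c("walk", "run")), "lengths differ")
  expect_error(confusion_matrix(c("walk", "hop"), c("walk", "run")), "classes")
})

test_that("masking never leaks into other rows and accuracy is permutation-stable", {
  set.seed(808)
  classes <- c("other", "walk", "run", "cycle")
  ref <- sample(classes, 500, replace = TRUE)
  pred <- ifelse(runif(500) < 0.85, ref, sample(classes, 500, replace = TRUE))
  mask <- ref == "cycle" & runif(500) < 0.5
  full <- confusion_matrix(pred, ref, rep(FALSE, 500))
  masked <- confusion_matrix(pred, ref, mask)
  expect_equal(masked$counts[c("other", "walk", "run"), ],
               full$counts[c("other", "walk", "run"), ])

  acc <- overall_accuracy(full)
  perm <- sample(4)
  cm_perm <- full
  cm_perm$percentages <- full$percentages[perm, perm]
  cm_perm$support_s <- full$support_s[perm]
  expect_equal(overall_accuracy(cm_perm), acc)

  uniform <- full
  uniform$percentages <- matrix(25, 4, 4, dimnames = dimnames(full$percentages))
  uniform$support_s <- stats::setNames(rep(100, 4), classes)
  expect_equal(overall_accuracy(uniform), 25)
})

test_that("cohort confusion is the unweighted mean of participant matrices", {
  cm1 <- confusion_matrix(c("walk", "walk"), c("walk", "walk"))
  cm2 <- confusion_matrix(c("walk", "other"), c("walk", "walk"))
  avg <- average_confusion(list(cm1, cm2))
  expect_equal(unname(avg$percentages["walk", "walk"]), 75)   # (100 + 50) / 2
  expect_equal(unname(avg$support_s["walk"]), 4)
})

test_that("step totals read counters over half-open intervals and sum to the combined row", {
  sched <- build_protocol_schedule()
  n <- max(sched$end_s)
  t <- 0:(n - 1)
  set.seed(66)
  inc_ref <- ifelse(runif(n) < 0.3, sample(0:3, n, replace = TRUE), 0)
  inc_dev <- ifelse(runif(n) < 0.3, sample(0:3, n, replace = TRUE), 0)
  dev <- sampled_trace(t, cumsum(inc_dev), "steps_cum", "device")
  ref <- sampled_trace(t, cumsum(inc_ref), "steps_cum", "reference")
  st <- step_totals(dev, ref, sched)
  gait <- c("treadmill", "treadmill_5pct", "outdoor_walking", "outdoor_running")
  expect_equal(st$activity, c(gait, "all_walk_activities"))
  for (g in gait) {
    row <- sched[sched$label == g, ]
    expect_equal(st$device_total[st$activity == g],
                 oracle_interval_steps(t, cumsum(inc_dev), row$start_s, row$end_s))
  }
  comb <- st[st$activity == "all_walk_activities", ]
  expect_equal(comb$device_total, sum(st$device_total[st$activity != "all_walk_activities"]))
  expect_equal(comb$error, sum(st$error[st$activity != "all_walk_activities"]))

  same <- step_totals(dev, dev, sched)
  expect_true(all(same$error == 0))

  down <- sampled_trace(0:2, c(5, 4, 6), "hr")  # decreasing counter via hr type
  down$quantity <- "steps_cum"
  expect_error(step_totals(down, ref, sched), "decreases")
})

test_that("per-activity step errors combine additively", {
  # four activities with known errors -13, 0, -18, +8 -> combined -23
  sched <- build_protocol_schedule()
  gait <- c("treadmill", "treadmill_5pct", "outdoor_walking", "outdoor_running")
  errs <- c(treadmill = -13, treadmill_5pct = 0, outdoor_walking = -18,
            outdoor_running = 8)
  n <- max(sched$end_s)
  inc_ref <- numeric(n); inc_dev <- numeric(n)
  for (g in gait) {
    row <- sched[sched$label == g, ]
    idx <- (row$start_s + 1):row$end_s
    inc_ref[idx] <- 1
    inc_dev[idx] <- 1
    inc_dev[idx[seq_len(abs(errs[[g]]))]] <- 1 + sign(errs[[g]])
  }
  dev <- sampled_trace(0:(n - 1), cumsum(inc_dev), "steps_cum")
  ref <- sampled_trace(0:(n - 1), cumsum(inc_ref), "steps_cum", "reference")
  st <- step_totals(dev, ref, sched)
  expect_equal(st$error[match(gait, st$activity)], unname(errs))
  expect_equal(st$error[st$activity == "all_walk_activities"], -23)
})
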