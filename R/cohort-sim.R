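#' Demographics sampling configuration
#'
#' Means and SDs of the cohort distributions used by [generate_cohort()].
#' Defaults reproduce the validation study's cohort: mean age 41.2 (SD 14.4)
#' years, weight 77.2 (10.2) kg, height 1.80 (0.10) m, resting heart rate 64
#' (7.3) bpm and basal metabolic rate 1654 (216.7) kcal/day. Samples are drawn
#' from normal distributions and clamped to physiologic bounds; BMI is always
#' recomputed from the sampled weight and height.
#'
#' @param age_mean,age_sd Age in years.
#' @param weight_mean,weight_sd Body weight in kg.
#' @param height_mean,height_sd Height in m.
#' @param rhr_mean,rhr_sd True resting heart rate in bpm.
#' @param bmr_mean,bmr_sd Basal metabolic rate in kcal/day.
#' @return A list of class `demographics_config`.
#' @export
demographics_config <- function(age_mean = 41.2, age_sd = 14.4,
                                weight_mean = 77.2, weight_sd = 10.2,
                                height_mean = 1.80, height_sd = 0.10,
                                rhr_mean = 64, rhr_sd = 7.3,
                                bmr_mean = 1654, bmr_sd = 216.7) {
  cfg <- list(age = c(age_mean, age_sd), weight = c(weight_mean, weight_sd),
              height = c(height_mean, height_sd), rhr = c(rhr_mean, rhr_sd),
              bmr = c(bmr_mean, bmr_sd))
  for (nm in names(cfg)) {
    if (cfg[[nm]][1] <= 0) stop(sprintf("mean of `%s` must be > 0", nm), call. = FALSE)
    if (cfg[[nm]][2] < 0) stop(sprintf("SD of `%s` must be >= 0 (got %g)", nm, cfg[[nm]][2]),
                               call. = FALSE)
  }
  structure(cfg, class = "demographics_config")
}

# physiologic clamping bounds for sampled demographics
.demog_bounds <- list(age = c(18, 90), weight = c(40, 140), height = c(1.40, 2.10),
                      rhr = c(30, 120), bmr = c(800, 3500))

#' Generate a synthetic cohort
#'
#' Draws participant demographics from the configured distributions. The draw
#' is fully determined by `seed`; BMI is derived from weight and height.
#'
#' @param n_participants Number of participants (>= 1).
#' @param config A [demographics_config()].
#' @param seed Integer seed; required.
#' @return A data.frame with one row per participant and columns
#'   `participant_id`, `age`, `weight`, `height`, `bmi`, `bmr`,
#'   `resting_hr_true`.
#' @examples
#' cohort <- generate_cohort(5, seed = 1)
#' cohort$bmi - cohort$weight / cohort$height^2   # identically zero
#' @export
generate_cohort <- function(n_participants, config = demographics_config(), seed) {
  stop_if_not_scalar_number(n_participants, "n_participants", positive = TRUE)
  if (n_participants != round(n_participants)) {
    stop("`n_participants` must be a whole number", call. = FALSE)
  }
  if (!inherits(config, "demographics_config")) {
    config <- do.call(demographics_config, as.list(config))
  }
  n <- as.integer(n_participants)
  draw <- function(nm) {
    v <- stats::rnorm(n, config[[nm]][1], config[[nm]][2])
    pmin(pmax(v, .demog_bounds[[nm]][1]), .demog_bounds[[nm]][2])
  }
  with_seed(seed, {
    age <- draw("age"); weight <- draw("weight"); height <- draw("height")
    rhr <- draw("rhr"); bmr <- draw("bmr")
    data.frame(
      participant_id = sprintf("S%03d", seq_len(n)),
      age = age, weight = weight, height = height,
      bmi = weight / height^2, bmr = bmr, resting_hr_true = rhr,
      stringsAsFactors = FALSE
    )
  })
}

#' Laboratory protocol activity profiles
#'
#' One row per scripted activity: the 15-minute seated rest (television
#' watching) followed by eleven 3-minute activities — treadmill walking (flat
#' and 5% incline), ergometer cycling, cross trainer, household chores, desk
#' work, lying, standing, and outdoor walking, cycling and running.
#' `hr_offset` is the steady-state heart-rate elevation above resting HR,
#' `cadence_spm` the stepping cadence (0 for non-gait tasks) and
#' `ee_met_factor` the multiple of basal energy expenditure at steady state.
#' Intensity values are defaults chosen from standard exercise-physiology
#' ranges; every column is overridable.
#'
#' @param include_rest Include the leading 15-minute rest (default TRUE).
#' @return A data.frame with columns `label`, `mapped_class`, `duration_s`,
#'   `hr_offset`, `cadence_spm`, `ee_met_factor`.
#' @export
activity_profiles <- function(include_rest = TRUE) {
  p <- data.frame(
    label = c("rest_tv", "treadmill", "treadmill_5pct", "ergometer_bike",
              "cross_trainer", "household", "desk_work", "lying", "standing",
              "outdoor_walking", "outdoor_cycling", "outdoor_running"),
    mapped_class = c("other", "walk", "walk", "cycle", "excluded", "other",
                     "other", "other", "other", "walk", "cycle", "run"),
    duration_s = c(900, rep(180, 11)),
    hr_offset = c(0, 35, 40, 45, 50, 20, 5, 0, 5, 35, 50, 60),
    cadence_spm = c(0, 105, 95, 0, 0, 0, 0, 0, 0, 110, 0, 160),
    ee_met_factor = c(1.0, 3.5, 4.5, 5.0, 5.5, 2.8, 1.4, 1.0, 1.2, 3.8, 6.0, 8.0),
    stringsAsFactors = FALSE
  )
  if (!include_rest) p <- p[p$label != "rest_tv", ]
  p
}

#' Build the protocol schedule of half-open labelled intervals
#'
#' Lays the activity profiles out contiguously from time 0, inserting a
#' `rest` interval of `rest_between_s` seconds after each activity (the
#' leading rest profile, if present, is not followed by an extra rest). With
#' the default profiles and 180-second rests the schedule spans 81 minutes.
#'
#' @param profiles A data.frame as returned by [activity_profiles()].
#' @param rest_between_s Rest inserted after each activity, seconds (0 for
#'   none).
#' @param rest_after_last Insert a rest after the final activity as well
#'   (default TRUE, matching the laboratory protocol's "rest after each
#'   activity").
#' @return A data.frame of class `protocol_schedule` with columns
#'   `interval_id`, `label`, `mapped_class`, `start_s`, `end_s`, `is_rest`,
#'   `hr_offset`, `cadence_spm`, `ee_met_factor`.
#' @examples
#' sched <- build_protocol_schedule()
#' max(sched$end_s) / 60   # 81 minutes
#' @export
build_protocol_schedule <- function(profiles = activity_profiles(),
                                    rest_between_s = 180,
                                    rest_after_last = TRUE) {
  if (nrow(profiles) == 0L) stop("`profiles` must be non-empty", call. = FALSE)
  if (any(profiles$duration_s <= 0)) {
    stop("activity durations must be > 0", call. = FALSE)
  }
  stop_if_not_scalar_number(rest_between_s, "rest_between_s", nonneg = TRUE)
  rows <- list()
  t <- 0
  is_lead_rest <- grepl("^rest", profiles$label)
  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      label = p$label, mapped_class = p$mapped_class,
      start_s = t, end_s = t + p$duration_s, is_rest = is_lead_rest[i],
      hr_offset = p$hr_offset, cadence_spm = p$cadence_spm,
      ee_met_factor = p$ee_met_factor, stringsAsFactors = FALSE)
    t <- t + p$duration_s
    wants_rest <- !is_lead_rest[i] && rest_between_s > 0 &&
      (i < nrow(profiles) || rest_after_last)
    if (wants_rest) {
      rows[[length(rows) + 1L]] <- data.frame(
        label = "rest", mapped_class = "other", start_s = t,
        end_s = t + rest_between_s, is_rest = TRUE,
        hr_offset = 0, cadence_spm = 0, ee_met_factor = 1,
        stringsAsFactors = FALSE)
      t <- t + rest_between_s
    }
  }
  sched <- do.call(rbind, rows)
  sched <- cbind(interval_id = make.unique(sched$label, sep = "."), sched)
  class(sched) <- c("protocol_schedule", "data.frame")
  sched
}

# first-order relaxation of a state variable toward per-segment set points;
# returns the 1-Hz latent series over the whole schedule
relax_to_targets <- function(schedule, targets, init, tau_s) {
  out <- numeric(max(schedule$end_s))
  state <- init
  for (i in seq_len(nrow(schedule))) {
    len <- schedule$end_s[i] - schedule$start_s[i]
    k <- seq_len(len) - 1
    seg <- targets[i] + (state - targets[i]) * exp(-k / tau_s)
    out[schedule$start_s[i] + seq_len(len)] <- seg
    state <- targets[i] + (state - targets[i]) * exp(-len / tau_s)
  }
  out
}

# draw a label stream: one categorical draw per dwell block from the emission
# row of the true class, giving contiguous misclassified segments with exact
# marginal probabilities
simulate_labels <- function(true_labels, confusion, dwell_s) {
  n <- length(true_labels)
  runs <- rle(true_labels)
  out <- character(n)
  pos <- 0L
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    cls <- runs$values[r]
    # cross-trainer style activities have no emission row of their own: a
    # gait-ambiguous task is emitted from the walk row (masked in scoring)
    row_cls <- if (cls %in% activity_classes) cls else "walk"
    p <- confusion[row_cls, ]
    n_blocks <- ceiling(len / dwell_s)
    draws <- activity_classes[sample.int(4L, n_blocks, replace = TRUE, prob = p)]
    out[pos + seq_len(len)] <- rep(draws, each = dwell_s, length.out = len)
    pos <- pos + len
  }
  out
}

# apply an observation error model to a latent numeric series (1 Hz)
observe_series <- function(latent, quantity, model, cumulative = FALSE) {
  eta <- stats::rnorm(1, 0, model$between_sd_log[[quantity]])
  eps <- if (model$noise_sd_log[[quantity]] > 0) {
    stats::rnorm(length(latent), 0, model$noise_sd_log[[quantity]])
  } else 0
  fac <- model$ratio_bias[[quantity]] * exp(eta + eps)
  obs <- if (cumulative) {
    inc <- diff(c(0, latent))
    cumsum(inc * fac)
  } else {
    latent * fac
  }
  # artifact segments: last valid value carried forward
  n <- length(obs)
  n_art <- stats::rpois(1, model$artifact_rate * n / 3600)
  if (n_art > 0) {
    dur <- as.integer(min(model$artifact_duration_s, n - 1))
    starts <- sample.int(n - dur, n_art, replace = TRUE)
    if (cumulative) {
      # a frozen counter registers no increments during the artifact
      inc2 <- diff(c(0, obs))
      for (s in starts) inc2[s:(s + dur - 1)] <- 0
      obs <- cumsum(inc2)
    } else {
      for (s in starts) obs[s:(s + dur - 1)] <- obs[max(s - 1, 1)]
    }
  }
  obs
}

#' Simulate one laboratory session
#'
#' Generates the latent 1-Hz physiology implied by the participant's
#' demographics and the protocol schedule, then observes it twice — once
#' through the device error model and once through the reference error model.
#' Heart rate relaxes toward `resting_hr_true + hr_offset` of the current
#' activity with a first-order time constant; energy-expenditure rate relaxes
#' toward `bmr/1440 x ee_met_factor` with the same constant (and is therefore
#' affine in the heart-rate excess within each activity); steps accrue at the
#' activity cadence; respiration rate scales mildly with metabolic load above
#' its resting mean.
#'
#' @param demographics One row of a [generate_cohort()] data.frame.
#' @param schedule A [build_protocol_schedule()] schedule.
#' @param device_model,reference_model [device_error_model()] objects.
#' @param seed Integer seed; required.
#' @param quantities Character subset of
#'   `c("hr", "ee_rate", "rr", "steps_cum", "activity")` to simulate.
#' @param hr_tau_s First-order time constant of the heart-rate (and EE)
#'   response, seconds.
#' @param rr_rest Resting respiration rate, breaths/min.
#' @return A `participant_record`: list with `demographics`, `schedule`,
#'   `annotations` (label/start_s/end_s) and `traces$device` /
#'   `traces$reference`, each a named list of [sampled_trace()]s.
#' @export
generate_session <- function(demographics, schedule,
                             device_model = device_error_model(),
                             reference_model = identity_error_model(),
                             seed,
                             quantities = c("hr", "ee_rate", "rr", "steps_cum", "activity"),
                             hr_tau_s = 30, rr_rest = 14) {
  if (missing(seed)) stop("`seed` is required: simulated sessions must be reproducible",
                          call. = FALSE)
  if (!inherits(schedule, "protocol_schedule") || nrow(schedule) == 0L) {
    stop("`schedule` must be a non-empty protocol_schedule", call. = FALSE)
  }
  stopifnot(inherits(device_model, "device_error_model"),
            inherits(reference_model, "device_error_model"))
  quantities <- match.arg(quantities, several.ok = TRUE)
  d <- as.list(demographics)
  total_s <- max(schedule$end_s)
  t <- seq_len(total_s) - 1L

  latent <- list()
  if ("hr" %in% quantities) {
    latent$hr <- relax_to_targets(schedule, d$resting_hr_true + schedule$hr_offset,
                                  d$resting_hr_true, hr_tau_s)
  }
  if ("ee_rate" %in% quantities) {
    basal <- d$bmr / 1440
    latent$ee_rate <- relax_to_targets(schedule, basal * schedule$ee_met_factor,
                                       basal, hr_tau_s)
  }
  if ("rr" %in% quantities) {
    latent$rr <- relax_to_targets(schedule, rr_rest * (1 + 0.35 * (schedule$ee_met_factor - 1)),
                                  rr_rest, hr_tau_s)
  }
  if ("steps_cum" %in% quantities) {
    rate <- numeric(total_s)
    for (i in seq_len(nrow(schedule))) {
      idx <- (schedule$start_s[i] + 1):schedule$end_s[i]
      rate[idx] <- schedule$cadence_spm[i] / 60
    }
    latent$steps_cum <- cumsum(rate)
  }
  true_labels <- NULL
  if ("activity" %in% quantities) {
    true_labels <- character(total_s)
    for (i in seq_len(nrow(schedule))) {
      true_labels[(schedule$start_s[i] + 1):schedule$end_s[i]] <- schedule$mapped_class[i]
    }
  }

  make_side <- function(model, source, sub_seed) {
    with_seed(sub_seed, {
      traces <- list()
      for (q in intersect(c("hr", "ee_rate", "rr"), names(latent))) {
        traces[[q]] <- sampled_trace(t, observe_series(latent[[q]], q, model),
                                     q, source, d$participant_id)
      }
      if (!is.null(latent$steps_cum)) {
        traces$steps_cum <- sampled_trace(
          t, observe_series(latent$steps_cum, "steps_cum", model, cumulative = TRUE),
          "steps_cum", source, d$participant_id)
      }
      if (!is.null(true_labels)) {
        traces$activity <- sampled_trace(
          t, simulate_labels(true_labels, model$label_confusion, model$label_dwell_s),
          "activity", source, d$participant_id)
      }
      traces
    })
  }

  record <- list(
    demographics = as.data.frame(demographics, stringsAsFactors = FALSE),
    schedule = schedule,
    annotations = data.frame(label = schedule$label, start_s = schedule$start_s,
                             end_s = schedule$end_s, stringsAsFactors = FALSE),
    traces = list(device = make_side(device_model, "device", derive_seed(seed, 1L)),
                  reference = make_side(reference_model, "reference", derive_seed(seed, 2L)))
  )
  class(record) <- "participant_record"
  record
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant_record> %s: %d device + %d reference traces, %d annotations\n",
              x$demographics$participant_id, length(x$traces$device),
              length(x$traces$reference), nrow(x$annotations)))
  invisible(x)
}

#' Simulate multi-day free-living wear
#'
#' Produces 1-Hz device heart-rate and energy-expenditure traces with a
#' simple circadian structure — nightly sleep (heart rate below resting),
#' awake-inactive blocks at exactly the participant's true resting heart
#' rate, and day-time activity — plus ground-truth annotations
#' (`sleep` / `awake_inactive` / `active`) for testing resting-heart-rate
#' selection. No reference traces are produced: reference devices are worn
#' only in the laboratory.
#'
#' @param demographics One cohort row.
#' @param days Number of simulated days (>= 1).
#' @param seed Integer seed; required.
#' @param device_model Observation model for the watch (default: 2%
#'   multiplicative HR noise, no bias).
#' @param include_activity Simulate day-time activity blocks (default TRUE);
#'   with FALSE the whole waking day is awake-inactive.
#' @param hr_tau_s Transition time constant, seconds.
#' @return A `participant_record` with `traces$device` and annotations.
#' @export
generate_free_living <- function(demographics, days, seed,
                                 device_model = device_error_model(noise_sd_log = c(hr = 0.02, ee_rate = 0.05)),
                                 include_activity = TRUE,
                                 hr_tau_s = 30) {
  if (missing(seed)) stop("`seed` is required: simulated sessions must be reproducible",
                          call. = FALSE)
  stop_if_not_scalar_number(days, "days", positive = TRUE)
  d <- as.list(demographics)
  # daily block plan in hours: sleep / awake-inactive / active
  day_plan <- data.frame(
    label = c("sleep", "awake_inactive", "active", "awake_inactive", "active",
              "awake_inactive", "sleep"),
    start_h = c(0, 7, 9, 12, 13.5, 20, 23),
    end_h = c(7, 9, 12, 13.5, 20, 23, 24),
    stringsAsFactors = FALSE
  )
  if (!include_activity) day_plan$label[day_plan$label == "active"] <- "awake_inactive"
  ann <- do.call(rbind, lapply(seq_len(as.integer(days)) - 1L, function(dd) {
    data.frame(label = day_plan$label,
               start_s = round((day_plan$start_h + 24 * dd) * 3600),
               end_s = round((day_plan$end_h + 24 * dd) * 3600),
               stringsAsFactors = FALSE)
  }))
  hr_target <- c(sleep = max(d$resting_hr_true - 6, 35),
                 awake_inactive = d$resting_hr_true,
                 active = d$resting_hr_true + 25)
  met_target <- c(sleep = 0.95, awake_inactive = 1.1, active = 3.0)
  sched <- data.frame(start_s = ann$start_s, end_s = ann$end_s)
  hr_latent <- relax_to_targets(sched, unname(hr_target[ann$label]),
                                d$resting_hr_true, hr_tau_s)
  ee_latent <- relax_to_targets(sched, unname(met_target[ann$label]) * d$bmr / 1440,
                                d$bmr / 1440, hr_tau_s)
  t <- seq_len(max(ann$end_s)) - 1L
  traces <- with_seed(seed, list(
    hr = sampled_trace(t, observe_series(hr_latent, "hr", device_model),
                       "hr", "device", d$participant_id),
    ee_rate = sampled_trace(t, observe_series(ee_latent, "ee_rate", device_model),
                            "ee_rate", "device", d$participant_id)
  ))
  record <- list(demographics = as.data.frame(demographics, stringsAsFactors = FALSE),
                 schedule = NULL, annotations = ann,
                 traces = list(device = traces))
  class(record) <- "participant_record"
  record
}
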