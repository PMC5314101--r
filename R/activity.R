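#' Expand a protocol schedule into 1-Hz reference labels with a scoring mask
#'
#' Maps each scheduled second to one of the four scored classes
#' (`other`, `walk`, `run`, `cycle`). Seconds belonging to activities mapped
#' to `excluded` (the gait-ambiguous cross trainer) are masked out of
#' scoring, as are — by default — the inter-activity rest intervals, so that
#' only the annotated laboratory activities are scored.
#'
#' @param schedule A [build_protocol_schedule()] schedule.
#' @param score_rests Score inserted rest intervals as reference `other`
#'   instead of masking them (default FALSE).
#' @param extra_mapping Optional named character vector mapping unknown
#'   activity labels to classes (or `"excluded"`).
#' @return A data.frame with one row per second: `t_s`, `class`, `masked`.
#' @export
map_reference_labels <- function(schedule, score_rests = FALSE,
                                 extra_mapping = NULL) {
  cls <- schedule$mapped_class
  if (!is.null(extra_mapping)) {
    unknown <- is.na(cls) | !(cls %in% c(activity_classes, "excluded"))
    cls[unknown] <- extra_mapping[schedule$label[unknown]]
  }
  bad <- is.na(cls) | !(cls %in% c(activity_classes, "excluded"))
  if (any(bad)) {
    stop("no class mapping for activity label(s): ",
         paste(unique(schedule$label[bad]), collapse = ", "), call. = FALSE)
  }
  total_s <- max(schedule$end_s)
  out_class <- rep(NA_character_, total_s)
  masked <- rep(TRUE, total_s)
  for (i in seq_len(nrow(schedule))) {
    idx <- (schedule$start_s[i] + 1):schedule$end_s[i]
    is_inserted_rest <- isTRUE(schedule$is_rest[i]) && schedule$label[i] != "rest_tv"
    if (cls[i] == "excluded" || (is_inserted_rest && !score_rests)) {
      out_class[idx] <- if (cls[i] == "excluded") NA_character_ else "other"
      masked[idx] <- TRUE
    } else {
      out_class[idx] <- cls[i]
      masked[idx] <- FALSE
    }
  }
  data.frame(t_s = seq_len(total_s) - 1L, class = out_class, masked = masked,
             stringsAsFactors = FALSE)
}

#' Second-by-second activity confusion matrix
#'
#' Counts predicted-versus-reference class agreement over unmasked seconds
#' and normalizes each reference-class row to percentages.
#'
#' @param predicted Character vector of 1-Hz predicted labels (classes
#'   `other`, `walk`, `run`, `cycle`).
#' @param reference Character vector of 1-Hz reference labels, same length.
#' @param mask Logical vector, same length: TRUE seconds are excluded from
#'   scoring (default none).
#' @return A list of class `confusion_matrix_result`: `percentages` (4x4, row
#'   = reference class, in %; `NA` rows for unsupported classes), `counts`,
#'   `support_s` (seconds of reference time per class), `classes`.
#' @examples
#' cm <- confusion_matrix(c("walk", "walk", "other"),
#'                        c("walk", "walk", "walk"))
#' cm$percentages["walk", ]
#' @export
confusion_matrix <- function(predicted, reference, mask = NULL) {
  n <- length(reference)
  if (length(predicted) != n) stop("`predicted` and `reference` lengths differ", call. = FALSE)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("`mask` length differs from the label streams", call. = FALSE)
  keep <- !mask & !is.na(reference) & !is.na(predicted)
  if (!any(keep)) stop("no unmasked seconds to score", call. = FALSE)
  p <- factor(predicted[keep], levels = activity_classes)
  r <- factor(reference[keep], levels = activity_classes)
  if (anyNA(p) || anyNA(r)) {
    stop("labels outside the scored classes (", paste(activity_classes, collapse = ", "),
         ")", call. = FALSE)
  }
  counts <- table(reference = r, predicted = p)
  counts <- matrix(as.integer(counts), 4, 4,
                   dimnames = list(activity_classes, activity_classes))
  support <- rowSums(counts)
  pct <- counts / ifelse(support > 0, support, NA) * 100
  structure(
    list(percentages = pct, counts = counts, support_s = support,
         classes = activity_classes),
    class = "confusion_matrix_result"
  )
}

#' @export
print.confusion_matrix_result <- function(x, digits = 1, ...) {
  cat("activity confusion matrix (row = reference, %):\n")
  print(round(x$percentages, digits))
  cat("support (s):", paste(sprintf("%s=%d", names(x$support_s), x$support_s),
                            collapse = " "), "\n")
  invisible(x)
}

#' Average per-participant confusion matrices into a cohort matrix
#'
#' Unweighted mean of the row-normalized per-participant percentage
#' matrices ("average percentage of correct classifications"); rows a
#' participant has no support for are skipped for that participant.
#'
#' @param cms A list of `confusion_matrix_result`s.
#' @return A `confusion_matrix_result` whose `support_s` is the summed
#'   support and whose `counts` are summed pooled counts.
#' @export
average_confusion <- function(cms) {
  stopifnot(length(cms) >= 1L)
  acc <- matrix(0, 4, 4, dimnames = list(activity_classes, activity_classes))
  nmat <- matrix(0, 4, 4, dimnames = dimnames(acc))
  counts <- matrix(0L, 4, 4, dimnames = dimnames(acc))
  support <- stats::setNames(numeric(4), activity_classes)
  for (cm in cms) {
    ok <- cm$support_s > 0
    acc[ok, ] <- acc[ok, ] + cm$percentages[ok, ]
    nmat[ok, ] <- nmat[ok, ] + 1
    counts <- counts + cm$counts
    support <- support + cm$support_s
  }
  pct <- acc / ifelse(nmat > 0, nmat, NA)
  structure(list(percentages = pct, counts = counts, support_s = support,
                 classes = activity_classes),
            class = "confusion_matrix_result")
}

#' Support-weighted overall classification accuracy
#'
#' @param cm A `confusion_matrix_result`.
#' @return Overall accuracy in percent: the diagonal percentages weighted by
#'   each class's reference support.
#' @export
overall_accuracy <- function(cm) {
  support <- cm$support_s
  if (sum(support) == 0) stop("confusion matrix has zero total support", call. = FALSE)
  ok <- support > 0
  sum(diag(cm$percentages)[ok] * support[ok]) / sum(support[ok])
}

#' Per-activity and combined step-count comparison
#'
#' Steps accrued during each scheduled gait activity are read off the
#' cumulative counters (counter value at the last second before the interval
#' end minus the value just before the interval start); the combined row sums
#' the listed gait activities.
#'
#' @param device_steps,reference_steps Cumulative `steps_cum`
#'   [sampled_trace()]s at 1 Hz.
#' @param schedule A [build_protocol_schedule()] schedule.
#' @param gait_activities Labels of the step-scored activities (default: the
#'   walking and running activities of the standard protocol).
#' @param combined_label Row label for the combined total.
#' @return A data.frame of class `step_comparison`: `activity`,
#'   `device_total`, `reference_total`, `error`, `pct_error`.
#' @export
step_totals <- function(device_steps, reference_steps, schedule,
                        gait_activities = c("treadmill", "treadmill_5pct",
                                            "outdoor_walking", "outdoor_running"),
                        combined_label = "all_walk_activities") {
  for (tr in list(device_steps, reference_steps)) {
    stopifnot(is_sampled_trace(tr))
    if (any(diff(tr$value) < -1e-9)) stop("cumulative step counter decreases", call. = FALSE)
  }
  counter_at <- function(trace, t) {
    # counter value just before time t (0 before the first sample)
    idx <- findInterval(t - 1, trace$t_s)
    ifelse(idx >= 1, trace$value[pmax(idx, 1L)], 0)
  }
  sch <- schedule[schedule$label %in% gait_activities, , drop = FALSE]
  if (nrow(sch) == 0L) stop("none of `gait_activities` appear in the schedule", call. = FALSE)
  rows <- lapply(seq_len(nrow(sch)), function(i) {
    dv <- counter_at(device_steps, sch$end_s[i]) - counter_at(device_steps, sch$start_s[i])
    rf <- counter_at(reference_steps, sch$end_s[i]) - counter_at(reference_steps, sch$start_s[i])
    data.frame(activity = sch$label[i], device_total = dv, reference_total = rf,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(activity = combined_label,
                               device_total = sum(out$device_total),
                               reference_total = sum(out$reference_total)))
  out$error <- out$device_total - out$reference_total
  out$pct_error <- ifelse(out$reference_total > 0,
                          100 * out$error / out$reference_total, NA_real_)
  class(out) <- c("step_comparison", "data.frame")
  out
}
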