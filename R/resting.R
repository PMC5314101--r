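#' Resting heart rate by the lowest sliding-window median
#'
#' Scans every `window_len_s`-second window lying fully inside the trace at
#' `step_s`-second increments, computes each window's median, and returns the
#' minimum — the convention used to derive resting heart rate from a rest
#' recording while remaining robust to transient artifacts. Even-length
#' medians are the mean of the two central order statistics; ties across
#' windows are broken by the earliest window start.
#'
#' @param trace A 1-Hz [sampled_trace()], already restricted to the rest
#'   period of interest.
#' @param window_len_s Window length in seconds (default 300, i.e. 5 min).
#' @param step_s Step between successive window starts, seconds (default 1).
#' @param round_bpm If TRUE, round the result to integer bpm (many monitors
#'   report integers).
#' @return A list of class `resting_hr_result`: `value`, `window_start_s`,
#'   `window_len_s`, `n_windows_scanned`.
#' @examples
#' tr <- sampled_trace(0:599, c(rep(70, 300), rep(55, 300)), "hr")
#' lowest_sliding_median(tr)$value   # 55
#' @export
lowest_sliding_median <- function(trace, window_len_s = 300, step_s = 1,
                                  round_bpm = FALSE) {
  stopifnot(is_sampled_trace(trace))
  stop_if_not_scalar_number(window_len_s, "window_len_s", positive = TRUE)
  n <- length(trace$t_s)
  if (n < window_len_s) {
    stop(sprintf("trace has %d samples but the sliding window requires at least %d",
                 n, as.integer(window_len_s)), call. = FALSE)
  }
  starts_idx <- seq(1L, n - window_len_s + 1L, by = step_s)
  meds <- vapply(starts_idx, function(i) {
    stats::median(trace$value[i:(i + window_len_s - 1L)])
  }, numeric(1))
  best <- which.min(meds)  # which.min returns the earliest minimum
  value <- meds[best]
  if (round_bpm) value <- round(value)
  structure(
    list(value = value, window_start_s = trace$t_s[starts_idx[best]],
         window_len_s = window_len_s, n_windows_scanned = length(starts_idx)),
    class = "resting_hr_result"
  )
}

#' @export
print.resting_hr_result <- function(x, ...) {
  cat(sprintf("resting HR %.2f bpm (lowest %g-s median; window at t=%g s, %d windows scanned)\n",
              x$value, x$window_len_s, x$window_start_s, x$n_windows_scanned))
  invisible(x)
}

#' Mean of a trace over a rest interval
#'
#' Arithmetic mean of the samples falling in the half-open interval
#' `[start_s, end_s)` — used for resting respiration rate, where the device
#' and reference means over the seated rest are compared.
#'
#' @param trace A [sampled_trace()].
#' @param start_s,end_s Interval bounds in seconds.
#' @return The mean value (quantity units).
#' @export
rest_mean <- function(trace, start_s, end_s) {
  w <- trace_window(trace, start_s, end_s)
  mean(w$value, na.rm = TRUE)
}

#' Daily resting heart rate from free-living wear
#'
#' Applies [lowest_sliding_median()] to the annotated awake-inactive segments
#' of each day. Windows never span segment boundaries; a day with no
#' awake-inactive segment at least `window_len_s` long is flagged and
#' returns no value.
#'
#' @param record A `participant_record` from [generate_free_living()] (or
#'   any record with an `hr` device trace and `awake_inactive` annotations).
#' @param window_len_s Window length, seconds (default 300).
#' @return A data.frame with one row per day: `day`, `resting_hr_bpm`,
#'   `window_start_s`, `flagged`.
#' @export
free_living_resting_hr <- function(record, window_len_s = 300) {
  hr <- record$traces$device$hr
  if (is.null(hr)) stop("record has no device heart-rate trace", call. = FALSE)
  ann <- record$annotations
  rest <- ann[ann$label == "awake_inactive", , drop = FALSE]
  days <- sort(unique(floor(ann$start_s / 86400)))
  rows <- lapply(days, function(dd) {
    day_lo <- dd * 86400; day_hi <- day_lo + 86400
    seg <- rest[rest$start_s < day_hi & rest$end_s > day_lo, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(seg))) {
      lo <- max(seg$start_s[i], day_lo); hi <- min(seg$end_s[i], day_hi)
      if (hi - lo < window_len_s) next
      res <- lowest_sliding_median(trace_window(hr, lo, hi), window_len_s)
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best)) {
      data.frame(day = dd, resting_hr_bpm = NA_real_, window_start_s = NA_real_,
                 flagged = TRUE)
    } else {
      data.frame(day = dd, resting_hr_bpm = best$value,
                 window_start_s = best$window_start_s, flagged = FALSE)
    }
  })
  do.call(rbind, rows)
}
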