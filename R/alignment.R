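#' Resample a trace to 1 Hz
#'
#' Puts a trace on consecutive integer seconds spanning its sampled range
#' (no extrapolation beyond the first or last sample). Continuous quantities
#' use linear interpolation, cumulative counters use hold (previous value
#' carried forward), and label streams use nearest-sample assignment; the
#' default picks the appropriate method from the trace's quantity.
#'
#' @param trace A [sampled_trace()].
#' @param method `"linear"`, `"hold"`, `"nearest"`, or `"auto"` (linear for
#'   `hr`/`ee_rate`/`rr`, hold for `steps_cum`, nearest for `activity`).
#' @return A 1-Hz [sampled_trace()].
#' @examples
#' tr <- sampled_trace(c(0, 2), c(60, 62), "hr")
#' resample_to_1hz(tr)$value   # 60 61 62
#' @export
resample_to_1hz <- function(trace, method = c("auto", "linear", "hold", "nearest")) {
  stopifnot(is_sampled_trace(trace))
  method <- match.arg(method)
  if (method == "auto") {
    method <- switch(trace$quantity,
                     hr = , ee_rate = , rr = "linear",
                     steps_cum = "hold",
                     activity = "nearest")
  }
  t_out <- seq(ceiling(min(trace$t_s)), floor(max(trace$t_s)))
  if (length(trace$t_s) == 1L) {
    if (method == "linear") {
      stop("linear resampling needs at least 2 samples", call. = FALSE)
    }
    return(sampled_trace(floor(trace$t_s), trace$value, trace$quantity,
                         trace$source, trace$participant_id))
  }
  v_out <- switch(method,
    linear = {
      if (!is.numeric(trace$value)) {
        stop("linear resampling requires numeric values", call. = FALSE)
      }
      stats::approx(trace$t_s, trace$value, xout = t_out, method = "linear")$y
    },
    hold = {
      idx <- findInterval(t_out, trace$t_s)
      trace$value[pmax(idx, 1L)]
    },
    nearest = {
      # nearest sample in time, earlier sample on ties
      idx <- findInterval(t_out, trace$t_s)
      idx <- pmax(idx, 1L)
      nxt <- pmin(idx + 1L, length(trace$t_s))
      take_next <- (trace$t_s[nxt] - t_out) < (t_out - trace$t_s[idx])
      trace$value[ifelse(take_next, nxt, idx)]
    }
  )
  sampled_trace(t_out, v_out, trace$quantity, trace$source, trace$participant_id)
}

#' Pair device and reference traces into fixed-length epochs
#'
#' Means over non-overlapping `epoch_len_s` windows of the overlap of the two
#' 1-Hz traces, with the epoch grid anchored at the overlap start. A trailing
#' partial window is dropped. An epoch is `valid` only when both sources
#' contribute at least `min_samples` non-missing samples in the window; means
#' are computed over the samples present.
#'
#' @param device,reference 1-Hz [sampled_trace()]s with overlapping ranges.
#' @param epoch_len_s Epoch length in seconds (default 10).
#' @param min_samples Minimum non-missing samples per source for a valid
#'   epoch (default 1).
#' @return A data.frame of class `epoch_series`: `epoch_start_s`,
#'   `device_mean`, `reference_mean`, `valid`, with attribute `epoch_len_s`.
#' @export
epoch_means <- function(device, reference, epoch_len_s = 10, min_samples = 1) {
  stopifnot(is_sampled_trace(device), is_sampled_trace(reference))
  stop_if_not_scalar_number(epoch_len_s, "epoch_len_s", positive = TRUE)
  lo <- max(min(device$t_s), min(reference$t_s))
  hi <- min(max(device$t_s), max(reference$t_s))
  if (hi < lo) stop("device and reference traces do not overlap", call. = FALSE)
  n_overlap <- floor(hi) - ceiling(lo) + 1
  n_epochs <- floor(n_overlap / epoch_len_s)
  if (n_epochs < 1L) stop("overlap shorter than one epoch", call. = FALSE)
  starts <- ceiling(lo) + (seq_len(n_epochs) - 1L) * epoch_len_s

  side_means <- function(trace) {
    keep <- trace$t_s >= ceiling(lo) & trace$t_s < ceiling(lo) + n_epochs * epoch_len_s
    tt <- trace$t_s[keep]; vv <- trace$value[keep]
    ep <- floor((tt - ceiling(lo)) / epoch_len_s) + 1L
    ok <- !is.na(vv)
    m <- rep(NA_real_, n_epochs)
    cnt <- integer(n_epochs)
    agg <- tapply(vv[ok], ep[ok], mean)
    m[as.integer(names(agg))] <- agg
    nn <- tapply(rep(1L, sum(ok)), ep[ok], sum)
    cnt[as.integer(names(nn))] <- nn
    list(mean = m, n = cnt)
  }
  dm <- side_means(device); rm_ <- side_means(reference)
  out <- data.frame(epoch_start_s = starts,
                    device_mean = dm$mean, reference_mean = rm_$mean,
                    valid = dm$n >= min_samples & rm_$n >= min_samples)
  attr(out, "epoch_len_s") <- epoch_len_s
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' Split a trace by the protocol schedule
#'
#' Returns one sub-trace per schedule interval, keyed by the schedule's
#' unique `interval_id`; each sub-trace contains exactly the samples with
#' time in the half-open interval `[start_s, end_s)`, so the segments
#' partition the scheduled portion of the trace.
#'
#' @param trace A [sampled_trace()].
#' @param schedule A [build_protocol_schedule()] schedule (overlapping
#'   intervals are rejected).
#' @return A named list of [sampled_trace()]s; intervals containing no
#'   samples are returned as `NULL` entries.
#' @export
segment_by_schedule <- function(trace, schedule) {
  stopifnot(is_sampled_trace(trace))
  sch <- schedule[order(schedule$start_s), ]
  if (nrow(sch) > 1L && any(sch$start_s[-1] < sch$end_s[-nrow(sch)])) {
    stop("schedule intervals overlap", call. = FALSE)
  }
  out <- vector("list", nrow(sch))
  names(out) <- sch$interval_id
  for (i in seq_len(nrow(sch))) {
    keep <- trace$t_s >= sch$start_s[i] & trace$t_s < sch$end_s[i]
    if (any(keep)) {
      out[[i]] <- sampled_trace(trace$t_s[keep], trace$value[keep],
                                trace$quantity, trace$source, trace$participant_id)
    }
  }
  out
}
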