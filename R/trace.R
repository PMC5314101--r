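#' Sampled trace container
#'
#' A `sampled_trace` holds one measured quantity from one source (the wearable
#' under test or a reference instrument) as a uniformly or non-uniformly
#' sampled time series. Time is integer seconds from session start; intervals
#' throughout the package are half-open `[start, end)`.
#'
#' @param t_s Numeric vector of sample times in seconds, strictly increasing.
#' @param value Vector of sample values (numeric, or character for activity
#'   labels), same length as `t_s`.
#' @param quantity One of `"hr"` (bpm), `"ee_rate"` (kcal/min), `"rr"`
#'   (breaths/min), `"steps_cum"` (cumulative count), `"activity"` (class
#'   label).
#' @param source `"device"` or `"reference"`.
#' @param participant_id Participant identifier string.
#'
#' @return An object of class `sampled_trace`: a list with elements
#'   `participant_id`, `source`, `quantity`, `t_s`, `value`.
#' @examples
#' tr <- sampled_trace(0:9, rep(60, 10), "hr", "device", "P001")
#' print(tr)
#' @export
sampled_trace <- function(t_s, value, quantity, source = "device",
                          participant_id = "P000") {
  quantity <- match.arg(quantity, c("hr", "ee_rate", "rr", "steps_cum", "activity"))
  source <- match.arg(source, c("device", "reference"))
  if (length(t_s) != length(value)) {
    stop("`t_s` and `value` must have the same length", call. = FALSE)
  }
  if (length(t_s) == 0L) stop("trace must contain at least one sample", call. = FALSE)
  if (any(diff(t_s) <= 0)) {
    stop("`t_s` must be strictly increasing", call. = FALSE)
  }
  if (quantity == "steps_cum") {
    v <- value[!is.na(value)]
    if (length(v) > 1L && any(diff(v) < -1e-9)) {
      stop("cumulative trace values must be non-decreasing", call. = FALSE)
    }
  }
  structure(
    list(participant_id = participant_id, source = source, quantity = quantity,
         t_s = as.numeric(t_s), value = value),
    class = "sampled_trace"
  )
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("<sampled_trace> %s / %s / %s: %d samples over [%g, %g] s\n",
              x$participant_id, x$source, x$quantity, length(x$t_s),
              min(x$t_s), max(x$t_s)))
  invisible(x)
}

#' @export
length.sampled_trace <- function(x) length(x$t_s)

is_sampled_trace <- function(x) inherits(x, "sampled_trace")

# TRUE when the trace is already sampled at 1 Hz on consecutive integers
is_1hz <- function(trace) {
  length(trace$t_s) >= 2L &&
    all(trace$t_s == round(trace$t_s)) &&
    all(diff(trace$t_s) == 1)
}

#' Restrict a trace to a half-open time interval
#'
#' @param trace A [sampled_trace()].
#' @param start_s,end_s Interval bounds in seconds; samples with
#'   `start_s <= t < end_s` are kept.
#' @return A `sampled_trace` with the selected samples.
#' @export
trace_window <- function(trace, start_s, end_s) {
  stopifnot(is_sampled_trace(trace))
  keep <- trace$t_s >= start_s & trace$t_s < end_s
  if (!any(keep)) {
    stop(sprintf("no samples in [%g, %g)", start_s, end_s), call. = FALSE)
  }
  sampled_trace(trace$t_s[keep], trace$value[keep], trace$quantity,
                trace$source, trace$participant_id)
}

#' Write traces to the package's CSV dialect
#'
#' Long format with columns `participant_id`, `source`, `quantity`, `t_s`,
#' `value`. Activity labels are written as strings, numeric quantities at full
#' precision.
#'
#' @param traces A list of [sampled_trace()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  if (is_sampled_trace(traces)) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(participant_id = tr$participant_id, source = tr$source,
               quantity = tr$quantity, t_s = tr$t_s,
               value = as.character(tr$value), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read traces from the package's CSV dialect
#'
#' @param path CSV path as written by [write_traces_csv()].
#' @return A list of [sampled_trace()] objects, one per
#'   participant/source/quantity combination present in the file.
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "source", "quantity", "t_s", "value")
  if (!all(need %in% names(df))) {
    stop("trace CSV must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  keys <- interaction(df$participant_id, df$source, df$quantity, drop = TRUE)
  lapply(split(df, keys), function(d) {
    d <- d[order(d$t_s), ]
    val <- if (d$quantity[1] == "activity") d$value else as.numeric(d$value)
    sampled_trace(d$t_s, val, d$quantity[1], d$source[1], d$participant_id[1])
  })
}
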