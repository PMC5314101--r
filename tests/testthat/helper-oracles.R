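# Brute-force oracles, kept deliberately naive and independent of the
# package's implementation paths.

oracle_lowest_median <- function(values, w) {
  best <- Inf; best_start <- NA_integer_
  for (i in seq_len(length(values) - w + 1L)) {
    m <- stats::median(values[i:(i + w - 1L)])
    if (m < best) { best <- m; best_start <- i }
  }
  list(value = best, start_idx = best_start)
}

oracle_coverage <- function(dev, ref, abs_limit, rel_limit) {
  n_abs <- 0L; n_rel <- 0L
  for (i in seq_along(dev)) {
    if (abs(dev[i] - ref[i]) <= abs_limit) n_abs <- n_abs + 1L
    if (abs(dev[i] - ref[i]) / ref[i] <= rel_limit) n_rel <- n_rel + 1L
  }
  c(abs = 100 * n_abs / length(dev), rel = 100 * n_rel / length(dev))
}

oracle_confusion_counts <- function(pred, ref, mask) {
  classes <- c("other", "walk", "run", "cycle")
  m <- matrix(0L, 4, 4, dimnames = list(classes, classes))
  for (i in seq_along(ref)) {
    if (!mask[i]) m[ref[i], pred[i]] <- m[ref[i], pred[i]] + 1L
  }
  m
}

oracle_interval_steps <- function(t_s, counter, start_s, end_s) {
  at <- function(tt) {
    idx <- which(t_s <= tt - 1)
    if (length(idx) == 0L) 0 else counter[max(idx)]
  }
  at(end_s) - at(start_s)
}

# small helper: constant-rate 1-Hz trace
const_trace <- function(n, value, quantity = "hr", source = "device") {
  sampled_trace(0:(n - 1), rep(value, n), quantity, source)
}
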