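#' Activity classes scored by the recognition analysis
#'
#' Fixed class order used everywhere a confusion matrix appears.
#' @export
activity_classes <- c("other", "walk", "run", "cycle")

#' Published-accuracy activity confusion matrix
#'
#' Row-stochastic 4x4 matrix (rows = true class, columns = predicted class,
#' proportions) matching the classification accuracy reported for the wrist
#' monitor: roughly 99% correct for sedentary/other activity, 94% for
#' walking, 90% for running and 92% for cycling, with running most often
#' confused with walking. Used as the simulator's default misclassification
#' model.
#'
#' @return A 4x4 numeric matrix with rows and columns named by
#'   [activity_classes], each row summing to 1.
#' @export
published_confusion_matrix <- function() {
  m <- matrix(c(
    0.993, 0.005, 0.000, 0.002,
    0.055, 0.942, 0.001, 0.003,  # note: row printed to 0.1% sums to 0.999
    0.036, 0.062, 0.899, 0.002,
    0.081, 0.004, 0.000, 0.916
  ), nrow = 4, byrow = TRUE, dimnames = list(activity_classes, activity_classes))
  # renormalise the rounding residue so rows are exactly stochastic
  sweep(m, 1, rowSums(m), "/")
}

identity_confusion_matrix <- function() {
  m <- diag(4)
  dimnames(m) <- list(activity_classes, activity_classes)
  m
}

quantity_names <- c("hr", "ee_rate", "rr", "steps_cum")

# expand a scalar or partially named per-quantity vector, filling `default`
expand_per_quantity <- function(x, name, default) {
  out <- stats::setNames(rep(default, length(quantity_names)), quantity_names)
  if (length(x) == 1L && is.null(names(x))) {
    out[] <- x
    return(out)
  }
  if (is.null(names(x)) || !all(names(x) %in% quantity_names)) {
    stop(sprintf("`%s` must be a scalar or a vector named by quantities (%s)",
                 name, paste(quantity_names, collapse = ", ")), call. = FALSE)
  }
  out[names(x)] <- x
  out
}

#' Observation error model for a measuring device
#'
#' Describes how a device's observed traces deviate from the latent true
#' signal: a multiplicative calibration bias per quantity, a session-level
#' multiplicative error (between-participant spread of the device/truth ratio,
#' on the log scale: wear position, skin optics and fit differ between people,
#' not between seconds), per-sample multiplicative noise, occasional fixed
#' -duration artifacts, and label misclassification for the activity channel.
#'
#' @param ratio_bias Multiplicative bias per quantity; scalar or named vector
#'   over `hr`, `ee_rate`, `rr`, `steps_cum`. 1 means calibrated.
#' @param noise_sd_log SD of per-sample multiplicative noise on the natural
#'   log scale (scalar or named vector).
#' @param between_sd_log SD of the session-level multiplicative error on the
#'   log scale (scalar or named vector). This is the component that sets the
#'   between-participant spread of session-aggregate ratios.
#' @param artifact_rate Expected artifact segments per hour (>= 0).
#' @param artifact_duration_s Artifact segment length in seconds.
#' @param label_confusion 4x4 row-stochastic matrix over
#'   `other, walk, run, cycle`: row r gives the distribution of emitted labels
#'   when the true class is r.
#' @param label_dwell_s Minimum dwell of the simulated label stream in
#'   seconds: labels are drawn once per contiguous `label_dwell_s` block, so
#'   misclassifications form contiguous segments as they would for a real
#'   classifier, while the marginal misclassification probabilities stay
#'   exactly those of `label_confusion`.
#'
#' @return An object of class `device_error_model`.
#' @seealso [identity_error_model()] for a perfectly calibrated, noise-free
#'   model.
#' @examples
#' m <- device_error_model(ratio_bias = c(ee_rate = 0.97),
#'                         between_sd_log = c(ee_rate = 0.13))
#' @export
device_error_model <- function(ratio_bias = 1,
                               noise_sd_log = 0,
                               between_sd_log = 0,
                               artifact_rate = 0,
                               artifact_duration_s = 10,
                               label_confusion = identity_confusion_matrix(),
                               label_dwell_s = 5) {
  ratio_bias <- expand_per_quantity(ratio_bias, "ratio_bias", default = 1)
  noise_sd_log <- expand_per_quantity(noise_sd_log, "noise_sd_log", default = 0)
  between_sd_log <- expand_per_quantity(between_sd_log, "between_sd_log", default = 0)
  if (any(ratio_bias <= 0)) stop("`ratio_bias` must be > 0", call. = FALSE)
  if (any(noise_sd_log < 0) || any(between_sd_log < 0)) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  stop_if_not_scalar_number(artifact_rate, "artifact_rate", nonneg = TRUE)
  stop_if_not_scalar_number(artifact_duration_s, "artifact_duration_s", positive = TRUE)
  stop_if_not_scalar_number(label_dwell_s, "label_dwell_s", positive = TRUE)
  if (!is.matrix(label_confusion) || !all(dim(label_confusion) == c(4, 4))) {
    stop("`label_confusion` must be a 4x4 matrix", call. = FALSE)
  }
  if (any(label_confusion < 0) || any(abs(rowSums(label_confusion) - 1) > 1e-9)) {
    stop("each `label_confusion` row must be a probability distribution (sum 1 within 1e-9)",
         call. = FALSE)
  }
  dimnames(label_confusion) <- list(activity_classes, activity_classes)
  structure(
    list(ratio_bias = ratio_bias, noise_sd_log = noise_sd_log,
         between_sd_log = between_sd_log, artifact_rate = artifact_rate,
         artifact_duration_s = artifact_duration_s,
         label_confusion = label_confusion, label_dwell_s = label_dwell_s),
    class = "device_error_model"
  )
}

#' @export
print.device_error_model <- function(x, ...) {
  cat("<device_error_model>\n")
  cat("  ratio_bias:     ", paste(sprintf("%s=%.3g", names(x$ratio_bias), x$ratio_bias), collapse = " "), "\n")
  cat("  noise_sd_log:   ", paste(sprintf("%s=%.3g", names(x$noise_sd_log), x$noise_sd_log), collapse = " "), "\n")
  cat("  between_sd_log: ", paste(sprintf("%s=%.3g", names(x$between_sd_log), x$between_sd_log), collapse = " "), "\n")
  cat(sprintf("  artifacts: %.3g/h x %gs; label dwell %gs, diag(confusion) = %s\n",
              x$artifact_rate, x$artifact_duration_s, x$label_dwell_s,
              paste(sprintf("%.3f", diag(x$label_confusion)), collapse = ", ")))
  invisible(x)
}

#' Error model of a perfect instrument
#'
#' Bias 1, zero noise, no artifacts, identity label confusion. With this model
#' on both sides, device traces equal reference traces sample for sample and
#' every downstream agreement statistic is exact.
#'
#' @return A [device_error_model()].
#' @export
identity_error_model <- function() device_error_model()
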