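#' Analyses known to the exclusion ledger
#' @export
analysis_names <- c("tee", "rhr", "hr", "rr", "steps", "activity")

#' Construct an exclusion ledger
#'
#' One row per (participant, analysis) exclusion. `scope = "whole"` removes
#' the participant from that analysis entirely; `scope = "partial"` keeps the
#' participant but masks the named activity (e.g. one mis-executed treadmill
#' bout from the step-count analysis).
#'
#' @param participant_id,analysis,reason Character vectors (recycled to a
#'   common length). `analysis` must be one of
#'   `r paste(analysis_names, collapse = ", ")`.
#' @param scope `"whole"` or `"partial"`.
#' @param activity_label Activity affected by a partial exclusion (required
#'   when `scope == "partial"`).
#' @return A data.frame of class `exclusion_ledger`.
#' @export
exclusion_ledger <- function(participant_id = character(), analysis = character(),
                             reason = character(), scope = "whole",
                             activity_label = NA_character_) {
  if (length(participant_id) == 0L) {
    df <- data.frame(participant_id = character(), analysis = character(),
                     excluded = logical(), reason = character(),
                     scope = character(), activity_label = character(),
                     stringsAsFactors = FALSE)
    class(df) <- c("exclusion_ledger", "data.frame")
    return(df)
  }
  df <- data.frame(participant_id = participant_id, analysis = analysis,
                   excluded = TRUE, reason = reason, scope = scope,
                   activity_label = activity_label, stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (!all(df$analysis %in% analysis_names)) {
      stop("unknown analysis name(s): ",
           paste(setdiff(df$analysis, analysis_names), collapse = ", "), call. = FALSE)
    }
    if (!all(df$scope %in% c("whole", "partial"))) {
      stop("`scope` must be 'whole' or 'partial'", call. = FALSE)
    }
    if (any(df$reason == "" | is.na(df$reason))) {
      stop("every exclusion needs a reason", call. = FALSE)
    }
    if (any(df$scope == "partial" & (is.na(df$activity_label) | df$activity_label == ""))) {
      stop("partial exclusions must name the affected activity", call. = FALSE)
    }
  }
  class(df) <- c("exclusion_ledger", "data.frame")
  df
}

#' Participant ids of the emulated validation trial
#'
#' 31 recruited participants of which 2 were excluded before data
#' collection, leaving the 29 who completed the laboratory protocol.
#'
#' @return Character vector of 29 ids.
#' @export
study_cohort_ids <- function() {
  setdiff(sprintf("P%03d", 101:131), c("P122", "P127"))
}

#' The validation study's exclusion ledger
#'
#' Reproduces the per-analysis data exclusions of the laboratory validation
#' trial the package's defaults emulate: two participants affected by an
#' adverse event (all continuous analyses), reference-device malfunctions,
#' one participant with heart rate logged as zero, and one mis-executed
#' treadmill bout encoded as a partial step-count exclusion. Applied to the
#' 29-participant cohort this yields n = 26 for total energy expenditure and
#' n = 23 for resting heart rate and continuous heart rate.
#'
#' @return An [exclusion_ledger()].
#' @export
study_exclusion_ledger <- function() {
  ae <- "possible influence of adverse event"
  refmal <- "reference device malfunction"
  rbind(
    exclusion_ledger(rep(c("P107", "P114"), each = 4),
                     rep(c("tee", "rhr", "hr", "rr"), 2), ae),
    exclusion_ledger("P102", c("tee", "rr"), refmal),
    exclusion_ledger("P104", c("rhr", "hr", "activity"), refmal),
    exclusion_ledger("P104", "steps", "incorrect execution of treadmill walking",
                     scope = "partial", activity_label = "treadmill"),
    exclusion_ledger("P106", c("rhr", "hr"), refmal),
    exclusion_ledger("P128", c("rhr", "hr"), refmal),
    exclusion_ledger("P126", c("rhr", "hr"), "heart rate invalid (logged as 0)")
  )
}

#' Apply an exclusion ledger to a cohort manifest
#'
#' @param manifest Character vector of participant ids, or a data.frame with
#'   a `participant_id` column.
#' @param ledger An [exclusion_ledger()].
#' @param analysis One of `r paste(analysis_names, collapse = ", ")`.
#' @return Character vector of participants available for the analysis
#'   (partial exclusions do not remove a participant; they are propagated by
#'   the pipeline as activity masks).
#' @examples
#' length(apply_exclusions(study_cohort_ids(), study_exclusion_ledger(), "tee"))
#' @export
apply_exclusions <- function(manifest, ledger, analysis) {
  ids <- if (is.data.frame(manifest)) manifest$participant_id else manifest
  analysis <- match.arg(analysis, analysis_names)
  if (nrow(ledger) == 0L) return(ids)
  unknown <- setdiff(ledger$participant_id, ids)
  if (length(unknown)) {
    stop("ledger references participants not in the manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop <- ledger$participant_id[ledger$analysis == analysis &
                                  ledger$excluded & ledger$scope == "whole"]
  setdiff(ids, drop)
}

# activities masked for a given participant/analysis by partial exclusions
partial_exclusions <- function(ledger, analysis) {
  sel <- ledger$analysis == analysis & ledger$excluded & ledger$scope == "partial"
  ledger[sel, c("participant_id", "activity_label"), drop = FALSE]
}
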