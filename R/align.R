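.WINDOWS <- c("W24_48", "W48_72")

#' Align samples to each patient's event time
#'
#' The core of phenotype alignment: instead of comparing samples by calendar
#' day, each sample of an event patient is expressed as hours before that
#' patient's own event. At day resolution this is
#' \code{(event_day - day_post_index) * 24}; when \code{hour_post_index} is
#' recorded, \code{event_day * 24 - hour_post_index} is used instead.
#' Samples are then bucketed into half-open pre-event windows:
#' \code{W24_48 = [24, 48)} h and \code{W48_72 = [48, 72)} h before the
#' event. Samples at or after the event, samples within 24 h of it, and
#' samples more than 72 h before it fall outside both windows
#' (\code{window = "none"}); control-patient samples have no event to align
#' to (\code{hours_pre_event = NA}).
#'
#' @param x a \linkS4class{MetaboCohort}.
#' @return data.frame: \code{sample_id, patient_id, event_patient,
#'   hours_pre_event, window}.
#' @export
alignToEvent <- function(x) {
  sd <- sampleData(x)
  pd <- patientData(x)
  idx <- match(sd$patient_id, rownames(pd))
  ev <- pd$event_status[idx]
  ev_day <- pd$event_day[idx]
  hours <- rep(NA_real_, nrow(sd))
  if ("hour_post_index" %in% colnames(sd) &&
      any(!is.na(sd$hour_post_index))) {
    h <- ifelse(is.na(sd$hour_post_index), sd$day_post_index * 24,
                sd$hour_post_index)
  } else {
    h <- sd$day_post_index * 24
  }
  hours[ev] <- ev_day[ev] * 24 - h[ev]
  win <- rep("none", nrow(sd))
  win[!is.na(hours) & hours >= 24 & hours < 48] <- "W24_48"
  win[!is.na(hours) & hours >= 48 & hours < 72] <- "W48_72"
  data.frame(sample_id = sd$sample_id, patient_id = sd$patient_id,
             event_patient = ev, hours_pre_event = hours, window = win,
             stringsAsFactors = FALSE)
}

#' Build the pre-event window strata
#'
#' One \linkS4class{WindowStratum} per window: its case samples are the
#' event-patient samples aligned into that window, and its control pool is
#' every sample from non-event patients, tagged with collection day for the
#' day-matched selection step. The count of patients contributing to both
#' windows is attached as attribute \code{dual_window_patients}.
#'
#' @param aligned output of \code{\link{alignToEvent}}.
#' @param x the \linkS4class{MetaboCohort}.
#' @return named list of \linkS4class{WindowStratum} (one per window).
#' @export
buildStrata <- function(aligned, x) {
  sd <- sampleData(x)
  pool <- aligned[!aligned$event_patient, c("sample_id", "patient_id")]
  pool$day_post_index <- sd$day_post_index[match(pool$sample_id,
                                                 sd$sample_id)]
  rownames(pool) <- NULL
  strata <- lapply(.WINDOWS, function(w) {
    cs <- aligned$sample_id[aligned$window == w]
    if (!length(cs))
      warning("no case samples fall in window ", w)
    new("WindowStratum", window = w, case_samples = cs,
        control_pool = pool)
  })
  names(strata) <- .WINDOWS
  by_win <- lapply(strata, function(s)
    unique(aligned$patient_id[aligned$sample_id %in% s@case_samples]))
  attr(strata, "dual_window_patients") <-
    length(intersect(by_win[[1]], by_win[[2]]))
  strata
}

#' Fixed-timepoint comparator stratification
#'
#' The conventional design the alignment corrects for: all samples collected
#' on one calendar day, split by the patient's eventual event status and
#' ignoring individual event timing. Samples from event patients on a fixed
#' day can be anywhere from post-event to many days pre-event, which dilutes
#' event-locked signals.
#'
#' @param x a \linkS4class{MetaboCohort}.
#' @param day calendar day post-index-event (0-based).
#' @return list with \code{case} and \code{control} sample id vectors.
#' @export
fixedTimepointStrata <- function(x, day) {
  study_days <- metadata(x)$study_days
  if (day < 0 || day > study_days)
    stop("day must lie within the study window 0-", study_days)
  sd <- sampleData(x)
  pd <- patientData(x)
  ev <- pd$event_status[match(sd$patient_id, rownames(pd))]
  on_day <- sd$day_post_index == day
  if (!any(on_day))
    warning("no samples collected on day ", day)
  list(case = sd$sample_id[on_day & ev],
       control = sd$sample_id[on_day & !ev])
}
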