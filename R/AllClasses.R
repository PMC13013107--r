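#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' MetaboCohort: a longitudinal metabolomics cohort
#'
#' A \linkS4class{SummarizedExperiment} holding the feature intensity matrix
#' (features in rows, plasma samples in columns) together with sample-level
#' metadata in \code{colData} and a patient-level table in a dedicated slot.
#' The intensity assay is either raw peak areas (strictly non-negative) or a
#' log2 view; the state is tracked in \code{metadata(x)$log2} and enforced so
#' the transform cannot be applied twice.
#'
#' \code{colData} columns: \code{patient_id}, \code{day_post_index}
#' (integer days since the index event, 0-based) and optionally
#' \code{hour_post_index} for sub-day resolution. \code{rowData} carries an
#' \code{annotated} flag separating named metabolites from unknown features.
#'
#' The patient table has one row per patient (rownames are patient ids) with
#' demographics (\code{age}, \code{sex}), \code{aneurysm_location},
#' admission severity grades (\code{hunt_hess} 1-5, \code{mfisher} 0-4),
#' \code{event_status} (logical), \code{event_day} (integer, present iff the
#' patient had the event) and optional ordinal outcome scores
#' (\code{gos_discharge}, \code{gos_1w}, \code{gos_1m}, \code{gos_12m} on
#' 1-5; \code{mrs_12m} on 0-6).
#'
#' @slot patientData \code{DataFrame} of patient records.
#' @export
setClass("MetaboCohort",
  contains = "SummarizedExperiment",
  slots = c(patientData = "DataFrame")
)

.ordinal_ok <- function(x, lo, hi) {
  x <- x[!is.na(x)]
  all(x == round(x) & x >= lo & x <= hi)
}

.validMetaboCohort <- function(object) {
  msg <- character()
  pd <- object@patientData
  cd <- colData(object)
  req_p <- c("age", "sex", "aneurysm_location", "hunt_hess", "mfisher",
             "event_status")
  miss <- setdiff(req_p, colnames(pd))
  if (length(miss))
    msg <- c(msg, paste0("patient table missing column(s): ",
                         paste(miss, collapse = ", ")))
  req_s <- c("patient_id", "day_post_index")
  miss <- setdiff(req_s, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("sample table missing column(s): ",
                         paste(miss, collapse = ", ")))
  if (!length(msg)) {
    unknown <- setdiff(cd$patient_id, rownames(pd))
    if (length(unknown))
      msg <- c(msg, paste0("sample(s) reference unknown patient id(s): ",
                           paste(unique(unknown), collapse = ", ")))
    if (anyDuplicated(colnames(object)))
      msg <- c(msg, "duplicate sample ids")
    if (any(cd$day_post_index < 0, na.rm = TRUE))
      msg <- c(msg, "negative day_post_index")
    ev <- pd$event_status
    ed <- if ("event_day" %in% colnames(pd)) pd$event_day else
      rep(NA_integer_, nrow(pd))
    bad <- ev & is.na(ed)
    if (any(bad))
      msg <- c(msg, paste0("event patient(s) without event_day: ",
                           paste(rownames(pd)[bad], collapse = ", ")))
    bad <- !ev & !is.na(ed)
    if (any(bad))
      msg <- c(msg, paste0("non-event patient(s) with event_day: ",
                           paste(rownames(pd)[bad], collapse = ", ")))
    if (any(ed[!is.na(ed)] < 1))
      msg <- c(msg, "event_day must be >= 1")
    if (!.ordinal_ok(pd$hunt_hess, 1, 5))
      msg <- c(msg, "hunt_hess outside 1-5")
    if (!.ordinal_ok(pd$mfisher, 0, 4))
      msg <- c(msg, "mfisher outside 0-4")
    for (g in intersect(c("gos_discharge", "gos_1w", "gos_1m", "gos_12m"),
                        colnames(pd)))
      if (!.ordinal_ok(pd[[g]], 1, 5)) msg <- c(msg, paste0(g, " outside 1-5"))
    if ("mrs_12m" %in% colnames(pd) && !.ordinal_ok(pd$mrs_12m, 0, 6))
      msg <- c(msg, "mrs_12m outside 0-6")
    if (!isTRUE(metadata(object)$log2) &&
        any(assay(object) < 0, na.rm = TRUE))
      msg <- c(msg, "negative intensities in raw state")
  }
  if (length(msg)) msg else TRUE
}

setValidity("MetaboCohort", .validMetaboCohort)

#' Construct a MetaboCohort
#'
#' @param intensity numeric matrix, features x samples; raw peak areas unless
#'   \code{log2 = TRUE}.
#' @param patients data.frame of patient records with a \code{patient_id}
#'   column (or patient ids as rownames).
#' @param samples data.frame of sample records: \code{sample_id},
#'   \code{patient_id}, \code{day_post_index}, optional
#'   \code{hour_post_index}.
#' @param annotated logical vector flagging annotated features (default all
#'   \code{TRUE}).
#' @param log2 logical; is the matrix already a log2 view?
#' @param study_days length of the sampling window in days (default 7);
#'   samples collected later raise an error.
#' @return A \linkS4class{MetaboCohort}.
#' @export
MetaboCohort <- function(intensity, patients, samples, annotated = NULL,
                         log2 = FALSE, study_days = 7L) {
  intensity <- as.matrix(intensity)
  patients <- as.data.frame(patients)
  samples <- as.data.frame(samples)
  if ("patient_id" %in% colnames(patients)) {
    rownames(patients) <- as.character(patients$patient_id)
    patients$patient_id <- NULL
  }
  if (!"sample_id" %in% colnames(samples))
    stop("sample table missing column(s): sample_id")
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id in sample table")
  rn <- as.character(samples$sample_id)
  samples$sample_id <- NULL
  if (is.null(colnames(intensity))) colnames(intensity) <- rn
  samples <- samples[match(colnames(intensity), rn), , drop = FALSE]
  if (anyNA(match(colnames(intensity), rn)))
    stop("intensity columns and sample table disagree on sample ids")
  if (is.null(rownames(intensity)))
    rownames(intensity) <- sprintf("M%04d", seq_len(nrow(intensity)))
  if (any(samples$day_post_index > study_days))
    stop("day_post_index exceeds the study window (", study_days, " days)")
  if (is.null(annotated)) annotated <- rep(TRUE, nrow(intensity))
  se <- SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = DataFrame(samples, row.names = colnames(intensity)),
    rowData = DataFrame(annotated = annotated,
                        row.names = rownames(intensity))
  )
  metadata(se)$log2 <- isTRUE(log2)
  metadata(se)$study_days <- as.integer(study_days)
  obj <- new("MetaboCohort", se, patientData = DataFrame(patients))
  validObject(obj)
  obj
}

#' @describeIn MetaboCohort Patient-level table (one row per patient).
#' @param x,object a \code{MetaboCohort}.
#' @export
setGeneric("patientData", function(x) standardGeneric("patientData"))

#' @export
setMethod("patientData", "MetaboCohort", function(x) x@patientData)

#' @describeIn MetaboCohort Sample-level table as a data.frame, with
#'   \code{sample_id} restored as a column.
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @export
setMethod("sampleData", "MetaboCohort", function(x) {
  df <- as.data.frame(colData(x))
  cbind(sample_id = rownames(df), df, row.names = NULL,
        stringsAsFactors = FALSE)
})

#' @describeIn MetaboCohort The intensity assay (features x samples).
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setMethod("intensities", "MetaboCohort", function(x) assay(x, "intensity"))

#' @describeIn MetaboCohort Is the assay a log2 view?
#' @export
setGeneric("isLog2", function(x) standardGeneric("isLog2"))

#' @export
setMethod("isLog2", "MetaboCohort", function(x) isTRUE(metadata(x)$log2))

setMethod("show", "MetaboCohort", function(object) {
  pd <- object@patientData
  cat("MetaboCohort:", nrow(object), "features x", ncol(object), "samples\n")
  cat("  patients:", nrow(pd), "(", sum(pd$event_status), "with event )\n")
  cat("  assay state:", if (isLog2(object)) "log2" else "raw peak areas", "\n")
  cat("  annotated features:", sum(rowData(object)$annotated), "\n")
})

#' WindowStratum: case samples of one pre-event window plus the control pool
#'
#' @slot window window label, \code{"W24_48"} or \code{"W48_72"}.
#' @slot case_samples ids of case samples falling in the window.
#' @slot control_pool data.frame of candidate control samples
#'   (\code{sample_id}, \code{patient_id}, \code{day_post_index}).
#' @export
setClass("WindowStratum",
  slots = c(window = "character", case_samples = "character",
            control_pool = "data.frame")
)

setMethod("show", "WindowStratum", function(object) {
  cat("WindowStratum", object@window, ":", length(object@case_samples),
      "case samples,", nrow(object@control_pool), "pool controls\n")
})

#' @describeIn WindowStratum case sample ids.
#' @param x a \code{WindowStratum}.
#' @export
setGeneric("caseSamples", function(x) standardGeneric("caseSamples"))

#' @export
setMethod("caseSamples", "WindowStratum", function(x) x@case_samples)

#' @describeIn WindowStratum candidate control samples with their day.
#' @export
setGeneric("controlPool", function(x) standardGeneric("controlPool"))

#' @export
setMethod("controlPool", "WindowStratum", function(x) x@control_pool)
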