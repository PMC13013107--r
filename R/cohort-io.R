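#' Read a cohort from delimited text files
#'
#' Loads the three study tables (patients, samples, feature intensities) and
#' an optional feature-annotation companion, validates them, and assembles a
#' \linkS4class{MetaboCohort}. All files are comma-separated UTF-8 with a
#' header row.
#'
#' Schemas: \code{patients.csv} needs \code{patient_id, age, sex,
#' aneurysm_location, hunt_hess, mfisher, event_status} plus optional
#' \code{event_day} and outcome columns; \code{samples.csv} needs
#' \code{sample_id, patient_id, day_post_index} (optional
#' \code{hour_post_index}); \code{features.csv} holds the intensity matrix,
#' by default one row per sample with the first column \code{sample_id}
#' (use \code{orientation = "features_as_rows"} for the transposed layout,
#' first column \code{feature_id}). \code{feature_annotations.csv}, when
#' given, needs \code{feature_id, annotated} and an optional \code{name}.
#'
#' @param patient_file,sample_file,feature_file paths to the three tables.
#' @param annotation_file optional path to the feature annotation table.
#' @param orientation layout of \code{feature_file}.
#' @param study_days sampling window length in days.
#' @return A validated \linkS4class{MetaboCohort} in raw intensity state.
#' @export
readCohort <- function(patient_file, sample_file, feature_file,
                       annotation_file = NULL,
                       orientation = c("samples_as_rows",
                                       "features_as_rows"),
                       study_days = 7L) {
  orientation <- match.arg(orientation)
  patients <- utils::read.csv(patient_file, stringsAsFactors = FALSE)
  samples <- utils::read.csv(sample_file, stringsAsFactors = FALSE)
  .require_cols(patients, c("patient_id", "age", "sex", "aneurysm_location",
                            "hunt_hess", "mfisher", "event_status"),
                "patient table")
  .require_cols(samples, c("sample_id", "patient_id", "day_post_index"),
                "sample table")
  patients$event_status <- as.logical(patients$event_status)
  mat <- .read_feature_matrix(feature_file, orientation)
  ann <- NULL
  if (!is.null(annotation_file)) {
    at <- utils::read.csv(annotation_file, stringsAsFactors = FALSE)
    .require_cols(at, c("feature_id", "annotated"), "annotation table")
    idx <- match(rownames(mat), at$feature_id)
    if (anyNA(idx))
      stop("annotation table missing feature id(s): ",
           paste(utils::head(rownames(mat)[is.na(idx)]), collapse = ", "))
    ann <- as.logical(at$annotated)[idx]
  }
  MetaboCohort(mat, patients, samples, annotated = ann,
               study_days = study_days)
}

.require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, colnames(df))
  if (length(miss))
    stop(what, " missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

.read_feature_matrix <- function(path, orientation) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate ", colnames(df)[1], " in feature matrix: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (orientation == "samples_as_rows") mat <- t(mat)
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative intensity at feature ", rownames(mat)[neg[1, 1]],
         ", sample ", colnames(mat)[neg[1, 2]])
  mat
}

#' Log2-transform raw peak areas
#'
#' Replaces each intensity by its base-2 logarithm and flips the state flag.
#' Raw peak areas of zero are floored first: by default to half the smallest
#' positive value of the same feature (\code{zero_floor = "half_min"});
#' \code{zero_floor = NA} disables flooring so zeros become an error.
#' Applying the transform to an already-log2 cohort is a state error.
#'
#' @param x a \linkS4class{MetaboCohort} in raw state.
#' @param zero_floor \code{"half_min"}, a positive number used as a global
#'   floor, or \code{NA} to forbid zeros.
#' @return The cohort with a log2 assay and \code{isLog2(x) == TRUE}.
#' @export
setGeneric("log2Transform",
           function(x, zero_floor = "half_min") standardGeneric("log2Transform"))

#' @rdname log2Transform
#' @export
setMethod("log2Transform", "MetaboCohort", function(x, zero_floor = "half_min") {
  if (isLog2(x))
    stop("cohort is already log2-transformed")
  mat <- assay(x, "intensity")
  if (any(mat < 0)) stop("negative intensities cannot be log2-transformed")
  zero <- mat == 0
  if (any(zero)) {
    if (identical(zero_floor, "half_min")) {
      for (i in which(rowSums(zero) > 0)) {
        pos <- mat[i, mat[i, ] > 0]
        if (!length(pos))
          stop("feature ", rownames(mat)[i],
               " is all zero; no floor can be derived")
        mat[i, zero[i, ]] <- min(pos) / 2
      }
    } else if (is.numeric(zero_floor) && zero_floor > 0) {
      mat[zero] <- zero_floor
    } else {
      stop("zero intensity encountered and no floor configured")
    }
  }
  assays(x)$intensity <- log2(mat)
  metadata(x)$log2 <- TRUE
  x
})

#' @importFrom SummarizedExperiment assays assays<-
NULL

#' Write a cohort back to its four CSV files
#'
#' Inverse of \code{\link{readCohort}}: writes \code{patients.csv},
#' \code{samples.csv}, \code{features.csv} (samples as rows) and
#' \code{feature_annotations.csv} under \code{dir}.
#'
#' @param x a \linkS4class{MetaboCohort}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeCohort <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- as.data.frame(patientData(x))
  pd <- cbind(patient_id = rownames(pd), pd, row.names = NULL)
  sd <- sampleData(x)
  mat <- t(intensities(x))
  fm <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                   row.names = NULL)
  ann <- data.frame(feature_id = rownames(x),
                    annotated = rowData(x)$annotated)
  paths <- file.path(dir, c("patients.csv", "samples.csv", "features.csv",
                            "feature_annotations.csv"))
  utils::write.csv(pd, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(sd, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(fm, paths[3], row.names = FALSE, quote = FALSE)
  utils::write.csv(ann, paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Write result tables as CSV
#'
#' Serializes a named list of result data.frames with a stable column order
#' and fixed precision (6 significant digits for doubles), so identical
#' inputs produce byte-identical files.
#'
#' @param tables named list of data.frames.
#' @param dir output directory.
#' @param digits significant digits for numeric columns.
#' @return Invisibly, the written file paths.
#' @export
writeResults <- function(tables, dir, digits = 6) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (j in seq_along(df))
      if (is.double(df[[j]]))
        df[[j]] <- signif(df[[j]], digits)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
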