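#' Pareto-scale a log2 intensity matrix
#'
#' Per feature: subtract the mean and divide by the square root of the
#' sample standard deviation — the usual metabolomics compromise between
#' unit-variance scaling and no scaling before PCA. Zero-variance features
#' are dropped with a warning.
#'
#' @param x a log2-state \linkS4class{MetaboCohort} or a numeric matrix
#'   (features x samples) of log2 intensities.
#' @return scaled matrix (features x samples) with attribute
#'   \code{pareto = TRUE}.
#' @export
paretoScale <- function(x) {
  mat <- if (is(x, "MetaboCohort")) {
    if (!isLog2(x)) stop("paretoScale expects a log2-state cohort")
    intensities(x)
  } else as.matrix(x)
  if (isTRUE(attr(mat, "pareto")))
    stop("matrix is already Pareto-scaled")
  sdv <- apply(mat, 1, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) stop("all features have zero variance")
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped before scaling")
  mat <- mat[keep, , drop = FALSE]
  out <- (mat - rowMeans(mat)) / sqrt(sdv[keep])
  attr(out, "pareto") <- TRUE
  out
}

#' PCA with Hotelling's T-squared outlier exclusion
#'
#' Runs PCA on the Pareto-scaled matrix (samples as observations), computes
#' each sample's Hotelling T-squared over the first \code{n_components}
#' scores, and excludes samples exceeding the critical value
#' \code{A(n-1)/(n-A) * F(1-alpha; A, n-A)}. The exclusion is applied once;
#' there is no iterative re-screening.
#'
#' @param x a log2-state \linkS4class{MetaboCohort} or log2 matrix
#'   (features x samples).
#' @param alpha significance level of the exclusion threshold.
#' @param n_components number of retained components A.
#' @return list of class \code{PcaQcResult}: \code{scores} (samples x
#'   components), \code{explained_variance_fractions}, \code{t2},
#'   \code{t2_critical}, \code{excluded_sample_ids}.
#' @export
pcaHotellingExclude <- function(x, alpha = 0.001, n_components = 5L) {
  if (n_components < 1) stop("n_components must be >= 1")
  scaled <- if (isTRUE(attr(x, "pareto"))) x else paretoScale(x)
  n <- ncol(scaled)
  A <- as.integer(min(n_components, n - 1L, nrow(scaled)))
  if (A < 1) stop("too few samples for PCA")
  pc <- stats::prcomp(t(scaled), center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- pc$x[, seq_len(A), drop = FALSE]
  lambda <- ev[seq_len(A)]
  t2 <- rowSums(sweep(scores^2, 2, lambda, "/"))
  crit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  out <- list(scores = scores,
              explained_variance_fractions = ev / sum(ev),
              t2 = t2, t2_critical = crit,
              excluded_sample_ids = colnames(scaled)[t2 > crit],
              alpha = alpha, n_components = A)
  class(out) <- "PcaQcResult"
  out
}

#' @export
print.PcaQcResult <- function(x, ...) {
  cat("PCA QC:", length(x$t2), "samples,", x$n_components,
      "components (", round(100 * sum(
        x$explained_variance_fractions[seq_len(x$n_components)]), 1),
      "% variance )\n")
  cat("  T2 critical at alpha =", x$alpha, ":", signif(x$t2_critical, 4),
      "; excluded:",
      if (length(x$excluded_sample_ids))
        paste(x$excluded_sample_ids, collapse = ", ") else "none", "\n")
  invisible(x)
}

# ---- vectorized two-group engine -----------------------------------------
# All per-feature statistics are computed in closed form on the rows of the
# two matrices: Student and Welch t from group moments, Mann-Whitney U from
# ranks (exact null via pwilcox when both groups <= 25 and no ties, normal
# approximation with tie and continuity correction otherwise), and Levene's
# test as the two-group ANOVA of absolute deviations from the group center.
.screen_matrix <- function(case, control, levene_center = "median") {
  n1 <- ncol(case); n2 <- ncol(control)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- rowMeans(case); m2 <- rowMeans(control)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v2 <- rowSums((control - m2)^2) / (n2 - 1)
  d <- m1 - m2

  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t_s <- d / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_student <- 2 * stats::pt(-abs(t_s), n1 + n2 - 2)

  se2 <- v1 / n1 + v2 / n2
  t_w <- d / sqrt(se2)
  df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p_welch <- 2 * stats::pt(-abs(t_w), df_w)

  degenerate <- sp2 == 0
  p_student[degenerate] <- NA_real_
  p_welch[degenerate] <- NA_real_

  p_mwu <- vapply(seq_len(nrow(case)), function(i)
    .mwu_p(case[i, ], control[i, ]), numeric(1))

  p_levene <- vapply(seq_len(nrow(case)), function(i)
    .levene_p(case[i, ], control[i, ], levene_center), numeric(1))

  data.frame(feature_id = rownames(case), n_case = n1, n_control = n2,
             mean_case = m1, mean_control = m2, log2_fc = d,
             p_student = p_student, p_welch = p_welch, p_mwu = p_mwu,
             p_levene = p_levene,
             robustness_flagged = !is.na(p_levene) & p_levene < 0.1,
             row.names = NULL, stringsAsFactors = FALSE)
}

.mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sr <- sort(r)
  starts <- which(c(TRUE, diff(sr) != 0))
  ties <- diff(c(starts, length(sr) + 1L))
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 <= 25 && n2 <= 25) {
    if (U > n1 * n2 / 2)
      p <- 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      p <- 2 * stats::pwilcox(U, n1, n2)
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  tie_term <- sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))
  sigma2 <- n1 * n2 / 12 * (n1 + n2 + 1 - tie_term)
  if (sigma2 <= 0) return(NA_real_)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

.levene_p <- function(x, y, center = "median") {
  cf <- if (center == "median") stats::median else mean
  zx <- abs(x - cf(x)); zy <- abs(y - cf(y))
  n1 <- length(zx); n2 <- length(zy)
  v1 <- stats::var(zx); v2 <- stats::var(zy)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  if (is.na(sp2) || sp2 == 0) return(NA_real_)
  t <- (mean(zx) - mean(zy)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), n1 + n2 - 2)
}

#' Two-group differential tests for one feature
#'
#' Student and Welch two-sided t-tests, the Mann-Whitney U test, and
#' Levene's variance test (Brown-Forsythe median centering by default) on
#' log2 intensities, plus group means and the log2 fold change
#' (case minus control). A Levene p below 0.1 raises the robustness flag
#' that motivates reading the variance-robust tests alongside Student's.
#'
#' @param case_values,control_values numeric vectors of log2 intensities
#'   (each of length >= 2).
#' @param levene_center \code{"median"} or \code{"mean"}.
#' @return one-row data.frame with the \code{DifferentialResult} statistic
#'   columns.
#' @export
twoGroupTests <- function(case_values, control_values,
                          levene_center = c("median", "mean")) {
  levene_center <- match.arg(levene_center)
  if (length(case_values) < 2 || length(control_values) < 2)
    stop("each group needs at least 2 values")
  res <- .screen_matrix(matrix(case_values, nrow = 1,
                               dimnames = list("feature", NULL)),
                        matrix(control_values, nrow = 1),
                        levene_center)
  res$feature_id <- NULL
  res
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment. \code{NA} entries are excluded from the
#' correction (they do not count toward the number of tests) and returned
#' as \code{NA}.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values in the original order.
#' @export
bhFDR <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Convert a log2 fold change to a percent depletion
#'
#' A log2 fold change of \code{f} corresponds to a multiplicative intensity
#' ratio \code{2^f}; for a negative \code{f} the depletion of the case group
#' relative to controls is \code{100 * (1 - 2^f)} percent (negative results
#' mean enrichment).
#'
#' @param log2_fc log2 fold change (case minus control).
#' @return percent depletion.
#' @export
depletionPercent <- function(log2_fc) 100 * (1 - 2^log2_fc)

#' Run the per-feature differential screen for a window stratum
#'
#' Compares the stratum's case samples against the union of their matched
#' control samples, feature by feature, with \code{\link{twoGroupTests}};
#' applies BH correction across the scoped feature set (annotated features
#' only, or all features — the two multiple-testing burdens of an annotated
#' vs full-matrix screen); and attaches per-test ascending-p ranks
#' (ties share the minimum rank).
#'
#' @param x a log2-state \linkS4class{MetaboCohort}.
#' @param stratum a \linkS4class{WindowStratum}.
#' @param matches the \code{matches} data.frame from
#'   \code{\link{selectMatchedControls}}.
#' @param feature_scope \code{"annotated_only"} or \code{"all_features"}.
#' @param primary_test which p-value feeds the FDR adjustment.
#' @param exclude_samples sample ids removed before testing (QC outliers).
#' @param levene_center passed to \code{\link{twoGroupTests}}.
#' @return data.frame (one row per feature) with the
#'   \code{DifferentialResult} columns; attributes \code{n_nominal}
#'   (p < 0.05 on the primary test) and \code{n_fdr} (q < 0.05).
#' @export
runDiscovery <- function(x, stratum, matches,
                         feature_scope = c("annotated_only", "all_features"),
                         primary_test = c("student", "welch", "mwu"),
                         exclude_samples = character(),
                         levene_center = "median") {
  feature_scope <- match.arg(feature_scope)
  primary_test <- match.arg(primary_test)
  if (!isLog2(x)) stop("runDiscovery expects a log2-state cohort")
  case_ids <- setdiff(caseSamples(stratum), exclude_samples)
  ctrl_ids <- setdiff(unique(matches$control_sample_id), exclude_samples)
  if (length(intersect(case_ids, ctrl_ids)))
    stop("case and control sample sets overlap")
  feats <- if (feature_scope == "annotated_only")
    rownames(x)[rowData(x)$annotated] else rownames(x)
  mat <- intensities(x)
  res <- .screen_matrix(mat[feats, case_ids, drop = FALSE],
                        mat[feats, ctrl_ids, drop = FALSE], levene_center)
  p_primary <- res[[paste0("p_", primary_test)]]
  res$q <- bhFDR(p_primary)
  for (tst in c("student", "welch", "mwu")) {
    pv <- res[[paste0("p_", tst)]]
    res[[paste0("rank_", tst)]] <- rank(pv, ties.method = "min",
                                        na.last = "keep")
  }
  res$window <- stratum@window
  attr(res, "n_nominal") <- sum(p_primary < 0.05, na.rm = TRUE)
  attr(res, "n_fdr") <- sum(res$q < 0.05, na.rm = TRUE)
  attr(res, "primary_test") <- primary_test
  res
}

#' Cross-method rank concordance
#'
#' Summarizes, per feature, the best and worst rank across the three tests
#' and whether the feature sits in the top \code{k} of every method — the
#' "top-ranked across all methods" criterion.
#'
#' @param results output of \code{\link{runDiscovery}}.
#' @param k rank threshold for the concordance flag.
#' @return data.frame: \code{feature_id, min_rank, max_rank,
#'   all_tests_top_k}.
#' @export
rankConcordance <- function(results, k = 1L) {
  rk <- as.matrix(results[, c("rank_student", "rank_welch", "rank_mwu")])
  data.frame(feature_id = results$feature_id,
             min_rank = apply(rk, 1, min),
             max_rank = apply(rk, 1, max),
             all_tests_top_k = apply(rk, 1, max) <= k,
             stringsAsFactors = FALSE)
}

#' Build log-ratio features
#'
#' Per-sample log2 ratios (difference of log2 intensities) for pairs such
#' as Arg/Orn, returned as a new log2-state cohort so the ratio set can run
#' through \code{\link{runDiscovery}} with BH applied across the ratios
#' only.
#'
#' @param x a log2-state \linkS4class{MetaboCohort}.
#' @param pairs character vector \code{"NUM/DEN"} or list of
#'   \code{c(num, den)} pairs.
#' @return a \linkS4class{MetaboCohort} whose features are the ratios.
#' @export
makeRatioFeatures <- function(x, pairs) {
  if (!isLog2(x)) stop("makeRatioFeatures expects a log2-state cohort")
  if (is.character(pairs)) pairs <- strsplit(pairs, "/", fixed = TRUE)
  mat <- intensities(x)
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% rownames(mat)))
      stop("unknown feature in ratio pair: ", paste(pr, collapse = "/"))
    mat[pr[1], ] - mat[pr[2], ]
  })
  rmat <- do.call(rbind, rows)
  rownames(rmat) <- vapply(pairs, paste, character(1), collapse = "/")
  pd <- as.data.frame(patientData(x))
  pd$patient_id <- rownames(pd)
  MetaboCohort(rmat, pd, sampleData(x), log2 = TRUE,
               study_days = metadata(x)$study_days)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact test for paired differences: zeros are dropped
#' (Wilcoxon's convention), absolute differences are average-ranked, and
#' the null distribution of the positive-rank sum W is the full set of 2^n
#' equiprobable sign assignments (computed by convolution over the rank
#' values, which enumerates that distribution exactly). The p-value is the
#' null probability of a |W - E[W]| at least as large as observed.
#'
#' @param differences numeric vector of paired differences (n <= 25 after
#'   dropping zeros).
#' @return list: \code{statistic} (W), \code{p}, \code{n} (non-zero pairs).
#' @export
exactWilcoxonPaired <- function(differences) {
  d <- differences[!is.na(differences)]
  nz <- d != 0
  if (!all(nz)) {
    warning(sum(!nz), " zero difference(s) dropped")
    d <- d[nz]
  }
  n <- length(d)
  if (n == 0) return(list(statistic = NA_real_, p = 1, n = 0L))
  if (n > 25) stop("exact enumeration supported for n <= 25")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  # integer-scaled ranks (ties can give half-integer ranks)
  ir <- as.integer(round(2 * r))
  # distribution of 2W over sign flips: polynomial product of (1 + z^r_i)/2
  dist <- c(1, rep(0, sum(ir)))
  for (ri in ir) {
    shifted <- c(rep(0, ri), dist[seq_len(length(dist) - ri)])
    dist <- (dist + shifted) / 2
  }
  support <- seq_along(dist) - 1L      # values of 2W
  EW2 <- sum(ir) / 2                   # E[2W]
  dev <- abs(2 * W - EW2)
  p <- sum(dist[abs(support - EW2) >= dev - 1e-9])
  list(statistic = W, p = min(1, p), n = n)
}

#' Outlier sensitivity re-test
#'
#' Re-runs the two-group tests for one feature after dropping extreme case
#' samples per window — e.g. the lowest case value in one window and the
#' highest in the other — and reports the statistics before and after.
#'
#' @param x a log2-state \linkS4class{MetaboCohort}.
#' @param feature_id the tracked feature.
#' @param strata named list of \linkS4class{WindowStratum}.
#' @param matches_list named list (per window) of match data.frames.
#' @param drop_rules named list mapping window label to \code{"min"},
#'   \code{"max"} or \code{NULL} (no drop).
#' @return data.frame with one row per window and phase
#'   (\code{before}/\code{after}).
#' @export
outlierSensitivityRetest <- function(x, feature_id, strata, matches_list,
                                     drop_rules = list()) {
  mat <- intensities(x)
  out <- list()
  for (w in names(strata)) {
    case_ids <- caseSamples(strata[[w]])
    ctrl_ids <- unique(matches_list[[w]]$control_sample_id)
    cv <- mat[feature_id, case_ids]
    xv <- mat[feature_id, ctrl_ids]
    before <- twoGroupTests(cv, xv)
    before <- cbind(window = w, phase = "before", before,
                    stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- before
    rule <- drop_rules[[w]]
    if (!is.null(rule)) {
      drop <- switch(rule, min = which.min(cv), max = which.max(cv),
                     stop("drop rule must be 'min' or 'max'"))
      cv2 <- cv[-drop]
      if (length(cv2) < 2) {
        warning("window ", w, ": dropping leaves fewer than 2 case samples;",
                " re-test skipped")
        next
      }
      after <- twoGroupTests(cv2, xv)
      out[[length(out) + 1L]] <- cbind(window = w, phase = "after", after,
                                       stringsAsFactors = FALSE)
    } else {
      out[[length(out) + 1L]] <- cbind(window = w, phase = "after", before[
        , setdiff(colnames(before), c("window", "phase"))],
        stringsAsFactors = FALSE)
      out[[length(out)]]$window <- w
      out[[length(out)]]$phase <- "after"
    }
  }
  do.call(rbind, out)
}
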