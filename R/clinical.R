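#' Collapse samples to independent patient-level observations
#'
#' Regression and ROC machinery need one observation per patient. Case
#' patients contribute their in-window sample (when a patient has more than
#' one, the sample closest to 24 h pre-event); control patients contribute
#' the average of their matched control samples, or one of them drawn
#' uniformly at random in \code{"single_random"} mode (the Monte Carlo
#' sensitivity analysis for the averaging choice).
#'
#' @param x a log2-state \linkS4class{MetaboCohort}.
#' @param stratum the \linkS4class{WindowStratum} being evaluated.
#' @param matches match data.frame for the stratum.
#' @param features feature ids to carry as predictors (log2 units).
#' @param clinical_terms patient-table columns to carry (default
#'   \code{"mfisher"}).
#' @param mode \code{"average"} or \code{"single_random"}.
#' @param exclude_samples QC-excluded sample ids.
#' @return data.frame: \code{patient_id, outcome, n_samples_averaged} and
#'   one column per predictor.
#' @export
buildPatientObservations <- function(x, stratum, matches, features,
                                     clinical_terms = "mfisher",
                                     mode = c("average", "single_random"),
                                     exclude_samples = character()) {
  mode <- match.arg(mode)
  if (!isLog2(x)) stop("buildPatientObservations expects a log2 cohort")
  mat <- intensities(x)
  sd <- sampleData(x)
  pd <- as.data.frame(patientData(x))
  aligned <- alignToEvent(x)

  case_ids <- setdiff(caseSamples(stratum), exclude_samples)
  ctrl_ids <- setdiff(unique(matches$control_sample_id), exclude_samples)
  rows <- list()
  add_row <- function(pid, outcome, samp_ids) {
    vals <- mat[features, samp_ids, drop = FALSE]
    pred <- rowMeans(vals)
    row <- data.frame(patient_id = pid, outcome = outcome,
                      n_samples_averaged = length(samp_ids),
                      stringsAsFactors = FALSE)
    for (f in features) row[[f]] <- unname(pred[f])
    for (ct in clinical_terms) row[[ct]] <- pd[pid, ct]
    rows[[length(rows) + 1L]] <<- row
  }
  for (pid in unique(sd$patient_id[match(case_ids, sd$sample_id)])) {
    mine <- case_ids[sd$patient_id[match(case_ids, sd$sample_id)] == pid]
    if (length(mine) > 1) {
      h <- aligned$hours_pre_event[match(mine, aligned$sample_id)]
      mine <- mine[which.min(abs(h - 24))]
    }
    add_row(pid, TRUE, mine)
  }
  for (pid in unique(sd$patient_id[match(ctrl_ids, sd$sample_id)])) {
    mine <- ctrl_ids[sd$patient_id[match(ctrl_ids, sd$sample_id)] == pid]
    if (!length(mine)) next
    if (mode == "single_random" && length(mine) > 1)
      mine <- mine[sample.int(length(mine), 1)]
    add_row(pid, FALSE, mine)
  }
  obs <- do.call(rbind, rows)
  rownames(obs) <- NULL
  obs
}

#' Standardized logistic regression with fit diagnostics
#'
#' Maximum-likelihood logistic fit of the binary outcome on z-scored
#' predictors (standardized on the analysis set), reporting per-term odds
#' ratios per 1 SD with Wald confidence intervals, McFadden's pseudo-R2,
#' AIC, and the in-sample AUC of the fitted probabilities. Suspected
#' separation (non-convergence or extreme coefficients) is flagged rather
#' than silently reported.
#'
#' @param obs output of \code{\link{buildPatientObservations}}.
#' @param terms predictor column names to include.
#' @param model_id label for reporting.
#' @return list of class \code{ModelReport}: \code{model_id}, \code{terms}
#'   (data.frame of coefficients/OR/CI/p), \code{mcfadden}, \code{aic},
#'   \code{auc}, \code{fitted}, \code{converged}.
#' @export
fitLogisticStandardized <- function(obs, terms, model_id = paste(terms,
                                                                 collapse = "+")) {
  y <- as.numeric(obs$outcome)
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least 2 observations per outcome class")
  X <- as.data.frame(scale(obs[, terms, drop = FALSE]))
  dat <- cbind(y = y, X)
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = dat)
  co <- summary(fit)$coefficients
  sep <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15)
  ll <- as.numeric(stats::logLik(fit))
  ll0 <- as.numeric(stats::logLik(
    stats::glm(y ~ 1, family = stats::binomial(), data = dat)))
  term_rows <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  terms_df <- data.frame(
    term = rownames(term_rows),
    coefficient = term_rows[, "Estimate"],
    odds_ratio = exp(term_rows[, "Estimate"]),
    or_ci_low = exp(term_rows[, "Estimate"] -
                      stats::qnorm(0.975) * term_rows[, "Std. Error"]),
    or_ci_high = exp(term_rows[, "Estimate"] +
                       stats::qnorm(0.975) * term_rows[, "Std. Error"]),
    p = term_rows[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  out <- list(model_id = model_id, terms = terms_df,
              mcfadden = 1 - ll / ll0, aic = stats::AIC(fit),
              auc = rocAuc(y, stats::fitted(fit)),
              fitted = stats::fitted(fit), converged = !sep)
  class(out) <- "ModelReport"
  out
}

#' @export
print.ModelReport <- function(x, ...) {
  cat("Logistic model [", x$model_id, "]",
      if (!x$converged) " (possible separation!)", "\n", sep = "")
  print(x$terms, digits = 3)
  cat("  McFadden pseudo-R2:", signif(x$mcfadden, 3),
      " AIC:", signif(x$aic, 4), " AUC:", signif(x$auc, 3), "\n")
  invisible(x)
}

#' Empirical AUC by the rank (Mann-Whitney) formulation
#'
#' @param outcome binary vector (1/TRUE = event).
#' @param score numeric predictor; ties count one half.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(outcome, score) {
  y <- as.logical(outcome)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one outcome class")
  r <- rank(score)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve with stratified bootstrap confidence interval
#'
#' AUC by the rank formulation plus a confidence interval from resampling
#' cases and controls separately (every replicate keeps the class counts).
#' The score should be oriented as a predicted event probability, so a
#' protective predictor still yields AUC above one half after model
#' fitting.
#'
#' @param outcome binary vector.
#' @param score numeric score.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @param ci_type \code{"percentile"} or \code{"basic"}.
#' @return list: \code{auc}, \code{ci} (length 2), \code{roc_points}
#'   (data.frame \code{fpr, tpr}), \code{boot_aucs}.
#' @export
rocAucBootstrap <- function(outcome, score, n_boot = 2000L, seed = 1L,
                            conf = 0.95, ci_type = c("percentile", "basic")) {
  ci_type <- match.arg(ci_type)
  y <- as.logical(outcome)
  auc <- rocAuc(y, score)
  pos <- which(y); neg <- which(!y)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    rocAuc(y[i], score[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(a, 1 - a), names = FALSE)
  ci <- if (ci_type == "percentile") qs else
    pmin(1, pmax(0, c(2 * auc - qs[2], 2 * auc - qs[1])))
  th <- sort(unique(score), decreasing = TRUE)
  roc_points <- data.frame(
    fpr = c(0, vapply(th, function(t) mean(score[!y] >= t), numeric(1))),
    tpr = c(0, vapply(th, function(t) mean(score[y] >= t), numeric(1))))
  list(auc = auc, ci = ci, roc_points = roc_points, boot_aucs = boot)
}

# DeLong structural components: placement values of each positive against
# the negatives and vice versa; psi = 1, 1/2, 0 for win/tie/loss
.delong_placements <- function(y, score) {
  xs <- score[y]; ys <- score[!y]
  m <- length(xs); n <- length(ys)
  v10 <- vapply(xs, function(x) (sum(x > ys) + 0.5 * sum(x == ys)) / n,
                numeric(1))
  v01 <- vapply(ys, function(yv) (sum(xs > yv) + 0.5 * sum(xs == yv)) / m,
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Variance of a single empirical AUC (DeLong)
#'
#' @param outcome binary vector.
#' @param score numeric score.
#' @return list: \code{auc}, \code{var}.
#' @export
delongVariance <- function(outcome, score) {
  y <- as.logical(outcome)
  if (!any(y) || all(y)) stop("AUC undefined: only one outcome class")
  pl <- .delong_placements(y, score)
  list(auc = pl$auc,
       var = stats::var(pl$v10) / length(pl$v10) +
             stats::var(pl$v01) / length(pl$v01))
}

#' DeLong's test for two paired AUCs
#'
#' Compares two scores measured on the same observations via the
#' placement-value (structural components) estimator of the covariance of
#' the two empirical AUCs, with a two-sided normal p-value on the AUC
#' difference.
#'
#' @param outcome binary vector.
#' @param score_a,score_b the two paired scores.
#' @return list of class \code{DeLongResult}: \code{delta_auc} (a minus b),
#'   \code{p}, \code{auc_a}, \code{auc_b}, \code{var_delta}.
#' @export
delongCompare <- function(outcome, score_a, score_b) {
  y <- as.logical(outcome)
  if (!any(y) || all(y)) stop("AUC undefined: only one outcome class")
  pa <- .delong_placements(y, score_a)
  pb <- .delong_placements(y, score_b)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_d <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  p <- if (var_d <= 0) {
    if (abs(delta) < 1e-12) 1 else 0
  } else 2 * stats::pnorm(-abs(delta) / sqrt(var_d))
  out <- list(delta_auc = delta, p = p, auc_a = pa$auc, auc_b = pb$auc,
              var_delta = var_d)
  class(out) <- "DeLongResult"
  out
}

#' @export
print.DeLongResult <- function(x, ...) {
  cat("DeLong paired AUC comparison: ", signif(x$auc_a, 3), " vs ",
      signif(x$auc_b, 3), " (dAUC = ", signif(x$delta_auc, 3),
      ", p = ", signif(x$p, 3), ")\n", sep = "")
  invisible(x)
}

#' Spearman correlations of a predictor with ordinal outcomes
#'
#' Rank correlation (average ranks, so ties are handled) between a
#' patient-level predictor and each requested outcome score, on
#' pairwise-complete data, with a two-sided p from the t approximation.
#' Outcomes with fewer than \code{min_n} complete pairs are skipped with a
#' warning.
#'
#' @param obs patient-level data.frame (see
#'   \code{\link{buildPatientObservations}}); outcome columns are looked up
#'   in \code{patients} when absent from \code{obs}.
#' @param predictor predictor column name.
#' @param outcome_fields outcome column names.
#' @param patients optional patient table supplying outcome columns.
#' @param min_n minimum complete pairs.
#' @return data.frame: \code{outcome, rho, p, n}.
#' @export
spearmanOutcomeCorrelations <- function(obs, predictor, outcome_fields,
                                        patients = NULL, min_n = 5L) {
  out <- list()
  for (f in outcome_fields) {
    yv <- if (f %in% colnames(obs)) obs[[f]] else
      patients[obs$patient_id, f]
    xv <- obs[[predictor]]
    ok <- !is.na(xv) & !is.na(yv)
    n <- sum(ok)
    if (n < min_n) {
      warning("outcome ", f, ": only ", n, " complete pairs; skipped")
      next
    }
    rho <- stats::cor(rank(xv[ok]), rank(yv[ok]))
    p <- if (abs(rho) >= 1) 0 else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(t), n - 2)
    }
    out[[f]] <- data.frame(outcome = f, rho = rho, p = p, n = n,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte Carlo single-sample sensitivity of the averaging choice
#'
#' Repeats the patient-level evaluation with one randomly selected sample
#' per control patient (instead of the within-patient average), refits the
#' predictor-only logistic model, and records the AUC distribution. A mean
#' Monte Carlo AUC close to the averaged-mode AUC indicates the averaging
#' convention is not driving the result.
#'
#' @param x,stratum,matches,feature as in
#'   \code{\link{buildPatientObservations}} (single predictor feature).
#' @param n_iter iterations (default 1000).
#' @param seed base seed; iteration i uses \code{seed + i}.
#' @param exclude_samples QC-excluded sample ids.
#' @return list: \code{mean_auc}, \code{sd_auc}, \code{aucs},
#'   \code{n_nonconverged}.
#' @export
monteCarloSingleSample <- function(x, stratum, matches, feature,
                                   n_iter = 1000L, seed = 1L,
                                   exclude_samples = character()) {
  aucs <- numeric(n_iter)
  bad <- 0L
  for (i in seq_len(n_iter)) {
    set.seed(seed + i)
    obs <- buildPatientObservations(x, stratum, matches, feature,
                                    mode = "single_random",
                                    exclude_samples = exclude_samples)
    fit <- fitLogisticStandardized(obs, feature)
    if (!fit$converged) bad <- bad + 1L
    aucs[i] <- fit$auc
  }
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs), aucs = aucs,
       n_nonconverged = bad)
}
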