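#' Matching configuration
#'
#' @param k controls per case sample.
#' @param day_tolerance maximum |day gap| between case and control sample;
#'   widened to \code{widen_to} for a case whose same-day pool is smaller
#'   than \code{k}.
#' @param widen_to fallback day tolerance on pool exhaustion.
#' @param weights named weights for the covariate distance terms
#'   (\code{age, sex, location, hunt_hess, mfisher}).
#' @param reuse_policy \code{"per_case_unique"} (a control sample may serve
#'   several cases, but appears once per case) or \code{"globally_unique"}
#'   (each control sample used at most once in a stratum).
#' @return list of class \code{MatchConfig}.
#' @export
matchConfig <- function(k = 2L, day_tolerance = 0L, widen_to = 1L,
                        weights = c(age = 1, sex = 1, location = 1,
                                    hunt_hess = 1, mfisher = 1),
                        reuse_policy = c("per_case_unique",
                                         "globally_unique")) {
  stopifnot(k >= 1, day_tolerance >= 0, widen_to >= day_tolerance)
  cfg <- list(k = as.integer(k), day_tolerance = as.integer(day_tolerance),
              widen_to = as.integer(widen_to), weights = weights,
              reuse_policy = match.arg(reuse_policy))
  class(cfg) <- "MatchConfig"
  cfg
}

#' Gower-style covariate distance between two patients
#'
#' \code{|d_age|/IQR_age + 1[sex differs] + 1[location differs] +
#' |d_HuntHess|/4 + |d_mFisher|/4}, each term multiplied by its weight. The
#' age gap is scaled by the cohort age IQR so all terms live on comparable
#' scales.
#'
#' @param case,control one-row patient records (data.frame-like, with
#'   rownames or a \code{patient_id} column used in error messages).
#' @param weights named term weights.
#' @param age_iqr cohort interquartile range of age.
#' @return non-negative distance.
#' @export
covariateDistance <- function(case, control,
                              weights = c(age = 1, sex = 1, location = 1,
                                          hunt_hess = 1, mfisher = 1),
                              age_iqr) {
  need <- c("age", "sex", "aneurysm_location", "hunt_hess", "mfisher")
  for (rec in list(case, control)) {
    for (f in need) {
      v <- rec[[f]]
      if (is.null(v) || is.na(v))
        stop("patient ", .pid_of(rec), " is missing matching covariate ", f)
    }
  }
  stopifnot(age_iqr > 0)
  unname(
    weights["age"] * abs(case$age - control$age) / age_iqr +
    weights["sex"] * as.numeric(case$sex != control$sex) +
    weights["location"] *
      as.numeric(case$aneurysm_location != control$aneurysm_location) +
    weights["hunt_hess"] * abs(case$hunt_hess - control$hunt_hess) / 4 +
    weights["mfisher"] * abs(case$mfisher - control$mfisher) / 4
  )
}

.pid_of <- function(rec) {
  if (!is.null(rec$patient_id)) as.character(rec$patient_id)
  else if (!is.null(rownames(rec))) rownames(rec)[1]
  else "<unknown>"
}

#' Select matched control samples for every case sample of a stratum
#'
#' For each case sample the pool is restricted to control samples collected
#' within \code{day_tolerance} days of the case sample's own collection day
#' (widened to \code{widen_to} when fewer than \code{k} candidates remain),
#' and the \code{k} controls with the smallest covariate distance are taken.
#' Ties are broken deterministically by (distance, control patient id,
#' control sample id). Under the default reuse policy the same control
#' sample may back several case samples, mirroring how 36 case samples can
#' draw on far fewer distinct control samples.
#'
#' @param stratum a \linkS4class{WindowStratum}.
#' @param x the \linkS4class{MetaboCohort}.
#' @param config a \code{\link{matchConfig}}.
#' @return list with \code{matches} (data.frame \code{case_sample_id,
#'   control_sample_id, distance, day_gap_used}) and \code{balance}
#'   (per-covariate standardized mean differences before/after matching).
#' @export
selectMatchedControls <- function(stratum, x, config = matchConfig()) {
  pd <- as.data.frame(patientData(x))
  sd <- sampleData(x)
  pool <- controlPool(stratum)
  cases <- caseSamples(stratum)
  if (!length(cases)) stop("stratum ", stratum@window, " has no case samples")
  age_iqr <- stats::IQR(pd$age)
  if (age_iqr == 0) age_iqr <- 1
  pool_pat <- pd[pool$patient_id, , drop = FALSE]
  case_day <- sd$day_post_index[match(cases, sd$sample_id)]
  case_pat <- sd$patient_id[match(cases, sd$sample_id)]
  available <- rep(TRUE, nrow(pool))
  rows <- list()
  w <- config$weights
  for (i in seq_along(cases)) {
    crec <- pd[case_pat[i], , drop = FALSE]
    # vectorized form of covariateDistance() over the whole pool
    dist <- w["age"] * abs(crec$age - pool_pat$age) / age_iqr +
      w["sex"] * (crec$sex != pool_pat$sex) +
      w["location"] * (crec$aneurysm_location !=
                         pool_pat$aneurysm_location) +
      w["hunt_hess"] * abs(crec$hunt_hess - pool_pat$hunt_hess) / 4 +
      w["mfisher"] * abs(crec$mfisher - pool_pat$mfisher) / 4
    dist <- unname(dist)
    gap <- abs(pool$day_post_index - case_day[i])
    tol_used <- config$day_tolerance
    elig <- which(gap <= tol_used & available)
    if (length(elig) < config$k && config$widen_to > tol_used) {
      tol_used <- config$widen_to
      elig <- which(gap <= tol_used & available)
    }
    if (length(elig) < config$k)
      warning("case sample ", cases[i], ": only ", length(elig),
              " eligible control(s) for k = ", config$k)
    ord <- elig[order(dist[elig], pool$patient_id[elig],
                      pool$sample_id[elig])]
    pick <- utils::head(ord, config$k)
    if (config$reuse_policy == "globally_unique") available[pick] <- FALSE
    if (length(pick))
      rows[[length(rows) + 1L]] <- data.frame(
        case_sample_id = cases[i],
        control_sample_id = pool$sample_id[pick],
        distance = dist[pick],
        day_gap_used = gap[pick],
        stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_sample_id = character(), control_sample_id = character(),
               distance = numeric(), day_gap_used = integer())
  rownames(matches) <- NULL
  balance <- .balance_table(cases, matches, pool, pd, sd)
  list(matches = matches, balance = balance)
}

# standardized mean differences of matching covariates, case samples vs the
# whole pool (before) and vs the selected controls with multiplicity (after)
.balance_table <- function(cases, matches, pool, pd, sd) {
  covnum <- function(samp_ids) {
    pids <- sd$patient_id[match(samp_ids, sd$sample_id)]
    p <- pd[pids, , drop = FALSE]
    cbind(age = p$age, sex = as.numeric(factor(p$sex, levels = sort(unique(pd$sex)))),
          location = as.numeric(p$aneurysm_location == "anterior"),
          hunt_hess = p$hunt_hess, mfisher = p$mfisher)
  }
  smd <- function(a, b) {
    m <- colMeans(a) - colMeans(b)
    s <- sqrt((apply(a, 2, stats::var) + apply(b, 2, stats::var)) / 2)
    ifelse(s == 0, 0, m / s)
  }
  ca <- covnum(cases)
  before <- smd(ca, covnum(pool$sample_id))
  after <- if (nrow(matches)) smd(ca, covnum(matches$control_sample_id)) else
    before * NA
  data.frame(covariate = colnames(ca), smd_before = as.numeric(before),
             smd_after = as.numeric(after), stringsAsFactors = FALSE)
}
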