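#' Pipeline run configuration
#'
#' Exactly one of \code{input} (list of file paths: \code{patients,
#' samples, features}, optional \code{annotations}) or \code{synthetic}
#' (a \linkS4class{SynthConfig}) must be supplied.
#'
#' @param input named list of input CSV paths, or \code{NULL}.
#' @param synthetic a \linkS4class{SynthConfig}, or \code{NULL}.
#' @param match a \code{\link{matchConfig}}.
#' @param feature_scope scope for the differential screens.
#' @param track_features feature ids followed through the design
#'   comparison; defaults to the spiked features of a synthetic run.
#' @param ratio_pairs character \code{"NUM/DEN"} ratios to screen.
#' @param eval_feature predictor feature for the clinical evaluation
#'   (default: first tracked feature).
#' @param qc_alpha,qc_components Hotelling exclusion parameters.
#' @param n_boot,mc_iter bootstrap / Monte Carlo sizes.
#' @param run_monte_carlo run the single-sample sensitivity loop?
#' @param seed seed recorded and used for every stochastic stage.
#' @param out_dir optional directory for the CSV bundle and manifest.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(input = NULL, synthetic = NULL,
                      match = matchConfig(),
                      feature_scope = "annotated_only",
                      track_features = NULL,
                      ratio_pairs = NULL,
                      eval_feature = NULL,
                      qc_alpha = 0.001, qc_components = 5L,
                      n_boot = 2000L, mc_iter = 1000L,
                      run_monte_carlo = TRUE,
                      seed = 1L, out_dir = NULL) {
  if (is.null(input) == is.null(synthetic))
    stop("exactly one of 'input' and 'synthetic' must be given")
  cfg <- list(input = input, synthetic = synthetic, match = match,
              feature_scope = feature_scope,
              track_features = track_features, ratio_pairs = ratio_pairs,
              eval_feature = eval_feature, qc_alpha = qc_alpha,
              qc_components = as.integer(qc_components),
              n_boot = as.integer(n_boot), mc_iter = as.integer(mc_iter),
              run_monte_carlo = isTRUE(run_monte_carlo),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full phenotype-aligned analysis
#'
#' Load or simulate the cohort; log2-transform; align samples to event
#' times and build the two pre-event window strata; select matched
#' controls per stratum; exclude multivariate outliers (PCA + Hotelling
#' T2); run the differential screen per window; screen the log-ratio
#' features; evaluate the candidate predictor (standardized logistic
#' models, bootstrap ROC, DeLong comparisons, outcome correlations,
#' optional Monte Carlo sensitivity); and run the fixed-timepoint
#' comparator screens for every calendar day. When \code{out_dir} is set,
#' all tables plus a JSON run manifest are written.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list ("bundle") with elements \code{cohort, truth, aligned,
#'   strata, matches, balance, qc, discovery, ratios, ratio_discovery,
#'   observations, models, delong, spearman, monte_carlo, fixed_day,
#'   comparison, manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  log_lines <- character()
  say <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  truth <- NULL
  if (!is.null(config$synthetic)) {
    gen <- generateCohort(config$synthetic)
    cohort_raw <- gen$cohort
    truth <- gen$truth
    say("generate: ", ncol(cohort_raw), " samples, ", nrow(cohort_raw),
        " features")
  } else {
    cohort_raw <- readCohort(config$input$patients, config$input$samples,
                             config$input$features,
                             config$input$annotations)
    say("load: ", ncol(cohort_raw), " samples, ", nrow(cohort_raw),
        " features")
  }
  cohort <- log2Transform(cohort_raw)

  track <- config$track_features
  if (is.null(track))
    track <- if (!is.null(truth)) unique(truth$feature_id) else character()
  ratio_pairs <- config$ratio_pairs
  if (is.null(ratio_pairs) && all(c("ARG", "ORN", "CIT", "GLN", "GLU")
                                  %in% rownames(cohort)))
    ratio_pairs <- c("ARG/ORN", "ARG/CIT", "GLN/GLU")
  eval_feature <- config$eval_feature
  if (is.null(eval_feature) && length(track)) eval_feature <- track[1]

  aligned <- alignToEvent(cohort)
  strata <- buildStrata(aligned, cohort)
  say("align: ", sum(aligned$window != "none"), " in-window case samples; ",
      attr(strata, "dual_window_patients"), " dual-window patient(s)")

  matches <- list(); balance <- list()
  for (w in names(strata)) {
    if (!length(caseSamples(strata[[w]]))) next
    m <- selectMatchedControls(strata[[w]], cohort, config$match)
    matches[[w]] <- m$matches
    balance[[w]] <- m$balance
    say("match ", w, ": ", length(unique(m$matches$case_sample_id)),
        " cases -> ", length(unique(m$matches$control_sample_id)),
        " distinct control samples")
  }

  used <- unique(c(unlist(lapply(strata[names(matches)], caseSamples)),
                   unlist(lapply(matches, function(m) m$control_sample_id))))
  qc <- pcaHotellingExclude(cohort[, used], alpha = config$qc_alpha,
                            n_components = config$qc_components)
  excl <- qc$excluded_sample_ids
  say("qc: ", length(excl), " sample(s) excluded by Hotelling T2")

  discovery <- list()
  for (w in names(matches)) {
    discovery[[w]] <- runDiscovery(cohort, strata[[w]], matches[[w]],
                                   feature_scope = config$feature_scope,
                                   exclude_samples = excl)
    say("discover ", w, ": ", attr(discovery[[w]], "n_nominal"),
        " nominal, ", attr(discovery[[w]], "n_fdr"), " FDR hits")
  }

  ratios <- NULL; ratio_discovery <- list()
  if (!is.null(ratio_pairs)) {
    ratios <- makeRatioFeatures(cohort, ratio_pairs)
    for (w in names(matches))
      ratio_discovery[[w]] <- runDiscovery(ratios, strata[[w]], matches[[w]],
                                           feature_scope = "all_features",
                                           exclude_samples = excl)
    say("ratios: ", nrow(ratios), " ratio feature(s) screened")
  }

  observations <- NULL; models <- list(); delong <- list()
  spearman_tab <- NULL; mc <- NULL
  w_eval <- "W24_48"
  if (!is.null(eval_feature) && !is.null(matches[[w_eval]])) {
    observations <- buildPatientObservations(
      cohort, strata[[w_eval]], matches[[w_eval]], eval_feature,
      exclude_samples = excl)
    models$predictor_only <- fitLogisticStandardized(
      observations, eval_feature, "predictor_only")
    models$score_only <- fitLogisticStandardized(
      observations, "mfisher", "score_only")
    models$combined <- fitLogisticStandardized(
      observations, c(eval_feature, "mfisher"), "combined")
    for (id in names(models)) {
      roc <- rocAucBootstrap(observations$outcome, models[[id]]$fitted,
                             n_boot = config$n_boot, seed = config$seed)
      models[[id]]$auc_ci <- roc$ci
      models[[id]]$roc_points <- roc$roc_points
    }
    delong$combined_vs_score <- delongCompare(
      observations$outcome, models$combined$fitted,
      models$score_only$fitted)
    delong$combined_vs_predictor <- delongCompare(
      observations$outcome, models$combined$fitted,
      models$predictor_only$fitted)
    delong$predictor_vs_score <- delongCompare(
      observations$outcome, models$predictor_only$fitted,
      models$score_only$fitted)
    pd <- as.data.frame(patientData(cohort))
    spearman_tab <- spearmanOutcomeCorrelations(
      observations, eval_feature,
      intersect(c("mfisher", "gos_discharge", "gos_1w", "gos_1m",
                  "gos_12m", "mrs_12m"), colnames(pd)),
      patients = pd)
    if (config$run_monte_carlo) {
      mc <- monteCarloSingleSample(cohort, strata[[w_eval]],
                                   matches[[w_eval]], eval_feature,
                                   n_iter = config$mc_iter,
                                   seed = config$seed,
                                   exclude_samples = excl)
      say("monte carlo: mean AUC ", signif(mc$mean_auc, 3), " +- ",
          signif(mc$sd_auc, 2), " vs averaged ",
          signif(models$predictor_only$auc, 3))
    }
    say("evaluate: AUCs ",
        paste(vapply(models, function(m) signif(m$auc, 3), numeric(1)),
              collapse = " / "))
  }

  fixed_day <- list()
  study_days <- metadata(cohort)$study_days
  for (d in 0:study_days) {
    st <- withCallingHandlers(fixedTimepointStrata(cohort, d),
                              warning = function(w) invokeRestart("muffleWarning"))
    ca <- setdiff(st$case, excl); co <- setdiff(st$control, excl)
    if (length(ca) < 2 || length(co) < 2) next
    mat <- intensities(cohort)
    res <- .screen_matrix(mat[, ca, drop = FALSE], mat[, co, drop = FALSE])
    res$q <- bhFDR(res$p_student)
    res$day <- d
    fixed_day[[as.character(d)]] <- res
  }

  bundle <- list(cohort = cohort, truth = truth, aligned = aligned,
                 strata = strata, matches = matches, balance = balance,
                 qc = qc, discovery = discovery, ratios = ratios,
                 ratio_discovery = ratio_discovery,
                 observations = observations, models = models,
                 delong = delong, spearman = spearman_tab,
                 monte_carlo = mc, fixed_day = fixed_day,
                 track_features = track, config = config)
  bundle$comparison <- if (length(track)) compareDesigns(bundle, track) else
    NULL
  bundle$manifest <- list(
    seed = config$seed, feature_scope = config$feature_scope,
    match = unclass(config$match)[c("k", "day_tolerance", "widen_to",
                                    "reuse_policy")],
    qc = list(alpha = config$qc_alpha, components = config$qc_components,
              excluded = excl),
    n_samples = ncol(cohort), n_features = nrow(cohort),
    stages = log_lines)
  if (!is.null(config$out_dir)) .write_bundle(bundle, config$out_dir)
  bundle
}

#' Aligned-design versus fixed-timepoint comparison
#'
#' For each tracked feature: the aligned-window p/q/log2FC per window next
#' to the best (smallest-p) fixed-calendar-day screen of the same feature,
#' and the ratio of the fixed-day p to the aligned p. Ratios above 1 mean
#' the event-aligned design sharpened the signal.
#'
#' @param bundle output of \code{\link{runPipeline}}.
#' @param features feature ids to tabulate.
#' @return data.frame, one row per feature and window.
#' @export
compareDesigns <- function(bundle, features = bundle$track_features) {
  if (!length(bundle$fixed_day))
    stop("bundle has no fixed-timepoint comparator stage")
  rows <- list()
  for (f in features) {
    fx <- lapply(bundle$fixed_day, function(df) df[df$feature_id == f, ])
    fx <- do.call(rbind, fx[vapply(fx, nrow, integer(1)) > 0])
    if (is.null(fx) || !nrow(fx)) next
    best <- fx[which.min(fx$p_student), ]
    for (w in names(bundle$discovery)) {
      dd <- bundle$discovery[[w]]
      row <- dd[dd$feature_id == f, ]
      if (!nrow(row)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = f, window = w,
        pam_p = row$p_student, pam_q = row$q, pam_log2_fc = row$log2_fc,
        fixed_best_day = best$day, fixed_p = best$p_student,
        fixed_q = best$q, fixed_log2_fc = best$log2_fc,
        p_ratio_fixed_over_pam = best$p_student / row$p_student,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- list(aligned_samples = bundle$aligned)
  for (w in names(bundle$matches)) {
    tabs[[paste0("matches_", w)]] <- bundle$matches[[w]]
    tabs[[paste0("balance_", w)]] <- bundle$balance[[w]]
  }
  for (w in names(bundle$discovery))
    tabs[[paste0("discovery_", w)]] <- bundle$discovery[[w]]
  for (w in names(bundle$ratio_discovery))
    tabs[[paste0("ratios_", w)]] <- bundle$ratio_discovery[[w]]
  tabs$qc_pca <- data.frame(sample_id = names(bundle$qc$t2),
                            t2 = bundle$qc$t2,
                            excluded = names(bundle$qc$t2) %in%
                              bundle$qc$excluded_sample_ids)
  if (!is.null(bundle$observations))
    tabs$observations <- bundle$observations
  if (length(bundle$models)) {
    tabs$models <- do.call(rbind, lapply(bundle$models, function(m)
      data.frame(model_id = m$model_id, term = m$terms$term,
                 odds_ratio = m$terms$odds_ratio,
                 or_ci_low = m$terms$or_ci_low,
                 or_ci_high = m$terms$or_ci_high, p = m$terms$p,
                 mcfadden = m$mcfadden, aic = m$aic, auc = m$auc,
                 auc_ci_low = m$auc_ci[1], auc_ci_high = m$auc_ci[2])))
    tabs$delong <- do.call(rbind, lapply(names(bundle$delong), function(nm) {
      d <- bundle$delong[[nm]]
      data.frame(model_pair = nm, delta_auc = d$delta_auc, p = d$p)
    }))
  }
  if (!is.null(bundle$spearman)) tabs$spearman <- bundle$spearman
  if (!is.null(bundle$monte_carlo))
    tabs$montecarlo <- data.frame(iteration = seq_along(
      bundle$monte_carlo$aucs), auc = bundle$monte_carlo$aucs)
  if (!is.null(bundle$comparison)) tabs$design_comparison <- bundle$comparison
  if (!is.null(bundle$truth)) tabs$truth <- bundle$truth
  paths <- writeResults(tabs, dir)
  manifest <- bundle$manifest
  manifest$files <- basename(paths)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}
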