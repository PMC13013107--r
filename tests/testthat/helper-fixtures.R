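# Small deterministic fixtures shared across test files.

# a 4-patient cohort (2 event, 2 control) with hand-set values
tiny_cohort <- function(log2 = FALSE) {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3", "P4"),
    age = c(50, 60, 55, 65),
    sex = c("F", "M", "F", "M"),
    aneurysm_location = c("anterior", "anterior", "posterior", "anterior"),
    hunt_hess = c(3, 4, 2, 3),
    mfisher = c(4, 3, 2, 3),
    event_status = c(TRUE, TRUE, FALSE, FALSE),
    event_day = c(5L, 4L, NA, NA),
    mrs_12m = c(4L, 5L, 1L, 2L),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4", "S5", "S6"),
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P4"),
    day_post_index = c(4L, 3L, 2L, 4L, 2L, 4L),
    stringsAsFactors = FALSE)
  mat <- matrix(c(8, 4, 2, 16, 32, 64,
                  1, 2, 4, 8, 16, 32), nrow = 2, byrow = TRUE,
                dimnames = list(c("F1", "F2"), samples$sample_id))
  if (log2) mat <- log2(mat)
  MetaboCohort(mat, patients, samples, log2 = log2)
}

# a quick small synthetic run: cohort in log2 state plus strata and matches
small_synth <- function(seed = 1, n_features = 60,
                        spikes = list(list(feature_id = "ARG",
                                           effects = c(W24_48 = -0.715,
                                                       W48_72 = 0)))) {
  cfg <- synthConfig(n_features = n_features, spikes = spikes, seed = seed)
  g <- generateCohort(cfg)
  co <- log2Transform(g$cohort)
  aligned <- alignToEvent(co)
  strata <- suppressWarnings(buildStrata(aligned, co))
  matches <- lapply(strata, function(s)
    if (length(caseSamples(s)))
      suppressWarnings(selectMatchedControls(s, co))$matches else NULL)
  list(cohort = co, truth = g$truth, aligned = aligned, strata = strata,
       matches = matches)
}

# brute-force BH step-up: q_i = min over p_(j) >= p_i of p_(j) * m / j
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  # direct definition, no shortcuts: for each i, scan all j with p_(j)>=p_(i)
  q <- vapply(seq_len(m), function(i) {
    js <- which(ps >= ps[i] - 1e-15)
    min(ps[js] * m / js)
  }, numeric(1))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# exact paired signed-rank p by literal 2^n enumeration (n <= 12)
wilcoxon_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Ws <- apply(signs, 1, function(s) sum(r[s]))
  EW <- sum(r) / 2
  mean(abs(Ws - EW) >= abs(W - EW) - 1e-9)
}

# AUC by counting all case-control pairs
auc_allpairs <- function(y, score) {
  y <- as.logical(y)
  pos <- score[y]; neg <- score[!y]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}
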