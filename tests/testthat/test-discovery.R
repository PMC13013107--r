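test_that("Pareto scaling matches the hand formula and drops flat features", {
  m <- rbind(F1 = c(0, 2), F2 = c(1, 1, 1)[1:2], F3 = c(3, 7))
  expect_warning(s <- paretoScale(m), "zero-variance")
  # feature {0,2}: mean 1, sample sd sqrt(2); scaled = (x-1)/2^(1/4)
  expect_equal(unname(s["F1", ]), c(-1, 1) / 2^0.25)
  expect_equal(unname(s["F3", ]), c(-2, 2) / sqrt(sqrt(8)))
  expect_false("F2" %in% rownames(s))
  expect_error(paretoScale(s), "already")
  expect_error(paretoScale(rbind(F1 = c(1, 1))), "zero variance")
})

test_that("Hotelling T2 exclusion finds a planted multivariate outlier", {
  set.seed(7)
  n <- 50; p <- 30
  mat <- matrix(rnorm(p * (n + 1)), nrow = p,
                dimnames = list(paste0("F", 1:p), paste0("S", 1:(n + 1))))
  mat[1:10, n + 1] <- mat[1:10, n + 1] + 20
  qc <- pcaHotellingExclude(mat, alpha = 0.001, n_components = 5)
  expect_identical(qc$excluded_sample_ids, paste0("S", n + 1))
  expect_true(qc$t2[n + 1] > qc$t2_critical)
  # explained variance fractions are non-increasing
  expect_true(all(diff(qc$explained_variance_fractions) <= 1e-12))
  expect_error(pcaHotellingExclude(mat, n_components = 0), "n_components")
})

test_that("with one component T2 reduces to the squared standardized score", {
  set.seed(8)
  mat <- matrix(rnorm(40), nrow = 4)
  rownames(mat) <- paste0("F", 1:4); colnames(mat) <- paste0("S", 1:10)
  qc <- pcaHotellingExclude(mat, alpha = 0.01, n_components = 1)
  sc <- prcomp(t(paretoScale(mat)), center = FALSE)$x[, 1]
  expect_equal(unname(qc$t2), unname(sc^2 / var(sc) * (9 / 10) / (9 / 10)),
               tolerance = 1e-8)
  # critical value is the F quantile scaled by A(n-1)/(n-A)
  expect_equal(qc$t2_critical, 1 * 9 / 9 * qf(0.99, 1, 9))
})

test_that("two-group tests agree with the reference implementations", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    r <- twoGroupTests(x, y)
    expect_equal(r$p_student, t.test(x, y, var.equal = TRUE)$p.value)
    expect_equal(r$p_welch, t.test(x, y)$p.value)
    expect_equal(r$p_mwu, wilcox.test(x, y, exact = length(x) <= 25 &&
                                        length(y) <= 25)$p.value)
    expect_equal(r$log2_fc, mean(x) - mean(y))
    # Brown-Forsythe: one-way ANOVA of |x - median| equals the two-group t
    z <- c(abs(x - median(x)), abs(y - median(y)))
    g <- factor(rep(1:2, c(length(x), length(y))))
    expect_equal(r$p_levene, anova(lm(z ~ g))$`Pr(>F)`[1])
  }
})

test_that("two-group edge cases behave as specified", {
  r <- twoGroupTests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_student, 1)
  expect_equal(r$log2_fc, 0)
  # degenerate zero-variance pair is reported NA
  r <- twoGroupTests(c(1, 1), c(1, 1))
  expect_true(is.na(r$p_student) && is.na(r$p_welch))
  expect_error(twoGroupTests(1, c(1, 2)), "at least 2")
  # exact MWU on fully separated tiny groups: enumeration over C(4,2)
  r <- twoGroupTests(c(1, 2), c(100, 101))
  expect_equal(r$p_mwu, 2 / choose(4, 2))
})

test_that("Student and Welch coincide for equal variances and sizes", {
  set.seed(3)
  x <- rnorm(12); y <- rnorm(12)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)   # force equal variance
  r <- twoGroupTests(x, y)
  expect_equal(r$p_student, r$p_welch, tolerance = 1e-12)
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(8); y <- rnorm(10, 0.5)
    p0 <- twoGroupTests(x, y)$p_mwu
    f <- function(v) exp(3 * v) - 1
    expect_equal(twoGroupTests(f(x), f(y))$p_mwu, p0)
  }
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bhFDR(0.03), 0.03)
  expect_equal(bhFDR(c(0.01, 0.04, 0.03, 0.005)),
               c(0.02, 0.04, 0.04, 0.02))
  expect_equal(bhFDR(rep(0.2, 10)), rep(0.2, 10))
  expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
  # NAs are excluded from the burden
  q <- bhFDR(c(0.01, NA, 0.02))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.02))
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bhFDR(p), bh_bruteforce(p))
  }
  # q is monotone in p and never below p
  p <- sort(runif(30))
  q <- bhFDR(p)
  expect_true(all(diff(q) >= -1e-12))
  expect_true(all(q >= p - 1e-12))
})

test_that("the windowed screen recovers the spike and controls ranks", {
  run <- small_synth(seed = 17, n_features = 120)
  res <- runDiscovery(run$cohort, run$strata$W24_48, run$matches$W24_48)
  arg <- res[res$feature_id == "ARG", ]
  expect_lt(arg$p_student, 0.01)
  expect_equal(arg$q, bhFDR(res$p_student)[match("ARG", res$feature_id)])
  expect_true(all(sort(res$rank_student) ==
                    rank(res$p_student, ties.method = "min")[
                      order(res$p_student)]))
  # no effect planted at 48-72 h: same feature should look null there
  res2 <- runDiscovery(run$cohort, run$strata$W48_72, run$matches$W48_72)
  expect_gt(res2[res2$feature_id == "ARG", "p_student"], 0.01)
  # overlapping case/control ids are an integrity error
  bad <- run$matches$W24_48
  bad$control_sample_id[1] <- caseSamples(run$strata$W24_48)[1]
  expect_error(runDiscovery(run$cohort, run$strata$W24_48, bad), "overlap")
})

test_that("feature scope controls the multiple-testing burden", {
  cfg <- synthConfig(n_features = 40L, n_unannotated = 60L,
                     spikes = list(list(feature_id = "ARG",
                                        effects = c(W24_48 = -0.9))),
                     seed = 23L)
  g <- generateCohort(cfg)
  co <- log2Transform(g$cohort)
  st <- suppressWarnings(buildStrata(alignToEvent(co), co))
  m <- suppressWarnings(selectMatchedControls(st$W24_48, co))$matches
  ann <- runDiscovery(co, st$W24_48, m, "annotated_only")
  all_ <- runDiscovery(co, st$W24_48, m, "all_features")
  expect_equal(nrow(ann), 40)
  expect_equal(nrow(all_), 100)
  i <- match("ARG", all_$feature_id)
  expect_equal(all_$p_student[i], ann$p_student[match("ARG",
                                                      ann$feature_id)])
  expect_gte(all_$q[i], ann$q[match("ARG", ann$feature_id)])
})

test_that("rank concordance summarizes cross-method agreement", {
  res <- data.frame(feature_id = c("a", "b"),
                    rank_student = c(1L, 2L), rank_welch = c(1L, 2L),
                    rank_mwu = c(2L, 1L))
  rc <- rankConcordance(res, k = 1)
  expect_equal(rc$min_rank, c(1, 1))
  expect_equal(rc$max_rank, c(2, 2))
  expect_false(any(rc$all_tests_top_k))
  # anti-correlated p-vectors show up as max_rank >> min_rank
  m <- 20
  res2 <- data.frame(feature_id = letters[1:m],
                     rank_student = 1:m, rank_welch = 1:m,
                     rank_mwu = m:1)
  rc2 <- rankConcordance(res2)
  expect_equal(max(rc2$max_rank - rc2$min_rank), m - 1)
})

test_that("log-ratio features are log2 differences and screen correctly", {
  co <- tiny_cohort(log2 = TRUE)
  rt <- makeRatioFeatures(co, c("F1/F2", "F1/F1"))
  expect_equal(unname(intensities(rt)["F1/F1", ]), rep(0, 6))
  expect_equal(unname(intensities(rt)["F1/F2", "S1"]), 3)   # 8 vs 1
  expect_error(makeRatioFeatures(co, "F1/NOPE"), "unknown feature")
  # spiked numerator over a null denominator preserves the group shift
  run <- small_synth(seed = 29, n_features = 50, spikes = list(
    list(feature_id = "ARG", effects = c(W24_48 = -0.715)),
    list(feature_id = "ORN", effects = c(W24_48 = 0))))
  rt <- makeRatioFeatures(run$cohort, "ARG/ORN")
  res <- runDiscovery(rt, run$strata$W24_48, run$matches$W24_48,
                      "all_features")
  expect_equal(nrow(res), 1)
  expect_lt(abs(res$log2_fc - (-0.715)), 0.8)
  expect_lt(res$p_student, 0.1)
})

test_that("exact paired Wilcoxon equals literal sign enumeration", {
  # all-negative n=6 differences: W = 0, p = 2/64
  d <- -(1:6)
  r <- exactWilcoxonPaired(d)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 2 / 64)
  # W = 1 at n = 6: the printed-trend case, p = 0.0625
  d <- c(1, -2, -3, -4, -5, -6)
  r <- exactWilcoxonPaired(d)
  expect_equal(r$statistic, 1)
  expect_equal(r$p, 0.0625)
  # n = 1
  expect_equal(exactWilcoxonPaired(5)$p, 1)
  # zeros dropped with a warning; all-zero gives p = 1
  expect_warning(r <- exactWilcoxonPaired(c(0, 1, -2)), "zero")
  expect_equal(r$n, 2L)
  expect_warning(r0 <- exactWilcoxonPaired(c(0, 0)), "zero")
  expect_equal(r0$p, 1)
  # exhaustive agreement with the 2^n oracle for all n <= 10,
  # including tied absolute differences
  set.seed(19)
  for (n in 2:10) {
    d <- round(rnorm(n) * 4) / 2
    d[d == 0] <- 0.5
    expect_equal(suppressWarnings(exactWilcoxonPaired(d))$p,
                 wilcoxon_enum(d), info = paste("n =", n))
    # no ties: also matches the textbook exact test
    d2 <- rnorm(n)
    expect_equal(exactWilcoxonPaired(d2)$p, wilcox.test(d2)$p.value)
  }
})

test_that("outlier re-test drops the targeted extremes and recomputes", {
  run <- small_synth(seed = 37, n_features = 30)
  tab <- outlierSensitivityRetest(run$cohort, "ARG", run$strata,
                                  run$matches,
                                  drop_rules = list(W24_48 = "min",
                                                    W48_72 = "max"))
  b <- tab[tab$window == "W24_48" & tab$phase == "before", ]
  a <- tab[tab$window == "W24_48" & tab$phase == "after", ]
  expect_equal(a$n_case, b$n_case - 1)
  # recomputation matches a direct call without the dropped sample
  v <- intensities(run$cohort)["ARG", caseSamples(run$strata$W24_48)]
  ctrl <- intensities(run$cohort)["ARG",
                                  unique(run$matches$W24_48$control_sample_id)]
  direct <- twoGroupTests(v[-which.min(v)], ctrl)
  expect_equal(a$p_student, direct$p_student)
  # empty rules leave everything unchanged
  tab0 <- outlierSensitivityRetest(run$cohort, "ARG", run$strata,
                                   run$matches)
  expect_equal(tab0$p_student[tab0$phase == "before"],
               tab0$p_student[tab0$phase == "after"])
  # a planted variance outlier drives the Levene trigger, and dropping it
  # restores homogeneity
  set.seed(41)
  ctrl2 <- rnorm(30)
  case2 <- c(rnorm(5), 20)
  expect_lt(twoGroupTests(case2, ctrl2)$p_levene, 0.1)
  expect_true(twoGroupTests(case2, ctrl2)$robustness_flagged)
  expect_gt(twoGroupTests(case2[-6], ctrl2)$p_levene, 0.1)
})
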