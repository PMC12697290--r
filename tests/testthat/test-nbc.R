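# Binned naive Bayes consensus classifier, ROC/AUC, cross-validation.

test_that("score tables validate their invariants", {
  tab <- score_table(c("a", "b"), c("f1", "f2"),
                     matrix(c(-9, -7, -10, -8), 2), c(1L, 0L))
  expect_s3_class(tab, "ScoreTable")
  expect_error(score_table(c("a", "a"), "f", matrix(1:2, 2)), "unique")
  expect_error(score_table(c("a", "b"), "f", matrix(c(1, NA), 2)), "finite")
})

test_that("single-feature NBC log-odds are monotone for shifted Gaussians", {
  tab <- gen_score_table(score_sim_spec(n_active = 5000, n_decoy = 5000,
                                        feature_ids = "S1",
                                        active_mean = -9, decoy_mean = -6,
                                        sd = 1, seed = 5))
  m <- fit_nbc(tab)
  grid <- seq(-11, -4, by = 0.5)
  lo <- vapply(grid, function(v) predict_log_odds(m, c(S1 = v)), 0)
  # lower (more negative) docking scores must look more active
  expect_lt(stats::cor(grid, lo, method = "spearman"), -0.95)
  expect_gt(predict_log_odds(m, c(S1 = -9)), 0)
  expect_lt(predict_log_odds(m, c(S1 = -6)), 0)
})

test_that("smoothing limit: alpha -> Inf pushes posteriors to the priors", {
  tab <- toy_score_table(40, 60, delta = 3, seed = 7)
  m <- fit_nbc(tab, alpha = 1e9)
  lo <- predict(m, tab)
  prior_lo <- log(0.4 / 0.6)
  expect_true(all(abs(lo - prior_lo) < 1e-3))
})

test_that("duplicating a feature preserves the ligand ranking", {
  tab <- toy_score_table(30, 70, delta = 2, seed = 9)
  vals2 <- cbind(tab$values, tab$values[, 1])
  tab2 <- score_table(tab$ligand_ids, c("S1", "S1b"), vals2, tab$labels)
  m1 <- fit_nbc(tab)
  m2 <- fit_nbc(tab2)
  r1 <- rank(predict(m1, tab))
  r2 <- rank(predict(m2, tab2))
  expect_equal(r1, r2)
})

test_that("log-odds match hand arithmetic on a tiny binned model", {
  # two features, three value bins each, built from explicit counts
  vals <- matrix(c(1, 1, 2, 3, 3, 3,   # f1: actives low, decoys high
                   1, 2, 2, 1, 3, 3), ncol = 2)
  tab <- score_table(sprintf("m%d", 1:6), c("f1", "f2"), vals,
                     c(1L, 1L, 1L, 0L, 0L, 0L))
  m <- fit_nbc(tab, alpha = 1, n_bins = 3)
  # reproduce by hand: per-feature edges from pooled quantiles, Laplace-
  # smoothed class-conditional bin counts
  f1 <- m$features$f1; f2 <- m$features$f2
  b1 <- function(v) findInterval(v, f1$edges) + 2L
  b2 <- function(v) findInterval(v, f2$edges) + 2L
  k1 <- length(f1$edges) + 2
  for (v in c(1, 2, 3)) {
    c1 <- sum(b1(vals[1:3, 1]) == b1(v))
    c0 <- sum(b1(vals[4:6, 1]) == b1(v))
    expect_equal(f1$loglik1[b1(v)], log((c1 + 1) / (3 + k1)),
                 tolerance = 1e-12)
    expect_equal(f1$loglik0[b1(v)], log((c0 + 1) / (3 + k1)),
                 tolerance = 1e-12)
  }
  lo <- predict_log_odds(m, c(f1 = 1, f2 = 3))
  byhand <- log(1) +
    (f1$loglik1[b1(1)] - f1$loglik0[b1(1)]) +
    (f2$loglik1[b2(3)] - f2$loglik0[b2(3)])
  expect_equal(lo, byhand, tolerance = 1e-12)
  # missing feature is an error; sentinel must be explicit
  expect_error(predict_log_odds(m, c(f1 = 1)), "missing feature")
})

test_that("sentinel rows stay finite and occupy their own bin", {
  tab <- gen_fit_values(50, 50, active_fail_prob = 0.2,
                        decoy_fail_prob = 0.8, seed = 11)
  m <- fit_nbc(tab)
  lo_fail <- predict_log_odds(m, c(FitValue = -10))
  expect_true(is.finite(lo_fail))
  # failures are mostly decoys here, so the sentinel bin must look decoy-like
  expect_lt(lo_fail, 0)
  # a feature entirely sentinel in one class still fits (smoothing)
  vals <- matrix(c(rep(-10, 5), rnorm(5)), ncol = 1)
  t2 <- score_table(sprintf("x%d", 1:10), "f", vals, rep(c(1L, 0L), each = 5))
  expect_s3_class(fit_nbc(t2), "nbc_model")
})

test_that("rank AUC matches its closed form, identities and the reference", {
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(2, 10), rep_len(c(1, 0), 10))$auc, 0.5)
  set.seed(13)
  s <- rnorm(400); y <- rep_len(c(1L, 0L), 400)
  a1 <- roc_auc(s, y)$auc
  expect_equal(a1 + roc_auc(-s, y)$auc, 1, tolerance = 1e-12)
  expect_equal(roc_auc(s, y, direction = "lower")$auc, 1 - a1,
               tolerance = 1e-12)
  # independent reference implementation
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a1, ref, tolerance = 1e-9)
  # curve monotonicity
  r <- roc_auc(s, y)
  expect_true(all(diff(r$tpr) >= -1e-12))
  expect_true(all(diff(r$fpr) >= -1e-12))
  expect_error(roc_auc(s, rep(1, 400)), "both classes")
})

test_that("empirical AUC converges to the Gaussian closed form", {
  tab <- gen_score_table(score_sim_spec(n_active = 5e4, n_decoy = 5e4,
                                        feature_ids = "S1",
                                        active_mean = -9, decoy_mean = -7,
                                        sd = 1, rho = 0, seed = 17))
  auc <- roc_auc(tab$values[, 1], tab$labels, direction = "lower")$auc
  expect_close(auc, stats::pnorm(2 / sqrt(2)), 0.01)
})

test_that("cross-validated AUC is sane, seeded, and null-calibrated", {
  tab <- gen_score_table(score_sim_spec(n_active = 500, n_decoy = 500,
                                        feature_ids = "S1",
                                        active_mean = -10, decoy_mean = -7,
                                        sd = 1, seed = 19))
  expect_gt(cv_auc(tab, folds = 5, seed = 1), 0.95)
  expect_identical(cv_auc(tab, folds = 5, seed = 4),
                   cv_auc(tab, folds = 5, seed = 4))
  # permuted labels -> AUC near 0.5
  set.seed(23)
  tabp <- score_table(tab$ligand_ids, tab$feature_ids, tab$values,
                      sample(tab$labels))
  aucp <- cv_auc(tabp, folds = 5, seed = 2)
  expect_true(aucp > 0.4 && aucp < 0.6)
  expect_error(cv_auc(score_table(c("a", "b"), "f", matrix(1:2, 2),
                                  c(1L, 0L)), folds = 5), "at least")
})

test_that("a 4-structure panel enumerates its 11 combination models", {
  xtals <- c("xtalA", "xtalB", "xtalC", "xtalD")
  tab <- gen_score_table(score_sim_spec(
    n_active = 150, n_decoy = 350, feature_ids = xtals,
    active_mean = -9, decoy_mean = -7.5, sd = 1, rho = 0.2, seed = 29))
  combos <- all_feature_combos(xtals)
  expect_length(combos, 11)   # all 2-,3-,4-subsets of 4 structures
  res <- enumerate_combo_models(tab, combos, folds = 5, seed = 3)
  expect_equal(nrow(res), 11)
  expect_true(all(res$cv_auc > 0.5))
  # a combo of a feature with itself equals the singleton model
  dup <- enumerate_combo_models(tab, list(c("xtalA", "xtalA")), seed = 3)
  single <- cv_auc(tab, "xtalA", seed = 3)
  expect_equal(dup$cv_auc, single, tolerance = 1e-12)
  expect_error(enumerate_combo_models(tab, list(character(0))), "empty")
})

test_that("adding an independent informative feature raises mean cv AUC", {
  gains <- vapply(1:12, function(s) {
    tab <- gen_score_table(score_sim_spec(
      n_active = 150, n_decoy = 150, feature_ids = c("F1", "F2"),
      active_mean = -8, decoy_mean = -7, sd = 1, rho = 0, seed = 100 + s))
    cv_auc(tab, c("F1", "F2"), seed = s) - cv_auc(tab, "F1", seed = s)
  }, 0)
  expect_gt(mean(gains), 0)
})

test_that("score-table CSV round-trips values, labels and FAIL literals", {
  tab <- gen_fit_values(15, 25, active_fail_prob = 0.2,
                        decoy_fail_prob = 0.5, seed = 31)
  path <- tempfile(fileext = ".csv")
  write_score_csv(tab, path)
  txt <- readLines(path)
  expect_true(any(grepl("FAIL", txt)))
  back <- read_score_csv(path)
  expect_equal(back$ligand_ids, tab$ligand_ids)
  expect_equal(back$labels, tab$labels)
  expect_equal(back$values, tab$values, tolerance = 1e-9)
})
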