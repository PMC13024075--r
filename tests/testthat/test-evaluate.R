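# Confusion metrics, ROC/AUC, cross-validation, gap, coefficient ranking.

test_that("confusion counts with AD positive", {
  truth <- c(rep("AD", 4L), rep("CN", 6L))
  cm <- confusion(truth, truth)
  expect_identical(c(cm$TP, cm$TN, cm$FP, cm$FN), c(4L, 6L, 0L, 0L))

  all_cn <- confusion(c("AD", "AD", "AD", "CN"), rep("CN", 4L))
  expect_identical(all_cn$FN, 3L)
  expect_identical(all_cn$TP, 0L)

  set.seed(17)
  for (i in 1:5) {
    t <- sample(c("AD", "CN"), 30L, replace = TRUE)
    p <- sample(c("AD", "CN"), 30L, replace = TRUE)
    cm <- confusion(t, p)
    expect_identical(cm$TP + cm$TN + cm$FP + cm$FN, 30L)
  }
  expect_error(confusion(c("AD", "CN"), "AD"), "length")
  expect_error(confusion(c("AD", "MCI"), c("AD", "CN")), "labels")
})

test_that("metrics are exact ratios of the counts", {
  m <- metrics(confusion_counts(TP = 32L, TN = 125L, FP = 14L, FN = 4L))
  expect_equal(m$accuracy, 157 / 175)
  expect_equal(m$sensitivity, 32 / 36)
  expect_equal(m$specificity, 125 / 139)
  expect_equal(m$precision[["AD"]], 32 / 46)
  expect_equal(m$f1[["AD"]],
               2 * (32 / 46) * (32 / 36) / (32 / 46 + 32 / 36))

  perfect <- metrics(confusion_counts(TP = 5L, TN = 7L, FP = 0L, FN = 0L))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(unname(perfect$precision), c(1, 1))
  expect_equal(unname(perfect$f1), c(1, 1))
})

test_that("zero-denominator metrics surface as undefined, not 0", {
  m <- metrics(confusion_counts(TP = 0L, TN = 10L, FP = 0L, FN = 5L))
  expect_true(is.na(m$precision[["AD"]]))  # no positive predictions
  expect_identical(m$sensitivity, 0)
  only_pos <- metrics(confusion_counts(TP = 3L, TN = 0L, FP = 0L, FN = 0L))
  expect_true(is.na(only_pos$specificity))
})

test_that("ROC endpoints, monotonicity and canonical AUCs", {
  truth <- c(rep("AD", 3L), rep("CN", 3L))
  sep <- roc_auc(truth, c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1))
  expect_equal(sep$auc, 1)
  ties <- roc_auc(truth, rep(0.5, 6L))
  expect_equal(ties$auc, 0.5)
  # 4-pair enumeration: AD {0.9, 0.4} vs CN {0.8, 0.1} -> 3/4 concordant
  ex <- roc_auc(c("AD", "AD", "CN", "CN"), c(0.9, 0.4, 0.8, 0.1))
  expect_equal(ex$auc, 0.75)
  expect_equal(ex$auc, pairwise_auc(c("AD", "AD", "CN", "CN"),
                                    c(0.9, 0.4, 0.8, 0.1)))

  expect_equal(ex$fpr[1L], 0)
  expect_equal(ex$tpr[1L], 0)
  expect_equal(ex$fpr[length(ex$fpr)], 1)
  expect_equal(ex$tpr[length(ex$tpr)], 1)
  expect_true(all(diff(ex$fpr) >= 0))
  expect_true(all(diff(ex$tpr) >= 0))
  expect_error(roc_auc(rep("AD", 3L), c(1, 2, 3)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney enumeration on random data", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(5:200, 1L)
    truth <- sample(c("AD", "CN"), n, replace = TRUE)
    if (length(unique(truth)) < 2L) next
    # coarse grid forces plenty of ties
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    r <- roc_auc(truth, scores)
    expect_equal(r$auc, pairwise_auc(truth, scores), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(29)
  truth <- sample(c("AD", "CN"), 80L, replace = TRUE, prob = c(0.3, 0.7))
  scores <- rnorm(80L)
  a <- roc_auc(truth, scores)$auc
  expect_equal(roc_auc(truth, exp(scores))$auc, a)
  expect_equal(roc_auc(truth, plogis(3 * scores + 2))$auc, a)
})

test_that("AUC agrees with an established external implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- sample(c("AD", "CN"), 150L, replace = TRUE)
  scores <- rnorm(150L) + (truth == "AD")
  ours <- roc_auc(truth, scores)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("CN", "AD"),
    direction = "<", quiet = TRUE
  )))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("CV folds are stratified partitions and drive sensible AUCs", {
  cfg <- toy_config(regions = toy_regions(8L),
                    effect_ad = c(-1.5, -1.5, -1.5, -1.5, 1.5, 1.5, 1.5, 1.5),
                    n_ref = 600L, n_ad = 110L, n_cn = 413L)
  ref <- simulate_reference(cfg, seed = 35)
  coh <- simulate_diagnostic(cfg, seed = 36)
  nm <- fit_normative(ref)
  P <- percentile_scores(nm, coh)

  cv <- cross_validate(P, coh$diagnosis, k = 5L, seed = 37)
  folds <- cv$folds
  expect_identical(sort(unique(folds)), 1:5)
  sizes <- table(folds)
  expect_lte(max(sizes) - min(sizes), 1L)
  ad_per_fold <- table(folds[coh$diagnosis == "AD"])
  expect_lte(max(ad_per_fold) - min(ad_per_fold), 1L)
  # strong 8-region effect: high cross-validated discrimination
  expect_gt(cv$mean, 0.9)
  expect_equal(cv$sd, sd(cv$fold_auc))

  few <- c(which(coh$diagnosis == "CN")[1:8], which(coh$diagnosis == "AD")[1:2])
  expect_error(cross_validate(P[few, ], coh$diagnosis[few], k = 5L, seed = 1),
               "fewer than k")
})

test_that("null-effect cohorts give chance-level CV AUC", {
  cfg <- toy_config(effect_ad = 0, n_ref = 400L, n_ad = 110L, n_cn = 413L)
  ref <- simulate_reference(cfg, seed = 41)
  coh <- simulate_diagnostic(cfg, seed = 42)
  nm <- fit_normative(ref)
  P <- percentile_scores(nm, coh)
  cv <- cross_validate(P, coh$diagnosis, k = 5L, seed = 43)
  # Mann-Whitney null SD for a held-out fold (~22 AD / 83 CN),
  # divided by sqrt(k) for the mean across folds
  n_ad <- 22; n_cn <- 83
  sd_null <- sqrt((n_ad + n_cn + 1) / (12 * n_ad * n_cn)) / sqrt(5)
  expect_lt(abs(cv$mean - 0.5), 3 * sd_null)
})

test_that("validation gap and mean validation AUC", {
  expect_equal(validation_gap(0.963, 0.981), 0.018)
  expect_equal(mean_validation_auc(0.963, 0.981), 0.972)
  expect_equal(validation_gap(0.7, 0.7), 0)
  expect_equal(validation_gap(0.9, 0.7), validation_gap(0.7, 0.9))
  expect_error(validation_gap(1.2, 0.5), "auc")
})

test_that("coefficient ranking orders by |beta| with stable ties", {
  beta <- c("Left inferior lateral ventricle" = 1.995,
            "Left amygdala" = -1.422,
            "Right hippocampus" = -1.292,
            "CSF" = 0.956,
            "Left lateral occipital" = 0.004)
  rk <- rank_coefficients(beta)
  expect_identical(rk$region[1L], "Left inferior lateral ventricle")
  expect_equal(rk$coefficient[1L], 1.995)
  expect_identical(rk$region[2L], "Left amygdala")
  expect_equal(rk$coefficient[2L], -1.422)
  expect_identical(rk$region[nrow(rk)], "Left lateral occipital")
  # negation leaves the order unchanged
  expect_identical(rank_coefficients(-beta)$region, rk$region)
  # all-zero coefficients fall back to canonical region order
  zero <- stats::setNames(numeric(3L),
                          c("Right hippocampus", "CSF", "Left amygdala"))
  expect_identical(rank_coefficients(zero)$region,
                   c("CSF", "Left amygdala", "Right hippocampus"))
  expect_error(rank_coefficients(c(1, 2)), "named")
})
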