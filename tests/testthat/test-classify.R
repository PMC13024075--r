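# Splitting, standardization, class weighting, penalized logistic fit.

make_labelled_table <- function(n_ad, n_cn) {
  data.frame(subject_id = sprintf("S%04d", seq_len(n_ad + n_cn)),
             diagnosis = c(rep("AD", n_ad), rep("CN", n_cn)),
             stringsAsFactors = FALSE)
}

test_that("60/20/20 stratified split reproduces the canonical counts", {
  tab <- make_labelled_table(183L, 690L)
  sp <- stratified_split(tab, seed = 1L)
  expect_length(sp$train, 523L)
  expect_length(sp$validation, 175L)
  expect_length(sp$test, 175L)
  n_ad <- function(ids) sum(ids %in% tab$subject_id[tab$diagnosis == "AD"])
  expect_identical(n_ad(sp$train), 110L)
  expect_identical(n_ad(sp$validation), 37L)
  expect_identical(n_ad(sp$test), 36L)
})

test_that("exactly divisible inputs split without rounding", {
  tab <- make_labelled_table(5L, 5L)
  sp <- stratified_split(tab, seed = 3L)
  expect_length(sp$train, 6L)
  expect_length(sp$validation, 2L)
  expect_length(sp$test, 2L)
  ad_ids <- tab$subject_id[tab$diagnosis == "AD"]
  expect_identical(sum(sp$train %in% ad_ids), 3L)
  expect_identical(sum(sp$validation %in% ad_ids), 1L)
  expect_identical(sum(sp$test %in% ad_ids), 1L)
})

test_that("splits are deterministic, disjoint, exhaustive and stratified", {
  tab <- make_labelled_table(37L, 101L)
  a <- stratified_split(tab, seed = 5L)
  b <- stratified_split(tab, seed = 5L)
  expect_identical(a, b)
  all_ids <- sort(c(a$train, a$validation, a$test))
  expect_identical(all_ids, sort(tab$subject_id))
  expect_length(intersect(a$train, a$validation), 0L)
  expect_length(intersect(a$train, a$test), 0L)
  expect_length(intersect(a$validation, a$test), 0L)
  # each split's AD fraction within 1 subject of the overall fraction
  overall <- 37 / 138
  ad_ids <- tab$subject_id[tab$diagnosis == "AD"]
  for (s in list(a$train, a$validation, a$test)) {
    expect_lt(abs(sum(s %in% ad_ids) - overall * length(s)), 1 + 1e-9)
  }
  expect_error(stratified_split(tab, ratios = c(0.5, 0.2, 0.2)), "sum")
})

test_that("scaler computes training statistics and stays frozen", {
  x <- matrix(c(40, 60), ncol = 1L, dimnames = list(NULL, "f"))
  sc <- fit_scaler(x)
  expect_equal(unname(sc$center), 50)
  expect_equal(unname(sc$scale), sqrt(200))  # sqrt((10^2+10^2)/1)

  set.seed(6)
  train <- matrix(rnorm(200, 50, 20), 50L, 4L)
  sc <- fit_scaler(train)
  z <- predict(sc, train)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(apply(z, 2L, sd) - 1)), 1e-10)
  # applying to shifted held-out data leaves the shift visible (no leakage)
  shifted <- predict(sc, train + 5)
  expect_true(all(colMeans(shifted) > 0.1))

  const <- train; const[, 2L] <- 7
  colnames(const) <- paste0("r", 1:4)
  expect_error(fit_scaler(const), "r2")
})

test_that("class weights follow N/(2*N_class) with its identities", {
  labels <- c(rep("AD", 110L), rep("CN", 413L))
  w <- class_weights(labels)
  expect_equal(w[["AD"]], 523 / 220)
  expect_equal(w[["CN"]], 523 / 826)
  # weighted class totals each equal N/2; their sum is N
  expect_equal(w[["AD"]] * 110, 523 / 2)
  expect_equal(w[["CN"]] * 413, 523 / 2)
  expect_equal(w[["AD"]] * 110 + w[["CN"]] * 413, 523)

  balanced <- class_weights(rep(c("AD", "CN"), 25L))
  expect_equal(unname(balanced), c(1, 1))
  expect_error(class_weights(rep("AD", 10L)), "2 classes")
})

test_that("separated 1-D data yield a positive coefficient, near-zero intercept", {
  set.seed(42)
  x <- matrix(c(rnorm(200, 3, 0.5), rnorm(200, -3, 0.5)), ncol = 1L,
              dimnames = list(NULL, "f"))
  labels <- c(rep("AD", 200L), rep("CN", 200L))
  fit <- train_logistic(x, labels)
  expect_gt(fit$coefficients[["f"]], 0)
  expect_lt(abs(fit$intercept), 0.5)
  expect_true(fit$converged)
  expect_lte(fit$grad_norm, 1e-6)
})

test_that("flipping feature signs flips coefficients, intercept fixed", {
  set.seed(7)
  x <- matrix(rnorm(120), 40L, 3L, dimnames = list(NULL, paste0("f", 1:3)))
  labels <- rep(c("AD", "CN"), 20L)
  a <- train_logistic(x, labels)
  b <- train_logistic(-x, labels)
  expect_equal(b$coefficients, -a$coefficients, tolerance = 1e-8)
  expect_equal(b$intercept, a$intercept, tolerance = 1e-8)
})

test_that("fit matches an independent generic minimizer on tiny data", {
  set.seed(8)
  x <- matrix(rnorm(12), 6L, 2L, dimnames = list(NULL, c("f1", "f2")))
  labels <- c("AD", "CN", "AD", "CN", "AD", "CN")
  w <- class_weights(labels)
  for (C in c(0.5, 1.0)) {
    fit <- train_logistic(x, labels, C = C, tol = 1e-10)
    y <- ifelse(labels == "AD", 1, -1)
    oracle <- stats::optim(
      rep(0, 3L), oracle_objective, X = x, y = y, w = unname(w[labels]),
      C = C, method = "BFGS",
      control = list(maxit = 2000L, reltol = 1e-14)
    )
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - oracle$par)), 1e-4)
  }
})

test_that("coefficient norm shrinks monotonically as C decreases", {
  set.seed(9)
  x <- matrix(rnorm(300), 100L, 3L, dimnames = list(NULL, paste0("f", 1:3)))
  labels <- rep(c("AD", "CN"), 50L)
  norms <- vapply(c(0.01, 1, 100), function(C) {
    sqrt(sum(train_logistic(x, labels, C = C)$coefficients^2))
  }, numeric(1L))
  expect_true(all(diff(norms) > 0))  # larger C => weaker penalty => larger norm
})

test_that("agrees with glmnet's ridge logistic fit on matched objectives", {
  skip_if_not_installed("glmnet")
  set.seed(10)
  n <- 200L
  x <- matrix(rnorm(n * 4L), n, 4L, dimnames = list(NULL, paste0("f", 1:4)))
  eta <- 0.8 * x[, 1L] - 0.5 * x[, 3L]
  labels <- ifelse(runif(n) < plogis(eta), "AD", "CN")
  if (length(unique(labels)) < 2L) skip("degenerate draw")
  w <- class_weights(labels)
  C <- 1.0
  fit <- train_logistic(x, labels, C = C, tol = 1e-12)
  # glmnet minimizes (1/n) sum w_i loss + lambda/2 ||beta||^2 with weights
  # internally rescaled to sum to n (ours already do); lambda = 1/(n*C)
  g <- glmnet::glmnet(x, factor(labels, levels = c("CN", "AD")),
                      family = "binomial", alpha = 0,
                      lambda = 1 / (n * C), weights = unname(w[labels]),
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(fit$coefficients),
               as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(fit$intercept, as.numeric(g$a0), tolerance = 1e-3)
})

test_that("prediction applies the sigmoid to the frozen-scaled score", {
  # hand-built model: zero coefficients -> probability 1/2 everywhere
  regions <- paste0("f", 1:2)
  base <- list(intercept = 0,
               coefficients = stats::setNames(c(0, 0), regions),
               scaler = structure(list(center = stats::setNames(c(50, 50), regions),
                                       scale = stats::setNames(c(10, 10), regions)),
                                  class = "feature_scaler"),
               class_weights = c(AD = 1, CN = 1), regions = regions,
               C = 1, positive = "AD", negative = "CN", converged = TRUE,
               iterations = 0L, grad_norm = 0, seed = 42L, n_train = 0L)
  m0 <- structure(base, class = "ad_classifier")
  X <- matrix(c(10, 90, 55, 2), 2L, 2L, dimnames = list(NULL, regions))
  expect_equal(unname(predict(m0, X)), c(0.5, 0.5))

  # single unit coefficient: x at the training mean -> 0.5;
  # standardized score log(3) -> probability 3/4
  m1 <- base
  m1$coefficients <- stats::setNames(c(1, 0), regions)
  m1 <- structure(m1, class = "ad_classifier")
  X2 <- matrix(c(50, 50 + 10 * log(3), 50, 50), 2L, 2L,
               dimnames = list(NULL, regions))
  expect_equal(unname(predict(m1, X2)), c(0.5, 0.75))
  # monotone in the linear score, saturating towards 1
  X3 <- matrix(c(50 + 10 * 40, 50), 1L, 2L, dimnames = list(NULL, regions))
  expect_gt(predict(m1, X3), 1 - 1e-12)
})

test_that("thresholding follows the documented tie rule", {
  p <- c(a = 0.49, b = 0.51, c = 0.5)
  got <- classify_labels(p)
  expect_identical(unname(got), c("CN", "AD", "AD"))
  expect_identical(unname(classify_labels(p, threshold = 0)),
                   rep("AD", 3L))
  expect_error(classify_labels(c(0.2, 1.4)), "probabilities")
})

test_that("evaluation is unchanged under permutation of scored rows", {
  cfg <- toy_config(effect_ad = c(-1, 0, 0.5, 0), n_ref = 200L,
                    n_ad = 60L, n_cn = 60L)
  ref <- simulate_reference(cfg, seed = 11)
  coh <- simulate_diagnostic(cfg, seed = 12)
  nm <- fit_normative(ref)
  P <- percentile_scores(nm, coh)
  fit <- ad_classifier(P, coh$diagnosis)
  prob <- predict(fit, P)
  set.seed(13)
  perm <- sample(nrow(P))
  prob_perm <- predict(fit, P[perm, , drop = FALSE])
  expect_equal(unname(prob_perm), unname(prob[perm]))
  expect_equal(roc_auc(coh$diagnosis[perm], prob_perm)$auc,
               roc_auc(coh$diagnosis, prob)$auc)
})

test_that("classifier round-trips through its text serialization", {
  cfg <- toy_config(effect_ad = c(-1, 0, 0.5, 0), n_ref = 150L,
                    n_ad = 40L, n_cn = 60L)
  ref <- simulate_reference(cfg, seed = 14)
  coh <- simulate_diagnostic(cfg, seed = 15)
  nm <- fit_normative(ref)
  P <- percentile_scores(nm, coh)
  fit <- ad_classifier(P, coh$diagnosis)
  path <- withr::local_tempfile(fileext = ".txt")
  write_classifier(fit, path)
  back <- read_classifier(path)
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$intercept, fit$intercept)
  expect_identical(back$class_weights, fit$class_weights)
  expect_identical(unname(predict(back, P)), unname(predict(fit, P)))
})
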