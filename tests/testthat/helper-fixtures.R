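# Shared fixtures: small synthetic tables built in code at test time.

# A compact non-canonical region set for fast unit tests.
toy_regions <- function(k = 4L) {
  paste0("Test region ", LETTERS[seq_len(k)])
}

# Generator config over a custom region set with controllable parameters.
toy_config <- function(regions = toy_regions(),
                       beta0 = 5000, beta1 = -10, beta2 = 200,
                       sigma = 300, effect_ad = 0,
                       n_ref = 200L, n_ad = 40L, n_cn = 40L,
                       shared_factor_sd = 0) {
  k <- length(regions)
  specs <- data.frame(
    region = regions,
    beta0 = rep_len(beta0, k), beta1 = rep_len(beta1, k),
    beta2 = rep_len(beta2, k), sigma = rep_len(sigma, k),
    effect_ad = rep_len(effect_ad, k),
    stringsAsFactors = FALSE
  )
  cohorts <- list()
  if (n_ref > 0L) {
    cohorts$reference <- cohort_spec(n_ref, "REFERENCE", 40, 90,
                                     female_fraction = 0.5)
  }
  if (n_cn > 0L) {
    cohorts$CN <- cohort_spec(n_cn, "CN", 50, 90, female_fraction = 0.5)
  }
  if (n_ad > 0L) {
    cohorts$AD <- cohort_spec(n_ad, "AD", 50, 90, female_fraction = 0.5)
  }
  generator_config(region_specs = specs, cohorts = cohorts,
                   shared_factor_sd = shared_factor_sd)
}

# Ground-truth normative model matching a toy_config (no estimation).
toy_truth_model <- function(config) {
  rs <- config$region_specs
  coefs <- cbind(beta0 = rs$beta0, beta1 = rs$beta1, beta2 = rs$beta2)
  rownames(coefs) <- rs$region
  normative_model(coefs, stats::setNames(rs$sigma, rs$region))
}

# Small hand-built volume table (full 95 canonical regions) for I/O tests.
canonical_toy_table <- function(n = 3L, seed = 7L) {
  set.seed(seed)
  regs <- brain_regions()
  df <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    age = round(runif(n, 55, 85), 3),
    sex = rbinom(n, 1, 0.5),
    diagnosis = rep_len(c("CN", "AD"), n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (r in regs) df[[r]] <- round(runif(n, 500, 9000), 6)
  volume_table(df)
}

# Independent normal-equations OLS oracle: coefficients and their
# standard errors for y ~ [1, age, sex].
ols_oracle <- function(age, sex, y) {
  X <- cbind(1, age, sex)
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - 3L)
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))),
       sigma = sqrt(s2))
}

# Brute-force Mann-Whitney AUC by exhaustive pair enumeration.
pairwise_auc <- function(truth, scores, positive = "AD") {
  pos <- scores[truth == positive]
  neg <- scores[truth != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Independent evaluation of the penalized weighted logistic objective,
# written from the formula (not reusing package internals).
oracle_objective <- function(b, X, y, w, C) {
  eta <- b[1L] + drop(X %*% b[-1L])
  loss <- sum(w * log1p(exp(-y * eta)))
  loss + sum(b[-1L]^2) / (2 * C)
}
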