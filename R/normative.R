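# Per-region normative modelling and percentile scoring.
#
# For each region r an OLS regression on the reference cohort,
#   V_r = beta0 + beta1 * Age + beta2 * Sex + eps,   sd(eps) = sigma_r,
# gives the expected volume for a subject's age/sex. An individual volume is
# standardized, z = (V - V_expected) / sigma_r, and mapped to a percentile
# P = 100 * pnorm(z): the fraction of the age/sex-matched reference
# population expected to have an equal or smaller volume.

#' Fit per-region age/sex normative models on a reference cohort
#'
#' Ordinary least squares of each regional volume on `[1, age, sex]`,
#' region by region, with residual SD estimated with the unbiased `n - 3`
#' denominator (three regression parameters). The design must be full rank:
#' at least 4 subjects, both sexes present, non-constant age.
#'
#' @param reference A [volume_table()] of reference subjects.
#' @param sigma_floor Smallest admissible residual SD in mm^3; a region
#'   fitting below it is reported as degenerate and the fit fails.
#' @return An object of class `normative_model` with components
#'   `coefficients` (R x 3 matrix: `beta0`, `beta1`, `beta2`), `sigma`
#'   (named vector of residual SDs), `regions`, `n_ref`, `age_range`.
#' @seealso [percentile_scores()], [predict.normative_model()],
#'   [simulate.normative_model()]
#' @examples
#' cfg <- adni_like_config()
#' ref <- simulate_reference(cfg, seed = 1)
#' m <- fit_normative(ref)
#' coef(m)[1:3, ]
#' @export
fit_normative <- function(reference, sigma_floor = 1e-8) {
  stopifnot(inherits(reference, "volume_table"))
  regions <- attr(reference, "regions")
  n <- nrow(reference)
  if (n < 4L) stop("reference cohort must have at least 4 subjects")
  if (length(unique(reference$sex)) < 2L) {
    stop("rank-deficient design: sex is constant in the reference cohort")
  }
  if (length(unique(reference$age)) < 2L) {
    stop("rank-deficient design: age is constant in the reference cohort")
  }

  x <- cbind(age = reference$age, sex = reference$sex)
  vols <- volume_matrix(reference)
  # one multi-response OLS fit; identical to region-wise lm()
  fit <- stats::lm(vols ~ x)
  beta <- t(stats::coef(fit))
  colnames(beta) <- c("beta0", "beta1", "beta2")
  rownames(beta) <- regions
  if (any(!is.finite(beta))) stop("non-finite normative coefficients")
  res <- as.matrix(stats::residuals(fit))
  sigma <- sqrt(colSums(res^2) / (n - 3L))
  names(sigma) <- regions
  if (any(sigma < sigma_floor)) {
    stop("degenerate region(s) with residual SD below floor: ",
         paste(regions[sigma < sigma_floor], collapse = ", "))
  }

  structure(
    list(coefficients = beta, sigma = sigma, regions = regions,
         n_ref = n, age_range = range(reference$age)),
    class = "normative_model"
  )
}

# Build a normative_model directly from known generative parameters
# (e.g. a generator config), bypassing estimation. Used for calibration
# checks and for scoring against a ground-truth model.
#' Construct a normative model from explicit parameters
#'
#' @param coefficients R x 3 matrix (`beta0`, `beta1`, `beta2`), rows named
#'   by region.
#' @param sigma Named vector of positive residual SDs (mm^3).
#' @param n_ref,age_range Optional provenance fields.
#' @return A `normative_model`.
#' @export
normative_model <- function(coefficients, sigma, n_ref = NA_integer_,
                            age_range = c(NA_real_, NA_real_)) {
  coefficients <- as.matrix(coefficients)
  stopifnot(ncol(coefficients) == 3L,
            nrow(coefficients) == length(sigma),
            all(sigma > 0))
  if (is.null(rownames(coefficients))) {
    stop("coefficient rows must be named by region")
  }
  canon <- match_regions(rownames(coefficients))
  regions <- ifelse(is.na(canon), rownames(coefficients), canon)
  colnames(coefficients) <- c("beta0", "beta1", "beta2")
  rownames(coefficients) <- regions
  names(sigma) <- regions
  structure(list(coefficients = coefficients, sigma = sigma,
                 regions = regions, n_ref = n_ref, age_range = age_range),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("Normative volume model: %d region(s), reference n = %s\n",
              length(x$regions), format(x$n_ref)))
  if (all(is.finite(x$age_range))) {
    cat(sprintf("  fitted age range: %.1f-%.1f years\n",
                x$age_range[1L], x$age_range[2L]))
  }
  invisible(x)
}

#' @export
summary.normative_model <- function(object, ...) {
  b <- object$coefficients
  cat(sprintf("Normative volume model (%d regions, reference n = %s)\n",
              length(object$regions), format(object$n_ref)))
  cat(sprintf("  age slope (mm^3/yr): median %.1f [%.1f, %.1f]\n",
              stats::median(b[, "beta1"]), min(b[, "beta1"]), max(b[, "beta1"])))
  cat(sprintf("  sex offset (mm^3):   median %.1f [%.1f, %.1f]\n",
              stats::median(b[, "beta2"]), min(b[, "beta2"]), max(b[, "beta2"])))
  cat(sprintf("  residual SD (mm^3):  median %.1f [%.1f, %.1f]\n",
              stats::median(object$sigma), min(object$sigma), max(object$sigma)))
  invisible(object)
}

#' @export
coef.normative_model <- function(object, ...) object$coefficients

.check_region <- function(model, region) {
  r <- match_regions(region, model$regions)
  if (anyNA(r)) {
    stop("region not in model: ", paste(region[is.na(r)], collapse = ", "))
  }
  r
}

#' Expected regional volume for a given age and sex
#'
#' @param model A `normative_model`.
#' @param region Region name (canonical or cosmetic variant).
#' @param age Age in years.
#' @param sex 0 = female, 1 = male.
#' @return Expected volume in mm^3 (`beta0 + beta1*age + beta2*sex`).
#' @export
expected_volume <- function(model, region, age, sex) {
  r <- .check_region(model, region)
  b <- model$coefficients[r, , drop = FALSE]
  as.numeric(b[, "beta0"] + b[, "beta1"] * age + b[, "beta2"] * sex)
}

#' Standardized deviation of an observed volume from its normative value
#'
#' @inheritParams expected_volume
#' @param volume Observed volume in mm^3.
#' @return z-score `(volume - expected) / sigma_r` (dimensionless).
#' @export
volume_zscore <- function(model, region, volume, age, sex) {
  r <- .check_region(model, region)
  unname((volume - expected_volume(model, region, age, sex)) / model$sigma[r])
}

#' Convert a z-score to a population percentile
#'
#' `P = 100 * pnorm(z)`: the expected fraction of the (age/sex-adjusted)
#' reference population with an equal or smaller volume. Strictly increasing
#' in z; finite z maps to the open interval (0, 100); no rounding or
#' clipping is applied.
#'
#' @param z Finite numeric z-score(s).
#' @return Percentile(s) in (0, 100).
#' @examples
#' zscore_percentile(0)      # 50
#' zscore_percentile(-1.5)   # about 6.7
#' @export
zscore_percentile <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  100 * stats::pnorm(z)
}

#' Percentile profile of a single subject
#'
#' Applies [volume_zscore()] then [zscore_percentile()] to each region, in
#' canonical region order.
#'
#' @param model A `normative_model`.
#' @param subject A one-row [volume_table()] (or one-row data.frame with the
#'   same columns).
#' @return Named numeric vector of percentiles, one per model region.
#' @export
percentile_profile <- function(model, subject) {
  stopifnot(nrow(subject) == 1L)
  missing <- setdiff(region_key(model$regions), region_key(names(subject)))
  if (length(missing) > 0L) {
    stop("subject lacks volume(s) for region(s): ",
         paste(model$regions[region_key(model$regions) %in% missing],
               collapse = ", "))
  }
  drop(percentile_scores(model, subject))
}

#' Percentile feature matrix for a cohort
#'
#' The feature representation consumed by the classifier: one row per
#' subject, one column per region (canonical order), entries the
#' population-referenced percentile of that subject's regional volume.
#'
#' @param model A `normative_model`.
#' @param table A [volume_table()] (or data.frame with the same columns).
#' @return Numeric matrix `n x R`, rownames subject ids, colnames regions.
#' @export
percentile_scores <- function(model, table) {
  regions <- model$regions
  cols <- match(region_key(regions), region_key(names(table)))
  if (anyNA(cols)) {
    stop("table lacks region column(s): ",
         paste(regions[is.na(cols)], collapse = ", "))
  }
  vols <- as.matrix(as.data.frame(table)[, cols, drop = FALSE])
  colnames(vols) <- regions
  b <- model$coefficients
  expected <- outer(table$age, b[, "beta1"]) + outer(table$sex, b[, "beta2"]) +
    matrix(b[, "beta0"], nrow(vols), length(regions), byrow = TRUE)
  z <- (vols - expected) / matrix(model$sigma, nrow(vols), length(regions),
                                  byrow = TRUE)
  p <- 100 * stats::pnorm(z)
  rownames(p) <- as.character(table$subject_id)
  p
}

#' Residuals of a reference table under a normative model
#'
#' @param object A `normative_model`.
#' @param table A [volume_table()] to evaluate.
#' @param ... Unused.
#' @return Matrix of raw residuals (mm^3), `n x R`.
#' @export
residuals.normative_model <- function(object, table, ...) {
  vols <- as.matrix(as.data.frame(table)[object$regions])
  b <- object$coefficients
  expected <- outer(table$age, b[, "beta1"]) + outer(table$sex, b[, "beta2"]) +
    matrix(b[, "beta0"], nrow(vols), length(object$regions), byrow = TRUE)
  res <- vols - expected
  rownames(res) <- as.character(table$subject_id)
  res
}

#' Predict expected volumes for new subjects
#'
#' @param object A `normative_model`.
#' @param newdata data.frame with columns `age` and `sex`.
#' @param regions Regions to predict (default all model regions).
#' @param ... Unused.
#' @return Matrix of expected volumes (mm^3), one row per subject.
#' @export
predict.normative_model <- function(object, newdata,
                                    regions = object$regions, ...) {
  r <- .check_region(object, regions)
  b <- object$coefficients[r, , drop = FALSE]
  out <- outer(newdata$age, b[, "beta1"]) + outer(newdata$sex, b[, "beta2"]) +
    matrix(b[, "beta0"], nrow(newdata), length(r), byrow = TRUE)
  colnames(out) <- r
  out
}

#' Simulate subjects from a fitted normative model
#'
#' Draws cognitively-normal-like subjects whose volumes follow the model's
#' linear predictor plus `N(0, sigma_r)` noise — the parametric bootstrap of
#' the normative fit.
#'
#' @param object A `normative_model`.
#' @param nsim Number of subjects.
#' @param seed Optional integer seed.
#' @param age_range Age range to draw uniformly from (default the model's
#'   fitted range).
#' @param female_fraction Expected fraction of females.
#' @param label Diagnosis label for the simulated subjects.
#' @param ... Unused.
#' @return A [volume_table()].
#' @export
simulate.normative_model <- function(object, nsim = 1L, seed = NULL,
                                     age_range = object$age_range,
                                     female_fraction = 0.5,
                                     label = "REFERENCE", ...) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(is.finite(age_range)))
  n <- as.integer(nsim)
  age <- stats::runif(n, age_range[1L], age_range[2L])
  sex <- stats::rbinom(n, 1L, 1 - female_fraction)
  mu <- predict(object, data.frame(age = age, sex = sex))
  noise <- matrix(stats::rnorm(n * length(object$regions)), n) *
    matrix(object$sigma, n, length(object$regions), byrow = TRUE)
  df <- data.frame(subject_id = sprintf("SIM%04d", seq_len(n)),
                   age = age, sex = sex, diagnosis = rep(label, n),
                   stringsAsFactors = FALSE, check.names = FALSE)
  vols <- pmax(mu + noise, 0)
  for (j in seq_along(object$regions)) df[[object$regions[j]]] <- vols[, j]
  volume_table(df, regions = object$regions)
}
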