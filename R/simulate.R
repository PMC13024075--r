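# Synthetic cohort generator.
#
# Emulates the generative model the normative stage assumes: per region r,
#   V_r = beta0 + beta1 * age + beta2 * sex + eps,  eps ~ N(0, sigma_r^2),
# with diagnostic (AD) subjects additionally shifted by effect_ad * sigma_r
# in the affected regions. Residuals are independent across regions by
# default; an optional shared latent factor adds global volume correlation.

# Regions with early, pronounced AD atrophy (medial temporal) get negative
# default effects; CSF-space regions that enlarge with atrophy get positive
# ones.
.AD_ATROPHY_REGIONS <- c(
  "Left hippocampus", "Right hippocampus",
  "Left amygdala", "Right amygdala",
  "Left entorhinal", "Right entorhinal"
)
.AD_ENLARGED_REGIONS <- c(
  "Left inferior lateral ventricle", "Right inferior lateral ventricle",
  "Left lateral ventricle", "Right lateral ventricle",
  "CSF", "WM hypointensities"
)

# Rough baseline adult volumes (mm^3) by structure class; used to seed
# realistic per-region generative parameters.
.region_baseline <- function(region) {
  key <- region_key(region)
  if (grepl("cerebral white matter", key)) return(240000)
  if (grepl("cerebellum cortex", key)) return(53000)
  if (grepl("cerebellum white matter", key)) return(14000)
  if (grepl("^(left|right) lateral ventricle", key)) return(15000)
  if (grepl("inferior lateral ventricle", key)) return(600)
  if (key == "3rd ventricle") return(1500)
  if (key == "4th ventricle") return(1800)
  if (key == "csf") return(1100)
  if (key == "brain stem") return(21000)
  if (key == "wm hypointensities") return(2500)
  if (grepl("thalamus", key)) return(7500)
  if (grepl("hippocampus", key)) return(4000)
  if (grepl("amygdala", key)) return(1600)
  if (grepl("caudate", key)) return(3500)
  if (grepl("putamen", key)) return(5000)
  if (grepl("pallidum", key)) return(1800)
  if (grepl("accumbens", key)) return(600)
  if (grepl("ventral dc", key)) return(4000)
  if (grepl("choroid plexus", key)) return(800)
  if (grepl("entorhinal", key)) return(1900)
  8000  # generic cortical parcel
}

#' Per-region generative parameter defaults
#'
#' One row per region with the linear age/sex model parameters used for
#' simulation: intercept `beta0` (mm^3), age slope `beta1` (mm^3/year), male
#' offset `beta2` (mm^3), residual SD `sigma` (mm^3), and the AD effect
#' `effect_ad` in sigma units (negative = atrophy, positive = enlargement).
#'
#' Defaults: baseline volumes by structure class; parenchymal regions shrink
#' 0.15 percent of baseline per year while CSF spaces grow 1.5 percent per
#' year; males +4 percent of baseline; residual SD 12 percent of baseline;
#' `effect_ad` is -1.5 for hippocampi, amygdalae and entorhinal cortices,
#' +1.5 for inferior lateral ventricles, lateral ventricles, CSF and WM
#' hypointensities, and 0 elsewhere.
#'
#' @param regions Region set (default canonical 95).
#' @param effect_scale Multiplier applied to the default `effect_ad` values
#'   (1 reproduces the defaults; use e.g. 2/3 for a milder-disease cohort).
#' @return data.frame with columns `region`, `beta0`, `beta1`, `beta2`,
#'   `sigma`, `effect_ad`.
#' @export
region_gen_defaults <- function(regions = brain_regions(), effect_scale = 1) {
  base <- vapply(regions, .region_baseline, numeric(1L))
  csf_space <- region_key(regions) %in%
    region_key(c(.AD_ENLARGED_REGIONS, "3rd Ventricle", "4th Ventricle",
                 "Left choroid plexus", "Right choroid plexus"))
  effect <- numeric(length(regions))
  effect[region_key(regions) %in% region_key(.AD_ATROPHY_REGIONS)] <- -1.5
  effect[region_key(regions) %in% region_key(.AD_ENLARGED_REGIONS)] <- 1.5
  data.frame(
    region = regions,
    beta0 = base,
    beta1 = ifelse(csf_space, 0.015 * base, -0.0015 * base),
    beta2 = 0.04 * base,
    sigma = 0.12 * base,
    effect_ad = effect * effect_scale,
    stringsAsFactors = FALSE
  )
}

#' Cohort demographic specification
#'
#' @param n Number of subjects (>= 0).
#' @param label Diagnosis label assigned to the cohort (`"REFERENCE"`,
#'   `"CN"`, `"AD"`, `"UNKNOWN"`).
#' @param age_low,age_high Age range in years (`age_low < age_high`).
#' @param female_fraction Expected fraction of females in `[0, 1]`.
#' @param age_mean,age_sd Optional mean/SD (years) for the truncated-normal
#'   age mode; both must be given to activate it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, label, age_low, age_high, female_fraction = 0.5,
                        age_mean = NULL, age_sd = NULL) {
  stopifnot(n >= 0, age_low < age_high,
            female_fraction >= 0, female_fraction <= 1)
  label <- .parse_diagnosis(label)
  structure(list(n = as.integer(n), label = label,
                 age_low = age_low, age_high = age_high,
                 female_fraction = female_fraction,
                 age_mean = age_mean, age_sd = age_sd),
            class = "cohort_spec")
}

#' Generator configuration
#'
#' Bundles per-region generative parameters, cohort demographics, the
#' default seed, and the optional shared latent "global atrophy" factor
#' (SD in sigma units added to every region for a subject; 0 = independent
#' residuals).
#'
#' @param region_specs data.frame as returned by [region_gen_defaults()].
#' @param cohorts Named list of [cohort_spec()] objects.
#' @param seed Default integer seed.
#' @param shared_factor_sd Non-negative scalar; SD of the shared per-subject
#'   latent factor, in units of each region's sigma.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(region_specs = region_gen_defaults(),
                             cohorts = list(), seed = 42L,
                             shared_factor_sd = 0) {
  stopifnot(is.data.frame(region_specs),
            all(c("region", "beta0", "beta1", "beta2", "sigma",
                  "effect_ad") %in% names(region_specs)),
            all(region_specs$sigma > 0),
            !anyDuplicated(region_key(region_specs$region)),
            shared_factor_sd >= 0)
  stopifnot(all(vapply(cohorts, inherits, logical(1L), "cohort_spec")))
  structure(list(region_specs = region_specs, cohorts = cohorts,
                 seed = as.integer(seed),
                 shared_factor_sd = shared_factor_sd),
            class = "generator_config")
}

#' Default ADNI-like generator configuration
#'
#' Reference cohort of 1833 cognitively normal subjects aged 21-90 (52.9
#' percent male), plus diagnostic cohorts mirroring the ADNI AD/CN case mix:
#' 690 CN (age 71.8 +/- 7.0, 58.4 percent female) and 183 AD (age 77.3 +/-
#' 6.1, 46.4 percent female), ages truncated to 50-90. AD effects are the
#' [region_gen_defaults()] +/-1.5 sigma pattern.
#'
#' @param effect_scale Multiplier on the default AD effect sizes.
#' @param seed Default seed stored in the config.
#' @return A [generator_config()].
#' @export
adni_like_config <- function(effect_scale = 1, seed = 42L) {
  generator_config(
    region_specs = region_gen_defaults(effect_scale = effect_scale),
    cohorts = list(
      reference = cohort_spec(1833, "REFERENCE", 21, 90,
                              female_fraction = 863 / 1833),
      CN = cohort_spec(690, "CN", 50, 90, female_fraction = 403 / 690,
                       age_mean = 71.8, age_sd = 7.0),
      AD = cohort_spec(183, "AD", 50, 90, female_fraction = 85 / 183,
                       age_mean = 77.3, age_sd = 6.1)
    ),
    seed = seed
  )
}

#' Korean-cohort-like external generator configuration
#'
#' A small balanced external cohort (36 AD / 36 CN, ages near 68, roughly
#' balanced sex) with milder AD effects (+/-1.0 sigma by default, vs 1.5 in
#' the internal cohort) to emulate greater heterogeneity in disease severity
#' in an independently recruited population.
#'
#' @param effect_scale Multiplier on the default effect sizes; the default
#'   2/3 turns the +/-1.5 sigma pattern into +/-1.0 sigma.
#' @param seed Default seed stored in the config.
#' @return A [generator_config()].
#' @export
korean_like_config <- function(effect_scale = 2 / 3, seed = 4242L) {
  generator_config(
    region_specs = region_gen_defaults(effect_scale = effect_scale),
    cohorts = list(
      CN = cohort_spec(36, "CN", 50, 90, female_fraction = 17 / 36,
                       age_mean = 68.5, age_sd = 7.1),
      AD = cohort_spec(36, "AD", 50, 90, female_fraction = 17 / 36,
                       age_mean = 67.8, age_sd = 7.0)
    ),
    seed = seed
  )
}

.draw_ages <- function(spec, n) {
  if (!is.null(spec$age_mean) && !is.null(spec$age_sd)) {
    # truncated normal by rejection; acceptance region is wide for all
    # defaults so this terminates quickly
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rnorm(max(n, 16L), spec$age_mean, spec$age_sd)
      out <- c(out, draw[draw >= spec$age_low & draw <= spec$age_high])
    }
    out[seq_len(n)]
  } else {
    stats::runif(n, spec$age_low, spec$age_high)
  }
}

.simulate_one_cohort <- function(config, spec, id_prefix) {
  n <- spec$n
  rs <- config$region_specs
  regions <- rs$region
  age <- .draw_ages(spec, n)
  sex <- stats::rbinom(n, 1L, 1 - spec$female_fraction)
  shared <- if (config$shared_factor_sd > 0) {
    stats::rnorm(n, 0, config$shared_factor_sd)
  } else {
    numeric(n)
  }
  is_ad <- spec$label == "AD"
  vols <- matrix(NA_real_, nrow = n, ncol = nrow(rs))
  for (j in seq_len(nrow(rs))) {
    mu <- rs$beta0[j] + rs$beta1[j] * age + rs$beta2[j] * sex
    if (is_ad) mu <- mu + rs$effect_ad[j] * rs$sigma[j]
    vols[, j] <- mu + rs$sigma[j] * (stats::rnorm(n) + shared)
  }
  vols <- pmax(vols, 0)  # volumes are physical quantities
  df <- data.frame(
    subject_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    age = age, sex = sex, diagnosis = rep(spec$label, n),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (j in seq_along(regions)) df[[regions[j]]] <- vols[, j]
  df
}

.simulate_cohorts <- function(config, labels, seed) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  set.seed(seed)
  keep <- vapply(config$cohorts, function(s) s$label %in% labels, logical(1L))
  specs <- config$cohorts[keep]
  if (length(specs) == 0L || sum(vapply(specs, `[[`, integer(1L), "n")) == 0L) {
    regions <- config$region_specs$region
    empty <- data.frame(subject_id = character(0), age = numeric(0),
                        sex = numeric(0), diagnosis = character(0),
                        stringsAsFactors = FALSE)
    for (r in regions) empty[[r]] <- numeric(0)
    return(volume_table(empty, regions = regions))
  }
  parts <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    prefix <- sprintf("%s-%02d-", substr(specs[[i]]$label, 1L, 3L), i)
    parts[[i]] <- .simulate_one_cohort(config, specs[[i]], prefix)
  }
  volume_table(do.call(rbind, parts),
               regions = config$region_specs$region)
}

#' Simulate a reference cohort
#'
#' Draws the cohorts labelled `REFERENCE` in `config`: ages uniform on the
#' cohort range (or truncated normal if the spec carries mean/SD), sex
#' Bernoulli with the configured female fraction, and each regional volume
#' `beta0 + beta1*age + beta2*sex + N(0, sigma)`. A fixed seed gives
#' bit-identical output.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (default: the config's seed).
#' @return A [volume_table()] (empty, not an error, if n = 0).
#' @export
simulate_reference <- function(config, seed = NULL) {
  .simulate_cohorts(config, "REFERENCE", seed)
}

#' Simulate a diagnostic (AD/CN) cohort
#'
#' CN subjects are drawn from the reference generative model; AD subjects
#' have each regional mean shifted by `effect_ad * sigma`. Diagnosis labels
#' are set accordingly.
#'
#' @inheritParams simulate_reference
#' @return A [volume_table()] with `AD`/`CN` diagnosis labels.
#' @export
simulate_diagnostic <- function(config, seed = NULL) {
  .simulate_cohorts(config, c("AD", "CN"), seed)
}
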