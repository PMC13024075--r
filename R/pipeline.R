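# End-to-end experiment driver.
#
# Stages, in order, with strict leakage control:
#   1. obtain reference, internal diagnostic and external cohorts
#      (simulated from generator configs, or loaded from volume tables);
#   2. fit the normative model on the reference cohort only;
#   3. score percentile profiles for every cohort;
#   4. stratified 60/20/20 split of the internal cohort;
#   5. fit scaler + class weights + logistic classifier on the training
#      split only; 5-fold stratified CV within the training split;
#   6. evaluate on internal validation, held-out test, and the external
#      cohort (no retraining or parameter adjustment);
#   7. validation gap and mean validation AUC; coefficient ranking.

#' Experiment configuration
#'
#' In `"simulate"` mode the reference/internal cohorts come from
#' `generator` and the external cohort from `external_generator`; in
#' `"load"` mode they are read from `reference_path` / `internal_path` /
#' `external_path` (CSV volume tables). The external cohort is optional in
#' both modes.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param generator [generator_config()] for the reference + internal
#'   cohorts (default [adni_like_config()]).
#' @param external_generator [generator_config()] for the external cohort,
#'   or `NULL` to skip it (default [korean_like_config()], whose milder
#'   effect sizes emulate an independently recruited population).
#' @param reference_path,internal_path,external_path File paths for
#'   `"load"` mode (`external_path` optional).
#' @param regions Region set expected in loaded tables (default the
#'   canonical 95; ignored in `"simulate"` mode, where the generator's
#'   region set applies).
#' @param ratios Split ratios (default 60/20/20).
#' @param seed Master integer seed; stage seeds are derived from it.
#' @param C,max_iter,threshold Classifier settings.
#' @param k Cross-validation folds.
#' @param out_dir Optional directory; when given, all intermediate
#'   artifacts (tables, models, per-subject probabilities, JSON report) are
#'   persisted there.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("simulate", "load"),
                              generator = adni_like_config(),
                              external_generator = korean_like_config(),
                              reference_path = NULL, internal_path = NULL,
                              external_path = NULL, regions = brain_regions(),
                              ratios = c(0.6, 0.2, 0.2), seed = 42L,
                              C = 1.0, max_iter = 1000L, threshold = 0.5,
                              k = 5L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "load") {
    for (p in c(reference_path, internal_path, external_path)) {
      if (!file.exists(p)) stop("input path does not exist: ", p)
    }
    if (is.null(reference_path) || is.null(internal_path)) {
      stop("load mode requires reference_path and internal_path")
    }
  }
  structure(list(mode = mode, generator = generator,
                 external_generator = external_generator,
                 reference_path = reference_path,
                 internal_path = internal_path,
                 external_path = external_path, regions = regions,
                 ratios = ratios, seed = as.integer(seed), C = C,
                 max_iter = as.integer(max_iter), threshold = threshold,
                 k = as.integer(k), out_dir = out_dir),
            class = "experiment_config")
}

.eval_set <- function(fit, percentiles, labels, threshold) {
  prob <- predict(fit, percentiles)
  pred <- classify_labels(prob, threshold = threshold,
                          positive = fit$positive, negative = fit$negative)
  roc <- roc_auc(labels, prob, positive = fit$positive)
  list(metrics = metrics(confusion(labels, pred, positive = fit$positive,
                                   negative = fit$negative)),
       auc = roc$auc, roc = roc, probabilities = prob, predicted = pred,
       truth = labels)
}

#' Run the full percentile-classification experiment
#'
#' Executes simulate/load, normative fit, percentile scoring, stratified
#' split, training, cross-validation and the three-way evaluation described
#' in [experiment_config()]. Deterministic: the same config and seed give a
#' bit-identical report.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Object of class `ad_experiment`: list with `normative`,
#'   `classifier`, `split`, `cv`, `evaluations` (named list with
#'   `validation`, `test`, and optionally `external`, each holding a
#'   [metrics()] report, AUC, ROC and per-subject probabilities),
#'   `validation_gap`, `mean_validation_auc`, `coefficient_ranking`, and
#'   `provenance`.
#' @examples
#' \donttest{
#' report <- run_experiment(experiment_config(seed = 42))
#' report
#' }
#' @export
run_experiment <- function(config = experiment_config(), quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  # --- stage 1: cohorts -----------------------------------------------
  if (config$mode == "simulate") {
    reference <- simulate_reference(config$generator, seed = seed)
    internal <- simulate_diagnostic(config$generator, seed = seed + 1L)
    external <- if (!is.null(config$external_generator)) {
      simulate_diagnostic(config$external_generator, seed = seed + 2L)
    }
  } else {
    reference <- read_volume_table(config$reference_path,
                                   regions = config$regions)
    internal <- read_volume_table(config$internal_path,
                                  regions = config$regions)
    external <- if (!is.null(config$external_path)) {
      read_volume_table(config$external_path, regions = config$regions)
    }
  }
  say("cohorts: reference n=%d, internal n=%d, external n=%s",
      nrow(reference), nrow(internal),
      if (is.null(external)) "none" else nrow(external))

  # --- stage 2-3: normative fit (reference only) + percentile scoring --
  nm <- fit_normative(reference)
  p_internal <- percentile_scores(nm, internal)
  p_external <- if (!is.null(external)) percentile_scores(nm, external)
  say("normative model fitted on %d reference subjects", nm$n_ref)

  # --- stage 4: stratified split of the internal cohort -----------------
  split <- stratified_split(internal, ratios = config$ratios, seed = seed)
  idx <- function(ids) match(ids, internal$subject_id)
  lab <- function(ids) internal$diagnosis[idx(ids)]
  say("split: train %d / validation %d / test %d", length(split$train),
      length(split$validation), length(split$test))

  # --- stage 5: training-split-only fitting + CV ------------------------
  X_train <- p_internal[idx(split$train), , drop = FALSE]
  fit <- ad_classifier(X_train, lab(split$train), C = config$C,
                       max_iter = config$max_iter, seed = seed)
  cv <- cross_validate(X_train, lab(split$train), k = config$k,
                       seed = seed, C = config$C,
                       max_iter = config$max_iter)
  say("training: %d subjects, CV AUC %.3f +/- %.3f", length(split$train),
      cv$mean, cv$sd)

  # --- stage 6: three-way evaluation ------------------------------------
  evaluations <- list(
    validation = .eval_set(fit, p_internal[idx(split$validation), , drop = FALSE],
                           lab(split$validation), config$threshold),
    test = .eval_set(fit, p_internal[idx(split$test), , drop = FALSE],
                     lab(split$test), config$threshold)
  )
  if (!is.null(external)) {
    evaluations$external <- .eval_set(fit, p_external, external$diagnosis,
                                      config$threshold)
  }
  for (nm_set in names(evaluations)) {
    say("%s: AUC %.3f, accuracy %.3f", nm_set, evaluations[[nm_set]]$auc,
        evaluations[[nm_set]]$metrics$accuracy)
  }

  # --- stage 7: generalization statistics -------------------------------
  gap <- mean_auc <- NA_real_
  if (!is.null(external)) {
    gap <- validation_gap(evaluations$validation$auc, evaluations$external$auc)
    mean_auc <- mean_validation_auc(evaluations$validation$auc,
                                    evaluations$external$auc)
  }

  report <- structure(list(
    normative = nm, classifier = fit, split = split, cv = cv,
    evaluations = evaluations, validation_gap = gap,
    mean_validation_auc = mean_auc,
    coefficient_ranking = rank_coefficients(fit),
    provenance = list(seed = seed, mode = config$mode, C = config$C,
                      threshold = config$threshold, ratios = config$ratios,
                      k = config$k,
                      package_version = as.character(utils::packageVersion("volpct")))
  ), class = "ad_experiment")

  if (!is.null(config$out_dir)) {
    .persist_experiment(report, config,
                        list(reference = reference, internal = internal,
                             external = external),
                        list(internal = p_internal, external = p_external))
  }
  report
}

.persist_experiment <- function(report, config, tables, percentiles) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  write_volume_table(tables$reference, p("reference.csv"))
  write_volume_table(tables$internal, p("internal.csv"))
  if (!is.null(tables$external)) {
    write_volume_table(tables$external, p("external.csv"))
  }
  write_normative_model(report$normative, p("normative_model.txt"))
  write_classifier(report$classifier, p("classifier.txt"))
  for (nm in names(percentiles)) {
    if (is.null(percentiles[[nm]])) next
    utils::write.csv(data.frame(subject_id = rownames(percentiles[[nm]]),
                                percentiles[[nm]], check.names = FALSE),
                     p(sprintf("percentiles_%s.csv", nm)), row.names = FALSE)
  }
  for (nm in names(report$evaluations)) {
    ev <- report$evaluations[[nm]]
    utils::write.csv(
      data.frame(subject_id = names(ev$probabilities),
                 probability = unname(ev$probabilities),
                 predicted = unname(ev$predicted), truth = ev$truth),
      p(sprintf("probabilities_%s.csv", nm)), row.names = FALSE)
  }
  jsonlite::write_json(as_report_list(report), p("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' Flatten an experiment report into plain lists (for JSON output)
#'
#' @param report An `ad_experiment`.
#' @return A nested list of plain numbers/strings.
#' @export
as_report_list <- function(report) {
  ev <- lapply(report$evaluations, function(e) {
    m <- e$metrics
    list(auc = e$auc, accuracy = m$accuracy, sensitivity = m$sensitivity,
         specificity = m$specificity,
         precision_AD = m$precision[["AD"]], f1_AD = m$f1[["AD"]],
         counts = list(TP = m$counts$TP, TN = m$counts$TN,
                       FP = m$counts$FP, FN = m$counts$FN))
  })
  list(
    cv = list(fold_auc = report$cv$fold_auc, mean = report$cv$mean,
              sd = report$cv$sd),
    evaluations = ev,
    validation_gap = report$validation_gap,
    mean_validation_auc = report$mean_validation_auc,
    top_coefficients = utils::head(report$coefficient_ranking, 15L),
    provenance = report$provenance
  )
}

#' @export
print.ad_experiment <- function(x, ...) {
  cat("Percentile-profile AD classification experiment\n")
  cat(sprintf("  normative reference: n = %d\n", x$normative$n_ref))
  cat(sprintf("  split: train %d / validation %d / test %d (seed %d)\n",
              length(x$split$train), length(x$split$validation),
              length(x$split$test), x$provenance$seed))
  cat(sprintf("  training CV AUC: %.3f +/- %.3f\n", x$cv$mean, x$cv$sd))
  for (nm in names(x$evaluations)) {
    e <- x$evaluations[[nm]]
    cat(sprintf("  %-10s AUC %.3f, accuracy %.3f, sensitivity %s, specificity %s\n",
                nm, e$auc, e$metrics$accuracy,
                format(round(e$metrics$sensitivity, 3L)),
                format(round(e$metrics$specificity, 3L))))
  }
  if (!is.na(x$validation_gap)) {
    cat(sprintf("  validation gap %.3f, mean validation AUC %.3f\n",
                x$validation_gap, x$mean_validation_auc))
  }
  top <- utils::head(x$coefficient_ranking, 5L)
  cat("  top coefficients:",
      paste(sprintf("%s (%+.2f)", top$region, top$coefficient),
            collapse = ", "), "\n")
  invisible(x)
}
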