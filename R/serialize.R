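# Flat key-value text serialization for fitted models.
#
# Format (version 1): UTF-8 lines "key<TAB>value". Scalar metadata first,
# then per-region lines keyed "region<TAB>name<TAB>field<TAB>value".
# Numbers are written with 17 significant digits so load(save(m)) is exact.

.fmt_num <- function(x) sprintf("%.17g", x)

#' Save a normative model as diffable text
#'
#' @param model A `normative_model`.
#' @param path Output path.
#' @export
write_normative_model <- function(model, path) {
  stopifnot(inherits(model, "normative_model"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "format\tvolpct_normative_model",
    "version\t1",
    paste0("n_ref\t", model$n_ref),
    paste0("age_low\t", .fmt_num(model$age_range[1L])),
    paste0("age_high\t", .fmt_num(model$age_range[2L])),
    paste0("n_regions\t", length(model$regions))
  ), con)
  b <- model$coefficients
  for (i in seq_along(model$regions)) {
    r <- model$regions[i]
    writeLines(sprintf("region\t%s\t%s\t%s\t%s\t%s", r,
                       .fmt_num(b[i, "beta0"]), .fmt_num(b[i, "beta1"]),
                       .fmt_num(b[i, "beta2"]), .fmt_num(model$sigma[i])),
               con)
  }
  invisible(path)
}

#' Load a normative model saved by [write_normative_model()]
#'
#' @param path Input path.
#' @return A `normative_model`.
#' @export
read_normative_model <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, character(1L), 1L)
  if (fields[[1L]][2L] != "volpct_normative_model") {
    stop("not a normative model file: ", path)
  }
  meta <- function(k) fields[[which(key == k)[1L]]][2L]
  reg <- fields[key == "region"]
  regions <- vapply(reg, `[[`, character(1L), 2L)
  num <- function(j) vapply(reg, function(f) as.numeric(f[[j]]), numeric(1L))
  coefs <- cbind(beta0 = num(3L), beta1 = num(4L), beta2 = num(5L))
  rownames(coefs) <- regions
  normative_model(coefs, stats::setNames(num(6L), regions),
                  n_ref = as.integer(meta("n_ref")),
                  age_range = c(as.numeric(meta("age_low")),
                                as.numeric(meta("age_high"))))
}

#' Save a fitted percentile classifier as diffable text
#'
#' Stores the intercept, per-region coefficients, the frozen training
#' scaler and the class weights — everything needed to reproduce
#' predictions exactly.
#'
#' @param model An `ad_classifier`.
#' @param path Output path.
#' @export
write_classifier <- function(model, path) {
  stopifnot(inherits(model, "ad_classifier"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    "format\tvolpct_classifier",
    "version\t1",
    paste0("positive\t", model$positive),
    paste0("negative\t", model$negative),
    paste0("C\t", .fmt_num(model$C)),
    paste0("intercept\t", .fmt_num(model$intercept)),
    paste0("n_train\t", model$n_train),
    paste0("seed\t", model$seed),
    sprintf("weight\t%s\t%s", names(model$class_weights),
            .fmt_num(model$class_weights)),
    paste0("n_regions\t", length(model$regions))
  ), con)
  for (i in seq_along(model$regions)) {
    writeLines(sprintf("region\t%s\t%s\t%s\t%s", model$regions[i],
                       .fmt_num(model$coefficients[i]),
                       .fmt_num(model$scaler$center[i]),
                       .fmt_num(model$scaler$scale[i])),
               con)
  }
  invisible(path)
}

#' Load a classifier saved by [write_classifier()]
#'
#' @param path Input path.
#' @return An `ad_classifier`.
#' @export
read_classifier <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  key <- vapply(fields, `[[`, character(1L), 1L)
  if (fields[[1L]][2L] != "volpct_classifier") {
    stop("not a classifier file: ", path)
  }
  meta <- function(k) fields[[which(key == k)[1L]]][2L]
  wts <- fields[key == "weight"]
  weights <- stats::setNames(
    vapply(wts, function(f) as.numeric(f[[3L]]), numeric(1L)),
    vapply(wts, `[[`, character(1L), 2L)
  )
  reg <- fields[key == "region"]
  regions <- vapply(reg, `[[`, character(1L), 2L)
  num <- function(j) stats::setNames(
    vapply(reg, function(f) as.numeric(f[[j]]), numeric(1L)), regions)
  structure(
    list(intercept = as.numeric(meta("intercept")),
         coefficients = num(3L),
         scaler = structure(list(center = num(4L), scale = num(5L)),
                            class = "feature_scaler"),
         class_weights = weights, regions = regions,
         C = as.numeric(meta("C")), positive = meta("positive"),
         negative = meta("negative"), converged = TRUE,
         iterations = NA_integer_, grad_norm = NA_real_,
         seed = as.integer(meta("seed")),
         n_train = as.integer(meta("n_train"))),
    class = "ad_classifier"
  )
}
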