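# AD-vs-CN classification on percentile profiles.
#
# Protocol: stratified 60/20/20 split; feature standardization with mean/SD
# from the training split only; class weights w_class = N / (2 * N_class);
# ridge-penalized logistic regression minimizing
#   (1/(2C)) * ||beta||^2  +  sum_i w_i * log(1 + exp(-y_i * eta_i)),
# y_i in {-1, +1}, eta_i = beta0 + x_i' beta, intercept unpenalized,
# C = 1.0 by default. Fitting is exact Newton with step-halving; the
# problem is strictly convex for C < Inf.

#' Stratified train/validation/test split
#'
#' Splits subjects into train/validation/test preserving the class mix.
#' Allocation is sequential: the training split takes
#' `floor(ratios[1] * N)` subjects overall; within each split, per-class
#' counts follow largest-remainder rounding of the remaining class pool
#' (ties to the earlier class in lexicographic label order), and the last
#' split takes the remainder. Membership is randomized within class by the
#' seed; the counts are deterministic. For 873 subjects (183 AD / 690 CN)
#' at 60/20/20 this yields totals 523/175/175 with 110/37/36 AD.
#'
#' @param table A [volume_table()] (or data.frame with `subject_id` and
#'   `diagnosis` columns) restricted to the two diagnostic classes.
#' @param ratios Numeric length 3, positive, summing to 1.
#' @param seed Integer seed for the within-class shuffle.
#' @return An object of class `split_spec`: list with character-vector
#'   components `train`, `validation`, `test` (subject ids), plus `ratios`
#'   and `seed`.
#' @export
stratified_split <- function(table, ratios = c(0.6, 0.2, 0.2), seed = 42L) {
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop("ratios must be 3 positive numbers summing to 1")
  }
  ids <- as.character(table$subject_id)
  cls <- as.character(table$diagnosis)
  classes <- sort(unique(cls))
  if (min(table(cls)) < 5L) stop("need at least 5 subjects per class")

  set.seed(seed)
  pool <- lapply(classes, function(k) sample(ids[cls == k]))
  names(pool) <- classes

  n_splits <- length(ratios)
  out <- vector("list", n_splits)
  remaining_ratio <- sum(ratios)
  for (s in seq_len(n_splits)) {
    pool_sizes <- vapply(pool, length, integer(1L))
    n_pool <- sum(pool_sizes)
    if (s == n_splits) {
      take_total <- n_pool
    } else {
      take_total <- floor(ratios[s] / remaining_ratio * n_pool)
    }
    # largest-remainder class allocation within this split
    quota <- take_total * pool_sizes / n_pool
    take <- floor(quota)
    short <- take_total - sum(take)
    if (short > 0L) {
      frac <- quota - take
      order_idx <- order(-frac, seq_along(frac))  # ties -> earlier class
      take[order_idx[seq_len(short)]] <- take[order_idx[seq_len(short)]] + 1L
    }
    out[[s]] <- unlist(lapply(classes, function(k) {
      k_take <- take[[k]]
      head_ids <- utils::head(pool[[k]], k_take)
      pool[[k]] <<- utils::tail(pool[[k]], length(pool[[k]]) - k_take)
      head_ids
    }), use.names = FALSE)
    if (is.null(out[[s]])) out[[s]] <- character(0)
    remaining_ratio <- remaining_ratio - ratios[s]
  }
  structure(list(train = out[[1L]], validation = out[[2L]], test = out[[3L]],
                 ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("Stratified split (seed %d): train %d / validation %d / test %d\n",
              x$seed, length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Fit a feature scaler on the training split
#'
#' Per-column mean and SD (`n - 1` denominator), computed once on the
#' training feature matrix and then frozen: validation/test/external data
#' are transformed with these training statistics, never their own.
#'
#' @param features Numeric matrix (rows = training subjects, columns =
#'   regions).
#' @return An object of class `feature_scaler` with `center` and `scale`.
#' @export
fit_scaler <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("need at least 2 rows to fit a scaler")
  center <- colMeans(features)
  scale_ <- apply(features, 2L, stats::sd)
  if (any(scale_ <= 0 | !is.finite(scale_))) {
    bad <- colnames(features)[scale_ <= 0 | !is.finite(scale_)]
    stop("constant feature column(s): ", paste(bad, collapse = ", "))
  }
  structure(list(center = center, scale = scale_), class = "feature_scaler")
}

#' Apply a frozen feature scaler
#'
#' @param object A `feature_scaler`.
#' @param newdata Numeric matrix with the same columns the scaler was fit
#'   on.
#' @param ... Unused.
#' @return Standardized matrix `(x - center) / scale`.
#' @export
predict.feature_scaler <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$center)) {
    stop("column count does not match the fitted scaler")
  }
  sweep(sweep(newdata, 2L, object$center, "-"), 2L, object$scale, "/")
}

#' Inverse-frequency class weights
#'
#' `w_class = N / (2 * N_class)`, so each class contributes half of the
#' total effective weight: `sum_class w_class * N_class = N`.
#'
#' @param labels Character vector of diagnosis labels with exactly two
#'   distinct values (canonically `"AD"`/`"CN"`).
#' @return Named numeric vector of per-class weights.
#' @export
class_weights <- function(labels) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) != 2L) stop("class weights require exactly 2 classes")
  w <- length(labels) / (2 * as.numeric(tab))
  names(w) <- names(tab)
  w
}

# log(1 + exp(-t)), numerically stable for large |t|
.log1pexp_neg <- function(t) {
  ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t)))
}

# Weighted ridge logistic objective/gradient; X has no intercept column,
# b = c(intercept, beta). Intercept unpenalized.
.logit_objective <- function(b, X, y, w, C) {
  eta <- b[1L] + drop(X %*% b[-1L])
  sum(w * .log1pexp_neg(y * eta)) + sum(b[-1L]^2) / (2 * C)
}

.logit_gradient <- function(b, X, y, w, C) {
  eta <- b[1L] + drop(X %*% b[-1L])
  # d/deta log(1+exp(-y*eta)) = -y * sigma(-y*eta)
  g_eta <- -y * w * stats::plogis(-y * eta)
  c(sum(g_eta), drop(crossprod(X, g_eta)) + b[-1L] / C)
}

#' Fit the ridge-penalized weighted logistic model
#'
#' Minimizes `(1/(2C)) ||beta||^2 + sum_i w_i log(1 + exp(-y_i eta_i))`
#' with unpenalized intercept by damped Newton iteration, stopping when the
#' max-norm of the gradient falls below `tol`. Features are expected to be
#' standardized already (see [fit_scaler()]); labels `positive` map to
#' y = +1.
#'
#' @param features Standardized numeric matrix (n x p).
#' @param labels Character vector of length n with two classes.
#' @param weights Named per-class weights (default [class_weights()] of
#'   `labels`); may also be `c(...)` with one entry per class.
#' @param C Regularization strength; the penalty weight is `1/C`.
#' @param max_iter Maximum Newton iterations.
#' @param tol Gradient max-norm convergence tolerance.
#' @param positive Label of the positive class (default `"AD"`).
#' @return List with `intercept`, `coefficients` (named by column),
#'   `converged`, `iterations`, `grad_norm`.
#' @export
train_logistic <- function(features, labels, weights = NULL, C = 1.0,
                           max_iter = 1000L, tol = 1e-6, positive = "AD") {
  X <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  if (length(unique(labels)) != 2L) {
    stop("training labels must contain exactly 2 classes")
  }
  if (is.null(weights)) weights <- class_weights(labels)
  y <- ifelse(labels == positive, 1, -1)
  w <- unname(weights[labels])
  if (any(is.na(w))) stop("weights must be named by class label")

  p <- ncol(X)
  b <- numeric(p + 1L)
  pen <- c(0, rep(1 / C, p))
  converged <- FALSE
  iter <- 0L
  g <- .logit_gradient(b, X, y, w, C)
  f <- .logit_objective(b, X, y, w, C)
  while (iter < max_iter) {
    if (max(abs(g)) <= tol) { converged <- TRUE; break }
    iter <- iter + 1L
    eta <- b[1L] + drop(X %*% b[-1L])
    mu <- stats::plogis(eta)
    d <- w * mu * (1 - mu)
    Xi <- cbind(1, X)
    H <- crossprod(Xi, Xi * d)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # damped update: halve until the objective decreases
    lam <- 1
    repeat {
      b_new <- b - lam * step
      f_new <- .logit_objective(b_new, X, y, w, C)
      if (f_new <= f + 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    b <- b_new
    f <- f_new
    g <- .logit_gradient(b, X, y, w, C)
  }
  if (!converged && max(abs(g)) <= tol) converged <- TRUE
  if (!converged) {
    warning(sprintf("logistic fit did not reach tol: gradient max-norm %.3e after %d iterations",
                    max(abs(g)), iter))
  }
  beta <- unname(b[-1L])
  names(beta) <- colnames(X)
  list(intercept = unname(b[1L]), coefficients = beta, converged = converged,
       iterations = iter, grad_norm = max(abs(g)))
}

#' Fit the percentile-profile AD classifier
#'
#' The user-level fitting function: takes raw percentile features and
#' diagnosis labels, fits the training scaler and inverse-frequency class
#' weights, and trains the ridge-penalized weighted logistic model. The
#' returned object carries the frozen scaler and weights, so predictions on
#' new cohorts involve no re-estimation of any kind.
#'
#' @param percentiles Numeric matrix of percentile scores (n x R), columns
#'   named by region in canonical order (see [percentile_scores()]).
#' @param diagnosis Character vector of labels (`"AD"`/`"CN"`).
#' @param C Regularization strength (default 1.0; penalty weight `1/C`).
#' @param max_iter Maximum optimizer iterations (default 1000).
#' @param tol Gradient convergence tolerance.
#' @param seed Integer seed (default 42), set before fitting; the Newton
#'   solver itself is deterministic, the seed is fixed for protocol-level
#'   reproducibility of any stochastic caller.
#' @param positive Positive class label (default `"AD"`).
#' @return Object of class `ad_classifier`: `intercept`, `coefficients`
#'   (per standardized feature unit), `scaler`, `class_weights`, `regions`,
#'   `C`, `positive`, plus convergence diagnostics.
#' @examples
#' cfg <- adni_like_config()
#' ref <- simulate_reference(cfg, seed = 1)
#' coh <- simulate_diagnostic(cfg, seed = 2)
#' nm <- fit_normative(ref)
#' P <- percentile_scores(nm, coh)
#' fit <- ad_classifier(P, coh$diagnosis)
#' fit
#' @export
ad_classifier <- function(percentiles, diagnosis, C = 1.0, max_iter = 1000L,
                          tol = 1e-6, seed = 42L, positive = "AD") {
  X <- as.matrix(percentiles)
  set.seed(seed)
  scaler <- fit_scaler(X)
  weights <- class_weights(diagnosis)
  fit <- train_logistic(predict(scaler, X), diagnosis, weights = weights,
                        C = C, max_iter = max_iter, tol = tol,
                        positive = positive)
  structure(
    list(intercept = fit$intercept, coefficients = fit$coefficients,
         scaler = scaler, class_weights = weights,
         regions = colnames(X), C = C, positive = positive,
         negative = setdiff(names(weights), positive),
         converged = fit$converged, iterations = fit$iterations,
         grad_norm = fit$grad_norm, seed = as.integer(seed),
         n_train = nrow(X)),
    class = "ad_classifier"
  )
}

#' @export
print.ad_classifier <- function(x, ...) {
  cat(sprintf("Percentile-profile logistic classifier (%s vs %s)\n",
              x$positive, x$negative))
  cat(sprintf("  %d features, n_train = %d, C = %g, %s in %d iteration(s)\n",
              length(x$coefficients), x$n_train, x$C,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%s=%.4f", names(x$class_weights),
                            x$class_weights), collapse = ", ")))
  invisible(x)
}

#' @export
coef.ad_classifier <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
summary.ad_classifier <- function(object, ...) {
  print(object)
  top <- rank_coefficients(object)
  cat("  strongest coefficients (|beta|, standardized units):\n")
  for (i in seq_len(min(6L, nrow(top)))) {
    cat(sprintf("    %-38s %+.3f\n", top$region[i], top$coefficient[i]))
  }
  invisible(object)
}

#' Predict AD probabilities or labels for raw percentile features
#'
#' Applies the model's frozen training scaler, then the logistic formula
#' `1 / (1 + exp(-(beta0 + x' beta)))`.
#'
#' @param object An `ad_classifier`.
#' @param percentiles Numeric matrix with the model's feature columns
#'   (canonical region order or named columns that resolve to it).
#' @param type `"response"` for probabilities, `"class"` for labels at
#'   `threshold`.
#' @param threshold Decision threshold for `type = "class"`; probability
#'   greater than or equal to the threshold classifies as the positive
#'   class.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1), or character labels.
#' @export
predict.ad_classifier <- function(object, percentiles,
                                  type = c("response", "class"),
                                  threshold = 0.5, ...) {
  type <- match.arg(type)
  X <- as.matrix(percentiles)
  if (!is.null(colnames(X))) {
    idx <- match(region_key(object$regions), region_key(colnames(X)))
    if (anyNA(idx)) {
      stop("feature column(s) missing: ",
           paste(object$regions[is.na(idx)], collapse = ", "))
    }
    X <- X[, idx, drop = FALSE]
  } else if (ncol(X) != length(object$regions)) {
    stop("feature count does not match the model")
  }
  Z <- predict(object$scaler, X)
  eta <- object$intercept + drop(Z %*% object$coefficients)
  prob <- stats::plogis(eta)
  names(prob) <- rownames(X)
  if (type == "response") return(prob)
  classify_labels(prob, threshold = threshold, positive = object$positive,
                  negative = object$negative)
}

#' Threshold probabilities into class labels
#'
#' A probability exactly at the threshold classifies as the positive class
#' (documented tie rule).
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @param positive,negative Labels to emit.
#' @return Character vector of labels.
#' @export
classify_labels <- function(probabilities, threshold = 0.5,
                            positive = "AD", negative = "CN") {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  out <- ifelse(probabilities >= threshold, positive, negative)
  names(out) <- names(probabilities)
  out
}
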