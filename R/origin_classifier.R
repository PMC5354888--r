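# Cancer-type signature selection by per-region regression and tissue-of-
# origin classification by a diagonal-covariance Gaussian discriminant.

#' Score one region's association with the cancer-type label
#'
#' Fits, for each class, a one-vs-rest binomial logistic regression of class
#' membership on the region's copy-number value and computes a
#' likelihood-ratio p-value against the intercept-only model ((quasi-)
#' separated regions fall back to a Firth-penalized fit and are flagged).
#' The region-level p-value is the smallest per-class p-value with a
#' Bonferroni correction for the number of distinct one-vs-rest splits (for
#' two classes both splits are the same test, so no correction applies);
#' this keeps the region p-value uniformly distributed under the null.
#' A one-way ANOVA F-test is available as an alternative scorer
#' (`method = "anova"`); it is a single test, so no correction applies.
#'
#' @param values numeric vector of per-sample region values.
#' @param labels factor (or coercible) of cancer-type labels, >= 2 classes
#'   with >= 2 samples each.
#' @param method `"logistic"` (default) or `"anova"`.
#' @return a list with `p_value` (region-level), `per_class` (data.frame
#'   with `class`, `p_value`, `slope`, `separated`), `degenerate` (constant
#'   region, p = 1 by convention), and `method`.
#' @export
score_region_association <- function(values, labels,
                                     method = c("logistic", "anova")) {
  method <- match.arg(method)
  labels <- droplevels(as.factor(labels))
  if (length(values) != length(labels))
    stopf("values and labels differ in length")
  if (any(!is.finite(values))) stopf("region values must be finite")
  k <- nlevels(labels)
  if (k < 2) stopf("need at least two classes")
  if (any(tabulate(labels) < 2)) stopf("every class needs >= 2 samples")
  classes <- levels(labels)
  per_class <- data.frame(class = classes, p_value = 1, slope = 0,
                          separated = FALSE, stringsAsFactors = FALSE)
  if (length(unique(values)) < 2) {
    return(list(p_value = 1, per_class = per_class, degenerate = TRUE,
                method = method))
  }
  if (method == "anova") {
    f <- anova_f_test(values, labels)
    means <- tapply(values, labels, mean)
    per_class$p_value <- f$p_value
    per_class$slope <- as.numeric(means - mean(values))
    return(list(p_value = f$p_value, per_class = per_class,
                degenerate = FALSE, method = method))
  }
  m_tests <- if (k == 2) 1L else k
  fit_class <- function(cls) logistic_lrt(values, labels == cls)
  if (k == 2) {
    f <- fit_class(classes[1])
    per_class$p_value <- f$p_value
    per_class$slope <- c(f$slope, -f$slope)
    per_class$separated <- f$separated
  } else {
    for (i in seq_along(classes)) {
      f <- fit_class(classes[i])
      per_class$p_value[i] <- f$p_value
      per_class$slope[i] <- f$slope
      per_class$separated[i] <- f$separated
    }
  }
  p_region <- min(1, m_tests * min(per_class$p_value))
  p_region <- max(p_region, 1e-320)  # keep strictly > 0
  list(p_value = p_region, per_class = per_class, degenerate = FALSE,
       method = method)
}

#' Select cancer-type-specific CNV signature regions
#'
#' Scores every region of a labelled region matrix with
#' [score_region_association()] and selects those with p strictly below
#' `alpha` (default 1e-12). Deterministic given its inputs.
#'
#' @param x a labelled `region_matrix` (see [fill_matrix()]).
#' @param alpha selection cutoff on the region p-value (strict `<`).
#' @param method association scorer, see [score_region_association()].
#' @return an object of class `signature_set`: list with `index` (selected
#'   region row indices), `regions` (selected regions with `p_value`),
#'   `p_values` (all regions), `per_class_slope` (selected x class matrix),
#'   `alpha`, `method`, `n_regions`, `classes`.
#' @export
select_signatures <- function(x, alpha = 1e-12,
                              method = c("logistic", "anova")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "region_matrix"))
  if (is.null(x$labels))
    stopf("region matrix carries no class labels; supply labels to fill_matrix()")
  if (!(alpha >= 0)) stopf("alpha must be >= 0")
  labels <- droplevels(as.factor(x$labels))
  n_regions <- nrow(x$regions)
  p_values <- rep(1, n_regions)
  slopes <- matrix(0, n_regions, nlevels(labels),
                   dimnames = list(NULL, levels(labels)))
  for (r in seq_len(n_regions)) {
    sc <- score_region_association(x$values[r, ], labels, method = method)
    p_values[r] <- sc$p_value
    slopes[r, ] <- sc$per_class$slope
  }
  index <- which(p_values < alpha)
  regions <- x$regions[index, , drop = FALSE]
  regions$p_value <- p_values[index]
  rownames(regions) <- NULL
  if (length(index) == 0)
    warnf("no region passed the p < %g cutoff; downstream training will refuse",
          alpha)
  structure(list(index = index, regions = regions, p_values = p_values,
                 per_class_slope = slopes[index, , drop = FALSE],
                 alpha = alpha, method = method, n_regions = n_regions,
                 classes = levels(labels)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("Signature set: %d of %d regions at p < %g (%s scorer)\n",
              length(x$index), x$n_regions, x$alpha, x$method))
  invisible(x)
}

#' Train a diagonal-covariance Gaussian discriminant model
#'
#' Per-class feature means with a single pooled per-feature variance
#' (floored at `var_floor`), i.e. diagonal linear discriminant analysis.
#' The diagonal form is the workable choice when selected features far
#' outnumber samples, where a full pooled covariance is singular; a
#' full-covariance mode (`covariance = "full"`) is offered for the classical
#' small-feature setting and refuses to run when features >= samples.
#'
#' @param x either a labelled `region_matrix` (trained on the rows named by
#'   `signatures`) or a samples x features numeric matrix.
#' @param signatures a [select_signatures()] result (required when `x` is a
#'   `region_matrix`); must be non-empty.
#' @param labels class labels per sample (taken from `x$labels` when `x` is
#'   a labelled `region_matrix`).
#' @param priors `"empirical"` (class frequencies, default), `"uniform"`, or
#'   a named numeric vector summing to 1.
#' @param var_floor lower bound for pooled per-feature variances
#'   (default 1e-6), keeping scores finite for features constant in
#'   training.
#' @param covariance `"diagonal"` (default) or `"full"`.
#' @return an object of class `discriminant_model`.
#' @export
train_discriminant <- function(x, signatures = NULL, labels = NULL,
                               priors = "empirical", var_floor = 1e-6,
                               covariance = c("diagonal", "full")) {
  covariance <- match.arg(covariance)
  if (inherits(x, "region_matrix")) {
    if (is.null(labels)) labels <- x$labels
    if (is.null(labels)) stopf("region matrix carries no class labels")
    if (is.null(signatures))
      stopf("training on a region_matrix requires a signature_set")
    if (length(signatures$index) == 0)
      stopf("empty signature set: no regions selected; refusing to train")
    feat <- t(x$values[signatures$index, , drop = FALSE])
  } else {
    feat <- as.matrix(x)
    if (is.null(labels)) stopf("labels are required")
  }
  if (is.null(colnames(feat)))
    colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stopf("need at least two classes")
  counts <- table(labels)
  if (any(counts < 2))
    stopf("class '%s' has fewer than 2 samples", names(counts)[counts < 2][1])
  if (!(var_floor > 0)) stopf("var_floor must be > 0")
  classes <- levels(labels)
  p <- ncol(feat); n <- nrow(feat)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(feat[labels == cl, , drop = FALSE])))
  rownames(means) <- classes
  centered <- feat - means[as.integer(labels), , drop = FALSE]
  if (covariance == "full") {
    if (p >= n)
      stopf("full-covariance mode needs features < samples (%d >= %d)", p, n)
    sigma <- crossprod(centered) / (n - length(classes))
    diag(sigma) <- pmax(diag(sigma), var_floor)
    pooled_var <- diag(sigma)
  } else {
    sigma <- NULL
    pooled_var <- pmax(colSums(centered^2) / (n - length(classes)), var_floor)
  }
  pr <- if (identical(priors, "empirical")) as.numeric(counts) / n
        else if (identical(priors, "uniform")) rep(1 / length(classes),
                                                   length(classes))
        else {
          if (is.null(names(priors)) || !setequal(names(priors), classes))
            stopf("numeric priors must be named by class")
          as.numeric(priors[classes])
        }
  if (abs(sum(pr) - 1) > 1e-8) stopf("priors must sum to 1")
  names(pr) <- classes
  structure(list(classes = classes, means = means, pooled_var = pooled_var,
                 sigma = sigma, priors = pr, covariance = covariance,
                 var_floor = var_floor, feature_names = colnames(feat),
                 n_train = n),
            class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf("Discriminant model (%s covariance): %d classes, %d features, %d training samples\n",
              x$covariance, length(x$classes), length(x$feature_names),
              x$n_train))
  cat("  priors:", paste(sprintf("%s=%.3f", x$classes, x$priors),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Classify samples with a discriminant model
#'
#' Scores each sample against each class as log prior plus the sum of
#' per-feature Gaussian log-densities and predicts the argmax. Exact score
#' ties are broken by class label order and flagged.
#'
#' @param model a [train_discriminant()] model.
#' @param newdata a samples x features matrix whose columns cover the
#'   model's features (matched by name when named), or a `region_matrix` /
#'   projected value matrix with regions as rows (rows matched by
#'   `chrom:start-end` key).
#' @return a list with `class` (predicted label per sample), `scores`
#'   (samples x classes log-score matrix), `tie` (logical per sample).
#' @export
classify <- function(model, newdata) {
  stopifnot(inherits(model, "discriminant_model"))
  feat <- extract_features(model, newdata)
  n <- nrow(feat)
  scores <- matrix(NA_real_, n, length(model$classes),
                   dimnames = list(rownames(feat), model$classes))
  if (model$covariance == "full") {
    sig_inv <- solve(model$sigma)
    logdet <- determinant(model$sigma, logarithm = TRUE)$modulus
    for (ci in seq_along(model$classes)) {
      d <- feat - matrix(model$means[ci, ], n, ncol(feat), byrow = TRUE)
      q <- rowSums((d %*% sig_inv) * d)
      scores[, ci] <- log(model$priors[ci]) - 0.5 * q -
        0.5 * as.numeric(logdet) - 0.5 * ncol(feat) * log(2 * pi)
    }
  } else {
    v <- model$pooled_var
    const <- -0.5 * sum(log(2 * pi * v))
    for (ci in seq_along(model$classes)) {
      d <- feat - matrix(model$means[ci, ], n, ncol(feat), byrow = TRUE)
      scores[, ci] <- log(model$priors[ci]) + const -
        0.5 * rowSums((d * d) / matrix(v, n, ncol(feat), byrow = TRUE))
    }
  }
  if (anyNA(scores)) stopf("missing feature values after fill")
  best <- max.col(scores, ties.method = "first")
  tie <- vapply(seq_len(n), function(i)
    sum(scores[i, ] == max(scores[i, ])) > 1, TRUE)
  list(class = model$classes[best], scores = scores, tie = tie)
}

# Align newdata columns with the model's features. Accepts a samples x
# features matrix (columns matched by name when named) or a region_matrix /
# region x sample matrix (rows keyed by chrom:start-end).
extract_features <- function(model, newdata) {
  fn <- model$feature_names
  if (inherits(newdata, "region_matrix")) newdata <- newdata$values
  m <- as.matrix(newdata)
  if (!is.null(rownames(m)) && all(fn %in% rownames(m)))
    return(t(m[fn, , drop = FALSE]))
  if (!is.null(colnames(m)) && all(fn %in% colnames(m)))
    return(m[, fn, drop = FALSE])
  if (ncol(m) == length(fn)) {
    colnames(m) <- fn
    return(m)
  }
  stopf("newdata does not provide the model's %d features", length(fn))
}

#' Cross-validated (or resubstitution) classification accuracy
#'
#' Stratified k-fold cross-validation of the full pipeline: signature
#' selection is re-run inside every training fold (no leakage of the
#' held-out samples into selection), a discriminant model is trained on the
#' fold's selected regions, and held-out samples are scored. The confusion
#' matrix (true class x predicted class) and per-class accuracy (recall) are
#' aggregated over folds. `mode = "resubstitution"` instead selects, trains
#' and evaluates on the full matrix, the optimistic protocol sometimes
#' reported with discriminant analyses.
#'
#' @param x a labelled `region_matrix`.
#' @param alpha signature selection cutoff.
#' @param k number of folds (default 5); every class needs >= k samples.
#' @param seed integer seed for the stratified fold assignment (required for
#'   `mode = "cv"`).
#' @param mode `"cv"` (default) or `"resubstitution"`.
#' @param method association scorer.
#' @param priors,var_floor passed to [train_discriminant()].
#' @return an object of class `classification_report`: list with
#'   `confusion`, `per_class_accuracy`, `overall_accuracy`, `predictions`
#'   (data.frame sample/truth/predicted/fold), `n_signatures` (per fold),
#'   `mode`, `alpha`, `k`, `seed`.
#' @export
cross_validate <- function(x, alpha = 1e-12, k = 5, seed = NULL,
                           mode = c("cv", "resubstitution"),
                           method = c("logistic", "anova"),
                           priors = "empirical", var_floor = 1e-6) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  stopifnot(inherits(x, "region_matrix"))
  if (is.null(x$labels)) stopf("region matrix carries no class labels")
  labels <- droplevels(as.factor(x$labels))
  classes <- levels(labels)
  samples <- x$samples
  if (mode == "resubstitution") {
    sig <- select_signatures(x, alpha = alpha, method = method)
    model <- train_discriminant(x, signatures = sig, priors = priors,
                                var_floor = var_floor)
    pred <- classify(model, t(x$values[sig$index, , drop = FALSE]))
    predictions <- data.frame(sample = samples, truth = as.character(labels),
                              predicted = pred$class, fold = 0L,
                              stringsAsFactors = FALSE)
    n_signatures <- length(sig$index)
  } else {
    if (!(k >= 2)) stopf("k must be >= 2")
    if (is.null(seed)) stopf("a seed is required for cross-validation")
    counts <- table(labels)
    small <- names(counts)[counts < k]
    if (length(small))
      stopf("class '%s' has fewer samples (%d) than folds (%d)",
            small[1], counts[small[1]], k)
    fold <- integer(length(labels))
    with_seed(seed, {
      for (cl in classes) {
        idx <- which(labels == cl)
        fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    })
    predictions <- data.frame(sample = samples, truth = as.character(labels),
                              predicted = NA_character_, fold = fold,
                              stringsAsFactors = FALSE)
    n_signatures <- integer(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      xt <- new_region_matrix(x$regions, samples[tr],
                              x$values[, tr, drop = FALSE],
                              labels = x$labels[tr], fill = x$fill)
      sig <- select_signatures(xt, alpha = alpha, method = method)
      if (length(sig$index) == 0)
        stopf("fold %d selected no signature regions at alpha = %g", f, alpha)
      model <- train_discriminant(xt, signatures = sig, priors = priors,
                                  var_floor = var_floor)
      pred <- classify(model, t(x$values[sig$index, !tr, drop = FALSE]))
      predictions$predicted[!tr] <- pred$class
      n_signatures[f] <- length(sig$index)
    }
  }
  confusion <- table(factor(predictions$truth, levels = classes),
                     factor(predictions$predicted, levels = classes),
                     dnn = c("truth", "predicted"))
  per_class <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion,
                 per_class_accuracy = per_class,
                 overall_accuracy = sum(diag(confusion)) / sum(confusion),
                 predictions = predictions, n_signatures = n_signatures,
                 mode = mode, alpha = alpha,
                 k = if (mode == "cv") k else NA_integer_, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Classification report (%s%s): overall accuracy %.3f\n",
              x$mode, if (x$mode == "cv") sprintf(", k = %d", x$k) else "",
              x$overall_accuracy))
  cat("  per-class accuracy:",
      paste(sprintf("%s=%.3f", names(x$per_class_accuracy),
                    x$per_class_accuracy), collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}
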