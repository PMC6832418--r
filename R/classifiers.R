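#' Describe a classifier
#'
#' Builds an (unfitted) classifier specification for one of the four model
#' families. Defaults follow the study configuration: a random forest of 50
#' trees with unrestricted terminal nodes; an RBF support vector machine
#' with gamma = 0.01 and C = 10 using one-against-one multiclass
#' decomposition; plain (unpenalized) multinomial logistic regression with
#' a reference class; standard linear discriminant analysis.
#'
#' @param family one of `"lda"`, `"lr"`, `"svm"`, `"rf"`.
#' @param n_trees random forest size (RF only).
#' @param gamma,cost RBF kernel width and soft-margin penalty (SVM only).
#' @param scale if `TRUE`, features are z-scored with the training means
#'   and standard deviations, and the same transform is applied at
#'   prediction. Off by default: the shape features are already bounded and
#'   the SVM gamma is stated for raw feature magnitudes.
#' @param seed integer seed controlling every stochastic step of fitting
#'   (bootstrap resampling and candidate-variable draws in RF).
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(family = c("rf", "lda", "lr", "svm"),
                            n_trees = 50L, gamma = 0.01, cost = 10,
                            scale = FALSE, seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family,
                 hyperparams = list(n_trees = as.integer(n_trees),
                                    gamma = gamma, cost = cost,
                                    scale = isTRUE(scale)),
                 seed = as.integer(seed),
                 fitted_state = NULL, feature_names = NULL,
                 class_levels = NULL, center = NULL, spread = NULL),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("classifier_spec: %s (%s)\n", toupper(x$family),
              if (is.null(x$fitted_state)) "unfitted" else
                sprintf("fitted on %d features, %d classes",
                        length(x$feature_names), length(x$class_levels))))
  invisible(x)
}

#' Balanced training sample
#'
#' Draws up to `per_class` rows per class uniformly without replacement, so
#' every class contributes approximately equally to training regardless of
#' its abundance in the scene.
#'
#' @param features feature matrix (rows = points).
#' @param labels integer class ids, one per row.
#' @param per_class target rows per class; classes with fewer points
#'   contribute all of them.
#' @param seed integer seed making the draw reproducible.
#' @return list with `features`, `labels` and the drawn row `indices`.
#' @export
balanced_sample <- function(features, labels, per_class, seed = 1L) {
  if (is.null(labels)) stop("labels are required for balanced sampling")
  stopifnot(per_class >= 1, length(labels) == nrow(features))
  idx <- local({
    set.seed(as.integer(seed))
    unlist(lapply(split(seq_along(labels), labels), function(rows)
      sample(rows, min(per_class, length(rows)))), use.names = FALSE)
  })
  idx <- sort(idx)
  list(features = features[idx, , drop = FALSE], labels = labels[idx],
       indices = idx)
}

#' Fit a classifier
#'
#' @param spec a [classifier_spec()].
#' @param features numeric feature matrix with column names.
#' @param labels integer class ids, one per row; at least two classes.
#' @return the spec with `fitted_state` populated.
#' @export
fit_classifier <- function(spec, features, labels) {
  stopifnot(inherits(spec, "classifier_spec"))
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("feature columns must be named")
  if (any(!is.finite(features))) stop("non-finite feature values")
  if (is.null(labels)) stop("training labels are missing")
  y <- factor(labels)
  if (nlevels(y) < 2L)
    stop("training set contains a single class; at least two are required")
  spec$feature_names <- colnames(features)
  spec$class_levels <- levels(y)
  if (spec$hyperparams$scale) {
    spec$center <- colMeans(features)
    spec$spread <- apply(features, 2, stats::sd)
    spec$spread[spec$spread == 0] <- 1
    features <- scale(features, spec$center, spec$spread)
  }
  df <- data.frame(features, check.names = FALSE)
  df$.class <- y
  spec$fitted_state <- switch(spec$family,
    lda = MASS::lda(.class ~ ., data = df),
    lr = nnet::multinom(.class ~ ., data = df, trace = FALSE,
                        decay = 0, maxit = 500,
                        MaxNWts = 10000),
    svm = e1071::svm(.class ~ ., data = df, kernel = "radial",
                     gamma = spec$hyperparams$gamma,
                     cost = spec$hyperparams$cost, scale = FALSE),
    rf = local({
      set.seed(spec$seed)
      randomForest::randomForest(features, y,
                                 ntree = spec$hyperparams$n_trees,
                                 nodesize = 1)
    }))
  spec
}

check_feature_columns <- function(spec, features) {
  if (is.null(spec$fitted_state)) stop("classifier is not fitted")
  got <- colnames(features)
  if (!identical(got, spec$feature_names)) {
    bad <- union(setdiff(got, spec$feature_names),
                 setdiff(spec$feature_names, got))
    stop("feature columns do not match the fitted model: ",
         paste(bad, collapse = ", "))
  }
}

#' Predict class ids
#'
#' @param object a fitted [classifier_spec()].
#' @param features feature matrix whose columns match the ones bound at
#'   fit time.
#' @param ... unused.
#' @return integer class ids (on the training label coding), one per row.
#' @export
predict.classifier_spec <- function(object, features, ...) {
  features <- as.matrix(features)
  check_feature_columns(object, features)
  if (object$hyperparams$scale)
    features <- scale(features, object$center, object$spread)
  df <- data.frame(features, check.names = FALSE)
  cls <- switch(object$family,
    lda = predict(object$fitted_state, df)$class,
    lr = predict(object$fitted_state, df, type = "class"),
    svm = predict(object$fitted_state, df),
    rf = predict(object$fitted_state, features))
  as.integer(as.character(cls))
}

#' Per-class membership probabilities
#'
#' Available for the probabilistic families (LDA posterior, multinomial
#' logistic softmax, random forest vote fractions); the SVM assigns classes
#' directly and carries no calibrated probabilities.
#'
#' @inheritParams predict.classifier_spec
#' @param spec a fitted [classifier_spec()].
#' @return numeric matrix, one row per point, columns named by class id;
#'   rows sum to 1.
#' @export
predict_prob <- function(spec, features) {
  features <- as.matrix(features)
  check_feature_columns(spec, features)
  if (spec$family == "svm")
    stop("the SVM family does not provide class probabilities")
  if (spec$hyperparams$scale)
    features <- scale(features, spec$center, spec$spread)
  df <- data.frame(features, check.names = FALSE)
  p <- switch(spec$family,
    lda = predict(spec$fitted_state, df)$posterior,
    lr = {
      pr <- predict(spec$fitted_state, df, type = "probs")
      if (is.null(dim(pr)))  # two-class fit returns P(second level)
        pr <- cbind(1 - pr, pr)
      pr
    },
    rf = predict(spec$fitted_state, features, type = "prob"))
  p <- as.matrix(p)
  colnames(p) <- spec$class_levels
  p
}

#' Save / load a fitted classifier
#'
#' Single-file artifact embedding the family, hyperparameters, bound
#' feature names, seed and fitted state, with a format version tag.
#'
#' @param spec a fitted [classifier_spec()].
#' @param path file path.
#' @return `path` (save) or the restored spec (load).
#' @export
save_classifier <- function(spec, path) {
  stopifnot(inherits(spec, "classifier_spec"))
  saveRDS(list(format = "cloudclass-model-1", spec = spec), path)
  invisible(path)
}

#' @rdname save_classifier
#' @param path file path.
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cloudclass-model-1"))
    stop("not a cloudclass model file: ", path)
  obj$spec
}
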