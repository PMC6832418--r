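#' Confusion matrix
#'
#' Rows index the reference class, columns the predicted class, both in the
#' order of `classes`.
#'
#' @param reference integer class ids (ground truth).
#' @param predicted integer class ids (model output), same length.
#' @param classes class id order for rows/columns; defaults to the sorted
#'   union of the labels seen.
#' @return C x C integer matrix with `dimnames` set to the class ids.
#' @export
confusion_matrix <- function(reference, predicted,
                             classes = sort(unique(c(reference,
                                                     predicted)))) {
  if (length(reference) != length(predicted))
    stop("reference and predicted labels differ in length")
  unknown <- setdiff(unique(c(reference, predicted)), classes)
  if (length(unknown))
    stop("labels outside the class list: ", paste(unknown, collapse = ", "))
  f <- function(x) factor(x, levels = classes)
  cm <- table(reference = f(reference), predicted = f(predicted))
  matrix(as.integer(cm), nrow = length(classes),
         dimnames = list(reference = as.character(classes),
                         predicted = as.character(classes)))
}

#' One-vs-all precision, recall and F1 for one class
#'
#' The class is treated as positive and all others as negative:
#' TP = cm\[c, c\], FP = column sum - TP, FN = row sum - TP. Ratios with a
#' zero denominator are defined as 0 so per-class tables stay complete.
#'
#' @param cm a confusion matrix from [confusion_matrix()].
#' @param class class id (must appear in the matrix dimnames).
#' @return named numeric vector `c(precision, recall, f1)`.
#' @export
one_vs_all_metrics <- function(cm, class) {
  i <- match(as.character(class), rownames(cm))
  if (is.na(i)) stop("class not in confusion matrix: ", class)
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Overall accuracy
#' @param cm a confusion matrix.
#' @return fraction of points on the diagonal.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  stopifnot(total > 0)
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with the expected
#' agreement `p_e` taken from the product of row and column marginals. In
#' the degenerate case `p_e = 1` (all mass in one cell) kappa is defined
#' as 0.
#'
#' @param cm a confusion matrix.
#' @return kappa coefficient in \[-1, 1\].
#' @export
kappa_coefficient <- function(cm) {
  total <- sum(cm)
  stopifnot(total > 0)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) return(0)
  (po - pe) / (1 - pe)
}

#' Gini impurity of a class-fraction vector
#'
#' `G = 1 - sum(p^2)`, the CART split criterion: 0 for a pure node,
#' approaching 1 as classes mix evenly.
#'
#' @param class_fractions non-negative fractions summing to 1 (tolerance
#'   1e-9).
#' @return impurity in \[0, 1).
#' @export
gini_index <- function(class_fractions) {
  p <- as.numeric(class_fractions)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class fractions must be non-negative and sum to 1")
  1 - sum(p^2)
}

#' Variable importance from a fitted random forest
#'
#' Mean decrease in Gini impurity accumulated over all node splits using
#' each feature, averaged over the forest; larger values mean the feature
#' contributes more to class separation. Only the RF family exposes this.
#'
#' @param spec a fitted [classifier_spec()] with `family = "rf"`.
#' @return data frame with columns `feature` and `mean_gini_decrease`,
#'   sorted by decreasing importance, covering every feature bound at fit.
#' @export
importance_report <- function(spec) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (spec$family != "rf")
    stop("variable importance is only available for the RF family")
  if (is.null(spec$fitted_state)) stop("classifier is not fitted")
  imp <- randomForest::importance(spec$fitted_state,
                                  type = 2)[, "MeanDecreaseGini"]
  out <- data.frame(feature = names(imp), mean_gini_decrease = unname(imp))
  out <- out[order(-out$mean_gini_decrease), ]
  rownames(out) <- NULL
  out
}

#' Full evaluation report
#'
#' @param reference,predicted integer class ids.
#' @param classes class id order (see [confusion_matrix()]).
#' @param class_names optional named character vector id -> name for
#'   display.
#' @param importance optional importance table from [importance_report()].
#' @return an `evaluation_report`: list with `confusion`, `per_class`
#'   (data frame: class, precision, recall, f1), `overall_accuracy`,
#'   `kappa` and `importance`.
#' @export
evaluation_report <- function(reference, predicted, classes = NULL,
                              class_names = NULL, importance = NULL) {
  if (is.null(classes))
    classes <- sort(unique(c(reference, predicted)))
  cm <- confusion_matrix(reference, predicted, classes)
  per <- t(vapply(classes, function(cl) one_vs_all_metrics(cm, cl),
                  numeric(3)))
  nm <- if (is.null(class_names)) as.character(classes) else
    unname(class_names[as.character(classes)])
  per_class <- data.frame(class = classes, name = nm, per,
                          check.names = FALSE)
  structure(list(confusion = cm, per_class = per_class,
                 overall_accuracy = overall_accuracy(cm),
                 kappa = kappa_coefficient(cm),
                 importance = importance),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  cat("Per-class one-vs-all metrics:\n")
  tab <- x$per_class
  tab[c("precision", "recall", "f1")] <-
    round(tab[c("precision", "recall", "f1")], digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Overall accuracy: %.*f\nKappa: %.*f\n",
              digits, x$overall_accuracy, digits, x$kappa))
  if (!is.null(x$importance)) {
    cat("Top variables by mean Gini decrease:\n")
    print(head(x$importance, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Write an evaluation report
#'
#' CSV mirrors the per-class precision/recall/F1 table with overall
#' accuracy and kappa appended as rows; JSON carries the full report
#' including the confusion matrix.
#'
#' @param report an [evaluation_report()].
#' @param path output path; format chosen by extension (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    tab <- report$per_class
    extra <- data.frame(class = NA, name = c("Ov. Acc", "Kappa"),
                        precision = c(report$overall_accuracy,
                                      report$kappa),
                        recall = NA, f1 = NA)
    write.csv(rbind(tab, extra), path, row.names = FALSE)
  } else if (ext == "json") {
    jsonlite::write_json(list(
      per_class = report$per_class,
      overall_accuracy = report$overall_accuracy,
      kappa = report$kappa,
      confusion = list(classes = rownames(report$confusion),
                       counts = unclass(report$confusion)),
      importance = report$importance), path, auto_unbox = TRUE,
      digits = NA)
  } else stop("unsupported report format: .", ext)
  invisible(path)
}
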