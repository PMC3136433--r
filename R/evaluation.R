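# Evaluation: stratified k-fold CV, confusion statistics, ROC area.
# Convention for the metric panel (class-weighted rates, matching common
# toolkit reporting): weighted TPR = sum over classes of (support/total) *
# per-class recall (algebraically equal to accuracy/100); weighted FPR and
# ROC area are weighted the same way.

#' Confusion matrix
#'
#' @param tn,fp,fn,tp Non-negative integer cell counts; positive class = CPP.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  stopifnot(all(cells >= 0))
  structure(as.list(cells), total = sum(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2L, byrow = TRUE,
              dimnames = list(truth = c("NON_CPP", "CPP"),
                              predicted = c("NON_CPP", "CPP")))
  print(m)
  invisible(x)
}

.cm_from_labels <- function(truth, predicted) {
  confusion_matrix(tn = sum(truth == "NON_CPP" & predicted == "NON_CPP"),
                   fp = sum(truth == "NON_CPP" & predicted == "CPP"),
                   fn = sum(truth == "CPP" & predicted == "NON_CPP"),
                   tp = sum(truth == "CPP" & predicted == "CPP"))
}

#' Metric panel from a confusion matrix
#'
#' Accuracy (percent), per-class accuracies, and class-weighted true/false
#' positive rates. ROC area requires decision values and is `NA` here; see
#' [cross_validate()] / [evaluate_on()].
#'
#' @param cm A [confusion_matrix()].
#' @return Object of class `cpp_eval`.
#' @examples
#' confusion_stats(confusion_matrix(tn = 0, fp = 34, fn = 1, tp = 110))
#' @export
confusion_stats <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- attr(cm, "total")
  if (n == 0) stop("EmptyInput: empty confusion matrix", call. = FALSE)
  n_pos <- cm$tp + cm$fn
  n_neg <- cm$tn + cm$fp
  recall_pos <- if (n_pos > 0) cm$tp / n_pos else NA_real_
  recall_neg <- if (n_neg > 0) cm$tn / n_neg else NA_real_
  # FPR of the CPP class = negatives called CPP; FPR of NON_CPP symmetric
  fpr_pos <- if (n_neg > 0) cm$fp / n_neg else NA_real_
  fpr_neg <- if (n_pos > 0) cm$fn / n_pos else NA_real_
  w_pos <- n_pos / n
  w_neg <- n_neg / n
  structure(list(cm = cm,
                 accuracy = 100 * (cm$tp + cm$tn) / n,
                 cpp_accuracy = 100 * recall_pos,
                 noncpp_accuracy = 100 * recall_neg,
                 tpr = w_pos * recall_pos + w_neg * recall_neg,
                 fpr = w_pos * fpr_pos + w_neg * fpr_neg,
                 roc_area = NA_real_),
            class = "cpp_eval")
}

#' @export
print.cpp_eval <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat(sprintf("Accuracy            %.2f%%\n", x$accuracy))
  cat(sprintf("  CPP accuracy      %.2f%%\n", x$cpp_accuracy))
  cat(sprintf("  Non-CPP accuracy  %.2f%%\n", x$noncpp_accuracy))
  cat(sprintf("True Positive Rate  %s\n", fmt(x$tpr)))
  cat(sprintf("False Positive Rate %s\n", fmt(x$fpr)))
  cat(sprintf("ROC area            %s\n", fmt(x$roc_area)))
  invisible(x)
}

#' Majority-class baseline accuracy
#'
#' Accuracy obtained by predicting every example as the most frequent class;
#' the floor against which classifiers on imbalanced data must be judged.
#'
#' @param n_pos,n_neg Class sizes.
#' @return Percent accuracy.
#' @examples
#' majority_baseline(111, 34) # 76.55
#' @export
majority_baseline <- function(n_pos, n_neg) {
  if (n_pos + n_neg == 0) stop("EmptyInput: no examples", call. = FALSE)
  100 * max(n_pos, n_neg) / (n_pos + n_neg)
}

#' ROC area from decision values
#'
#' Rank-based (Mann-Whitney) area under the ROC curve for the positive class,
#' with ties counted half.
#'
#' @param truth Character labels (`"CPP"` / `"NON_CPP"`).
#' @param decision Numeric decision values, larger = more CPP-like.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, decision) {
  pos <- decision[truth == "CPP"]
  neg <- decision[truth == "NON_CPP"]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Class-weighted ROC area: weight each class's one-vs-rest AUC by support.
.weighted_auc <- function(truth, decision) {
  auc_pos <- roc_auc(truth, decision)
  # the NON_CPP-as-positive AUC uses negated decisions; by rank symmetry it
  # equals auc_pos, but compute it explicitly for clarity
  auc_neg <- roc_auc(ifelse(truth == "CPP", "NON_CPP", "CPP"), -decision)
  w <- mean(truth == "CPP")
  w * auc_pos + (1 - w) * auc_neg
}

# Stratified fold assignment: shuffle within class, deal round-robin.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the PUK-SVM
#'
#' Splits the dataset into `k` stratified folds; for each fold fits the
#' normalizer and the PUK-SVM on the training rows only and predicts the
#' held-out rows. Out-of-fold predictions are pooled into one confusion
#' matrix; the ROC area is the class-weighted AUC of the pooled decision
#' values.
#'
#' @param dataset A `cpp_dataset`.
#' @param k Number of folds.
#' @param seed Fold-assignment (and solver) seed.
#' @param features Feature subset (`NULL` = all 61).
#' @param C,omega,sigma SVM settings.
#' @return A `cpp_eval` with fields `accuracy`, `tpr`, `fpr`, `roc_area`,
#'   plus the pooled `cm`, `k` and `seed`.
#' @export
cross_validate <- function(dataset, k = 10L, seed = 1L, features = NULL,
                           C = 1, omega = 1, sigma = 1) {
  stopifnot(inherits(dataset, "cpp_dataset"), k >= 2L)
  if (is.null(features)) features <- colnames(dataset$x)
  labels <- dataset$labels
  if (k > min(table(labels))) {
    stop("StratificationError: k = ", k, " exceeds the minority class size (",
         min(table(labels)), ")", call. = FALSE)
  }
  rng <- .seeded_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  fold <- .stratified_folds(labels, k)
  x <- dataset$x[, features, drop = FALSE]
  y <- dataset_y(dataset)
  pred <- character(length(labels))
  dec <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    norm <- fit_normalizer(x[tr, , drop = FALSE])
    fit <- cpp_svm(apply_normalizer(norm, x[tr, , drop = FALSE]), y[tr],
                   C = C, omega = omega, sigma = sigma,
                   seed = seed + f)
    d <- decision_values(fit, apply_normalizer(norm, x[!tr, , drop = FALSE]))
    dec[!tr] <- d
    pred[!tr] <- ifelse(d > 0, "CPP", "NON_CPP")
  }
  out <- confusion_stats(.cm_from_labels(labels, pred))
  out$roc_area <- .weighted_auc(labels, dec)
  out$k <- k
  out$seed <- seed
  out$decision <- dec
  out$truth <- labels
  out
}

#' Evaluate a trained classifier on a dataset
#'
#' Single-pass evaluation (no refitting): predicts every row of `dataset`
#' with the trained classifier and reports the metric panel, with ROC area
#' from the decision values. Deterministic.
#'
#' @param object A [cpp_classifier()].
#' @param dataset A `cpp_dataset` carrying the same 61-descriptor space.
#' @return A `cpp_eval`.
#' @export
evaluate_on <- function(object, dataset) {
  stopifnot(inherits(object, "cpp_classifier"), inherits(dataset, "cpp_dataset"))
  dec <- predict(object, dataset, type = "decision")
  pred <- ifelse(dec > 0, "CPP", "NON_CPP")
  out <- confusion_stats(.cm_from_labels(dataset$labels, pred))
  out$roc_area <- .weighted_auc(dataset$labels, dec)
  out$decision <- dec
  out$truth <- dataset$labels
  out
}
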