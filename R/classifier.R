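# End-to-end classifier: descriptor subset + min-max normalization + PUK-SVM,
# the unit that is trained on a cpp_dataset and applied to raw peptides.

#' Train a CPP classifier on a dataset
#'
#' Fits the full classification stack on a [build_dataset()] result:
#' restricts to a feature subset, fits the min-max normalizer on the training
#' rows, and trains the PUK-SVM. The returned object predicts directly from
#' peptides or collections (descriptors are computed, normalized and
#' subset-restricted internally).
#'
#' @param dataset A `cpp_dataset`.
#' @param features Character vector of descriptor names (subset of
#'   [feature_names()]); `NULL` uses all 61.
#' @param C,omega,sigma,tol SVM and kernel settings, see [cpp_svm()].
#' @param seed Solver seed.
#' @return Object of class `cpp_classifier`.
#' @examples
#' d <- build_dataset("unbalanced")
#' m <- cpp_classifier(d, features = c("net_charge", "isoelectric_point"))
#' predict(m, parse_peptide("RKKRRQRRR", "tat9"))
#' @export
cpp_classifier <- function(dataset, features = NULL, C = 1, omega = 1,
                           sigma = 1, tol = 1e-3, seed = 1L) {
  stopifnot(inherits(dataset, "cpp_dataset"))
  if (is.null(features)) features <- colnames(dataset$x)
  if (!length(features)) stop("EmptySubset: no features selected", call. = FALSE)
  bad <- setdiff(features, colnames(dataset$x))
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  x <- dataset$x[, features, drop = FALSE]
  norm <- fit_normalizer(x)
  fit <- cpp_svm(apply_normalizer(norm, x), dataset_y(dataset), C = C,
                 omega = omega, sigma = sigma, tol = tol, seed = seed)
  structure(list(svm = fit, normalizer = norm, features = features,
                 strategy = dataset$strategy, seed = seed),
            class = "cpp_classifier")
}

# Raw peptides/collections/matrices -> normalized subset matrix.
.classifier_matrix <- function(object, newdata) {
  if (inherits(newdata, "cpp_dataset")) newdata <- newdata$x
  if (inherits(newdata, "peptide")) newdata <- list(newdata)
  if (inherits(newdata, "peptide_collection") ||
      (is.list(newdata) && !is.data.frame(newdata))) {
    newdata <- peptide_features(newdata)
  }
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing <- setdiff(object$features, colnames(newdata))
    if (length(missing)) {
      stop("DimensionError: input lacks features ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    newdata <- newdata[, object$features, drop = FALSE]
  } else if (ncol(newdata) != length(object$features)) {
    stop("DimensionError: expected ", length(object$features), " columns",
         call. = FALSE)
  }
  apply_normalizer(object$normalizer, newdata)
}

#' @export
#' @rdname cpp_classifier
#' @param object A `cpp_classifier`.
#' @param newdata Peptide, collection, `cpp_dataset`, or feature matrix.
#' @param type `"class"` or `"decision"`.
#' @param ... Unused.
predict.cpp_classifier <- function(object, newdata,
                                   type = c("class", "decision"), ...) {
  predict(object$svm, .classifier_matrix(object, newdata),
          type = match.arg(type))
}

#' @export
print.cpp_classifier <- function(x, ...) {
  cat(sprintf("<cpp_classifier> %d features, trained on '%s' dataset\n",
              length(x$features), x$strategy))
  print(x$svm)
  invisible(x)
}

#' Serialize a classifier to versioned JSON
#'
#' Writes/reads the complete decision function (kernel parameters, selected
#' features, normalization bounds, support rows, dual coefficients, bias) so
#' that a reloaded model reproduces predictions exactly.
#'
#' @param object A `cpp_classifier`.
#' @param path Output JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` a
#'   `cpp_classifier`.
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "cpp_classifier"))
  payload <- list(
    format = "cppscreen-model", version = 1L,
    features = object$features, strategy = object$strategy,
    kernel = list(omega = object$svm$omega, sigma = object$svm$sigma),
    C = object$svm$C, b = object$svm$b,
    normalizer = list(min = unname(object$normalizer$min),
                      max = unname(object$normalizer$max)),
    support = unname(apply(object$svm$sv, 1L, function(r) unname(r),
                           simplify = FALSE)),
    dual_coefs = unname(object$svm$coefs))
  # 17 significant digits round-trips IEEE doubles exactly, so a reloaded
  # model reproduces decision values bit for bit
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cppscreen-model")) {
    stop("not a cppscreen model file: ", path, call. = FALSE)
  }
  sv <- if (is.matrix(p$support)) p$support
        else do.call(rbind, lapply(p$support, as.numeric))
  colnames(sv) <- p$features
  norm <- structure(list(min = stats::setNames(p$normalizer$min, p$features),
                         max = stats::setNames(p$normalizer$max, p$features),
                         names = p$features),
                    class = "minmax_normalizer")
  svm <- structure(list(sv = sv, coefs = as.numeric(p$dual_coefs), b = p$b,
                        C = p$C, omega = p$kernel$omega, sigma = p$kernel$sigma,
                        feature_names = p$features),
                   class = "cpp_svm")
  structure(list(svm = svm, normalizer = norm, features = p$features,
                 strategy = p$strategy, seed = NA_integer_),
            class = "cpp_classifier")
}
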