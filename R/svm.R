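# PUK-kernel SVM: the core estimator. The Pearson VII universal kernel
#   K(x, z) = 1 / [1 + (2 * ||x - z|| * sqrt(2^(1/omega) - 1) / sigma)^2]^omega
# interpolates between Gaussian-like (large omega) and Lorentzian (omega = 1)
# shapes; sigma sets the half-width.

#' Pearson VII universal kernel
#'
#' Evaluates the PUK between two numeric vectors. `puk_gram` evaluates the
#' kernel between all row pairs of one or two matrices.
#'
#' @param x,z Numeric vectors of equal length.
#' @param omega Tailing exponent (> 0); 1 gives a Lorentzian profile.
#' @param sigma Half-width (> 0).
#' @return Kernel value in (0, 1]; `puk_gram` returns a matrix.
#' @examples
#' puk_kernel(c(0, 0), c(0.3, 0.4), omega = 1, sigma = 1) # ||x-z|| = 0.5
#' @export
puk_kernel <- function(x, z, omega = 1, sigma = 1) {
  stopifnot(omega > 0, sigma > 0)
  if (length(x) != length(z)) {
    stop("DimensionError: vectors of length ", length(x), " and ", length(z),
         call. = FALSE)
  }
  d <- sqrt(sum((x - z)^2))
  1 / (1 + (2 * d * sqrt(2^(1 / omega) - 1) / sigma)^2)^omega
}

#' @rdname puk_kernel
#' @param X,Z Numeric matrices with observations in rows; `Z = NULL` gives
#'   the symmetric Gram matrix of `X`.
#' @export
puk_gram <- function(X, Z = NULL, omega = 1, sigma = 1) {
  stopifnot(omega > 0, sigma > 0)
  X <- as.matrix(X)
  if (is.null(Z)) {
    D2 <- as.matrix(stats::dist(X))^2
  } else {
    Z <- as.matrix(Z)
    if (ncol(X) != ncol(Z)) {
      stop("DimensionError: ", ncol(X), " vs ", ncol(Z), " columns",
           call. = FALSE)
    }
    D2 <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
    D2[D2 < 0] <- 0
  }
  1 / (1 + 4 * D2 * (2^(1 / omega) - 1) / sigma^2)^omega
}

#' Fit a PUK-kernel support vector machine
#'
#' Trains a binary soft-margin SVM with the Pearson VII universal kernel by
#' sequential minimal optimization (analytic two-variable dual updates with a
#' full error cache). The positive class is `"CPP"` when `y` is a character
#' or factor, otherwise the `+1` level of a numeric `+1/-1` response.
#'
#' @param x Numeric feature matrix (rows = observations). Supply features on
#'   a common scale (e.g. via [apply_normalizer()]); no rescaling is done here.
#' @param y Response: `+1/-1`, logical, or character/factor with two levels.
#' @param C Soft-margin penalty (> 0).
#' @param omega,sigma PUK kernel parameters.
#' @param tol KKT violation tolerance of the SMO solver.
#' @param eps Numerical epsilon.
#' @param max_epochs Cap on SMO outer sweeps.
#' @param seed Integer seed for the solver's randomized tie-breaks.
#' @return Object of class `cpp_svm`: support rows, dual coefficients
#'   `alpha_i y_i`, bias `b`, kernel and solver settings.
#' @examples
#' x <- rbind(c(0, 0), c(1, 1))
#' fit <- cpp_svm(x, c(-1, 1))
#' predict(fit, x)
#' @export
cpp_svm <- function(x, y, C = 1, omega = 1, sigma = 1, tol = 1e-3,
                    eps = 1e-12, max_epochs = 2000L, seed = 1L) {
  x <- as.matrix(x)
  stopifnot(C > 0, tol > 0, nrow(x) >= 2L)
  yy <- .as_pm1(y)
  if (length(unique(yy)) < 2L) {
    stop("DegenerateLabels: both classes are required to fit an SVM",
         call. = FALSE)
  }
  if (length(yy) != nrow(x)) {
    stop("DimensionError: ", nrow(x), " rows but ", length(yy), " labels",
         call. = FALSE)
  }
  K <- puk_gram(x, omega = omega, sigma = sigma)
  sol <- smo_solve(K, yy, C, tol, eps, as.integer(max_epochs),
                   as.integer(seed))
  alpha <- sol$alpha
  sv <- which(alpha > eps)
  obj <- sum(alpha) - 0.5 * drop(t(alpha * yy) %*% K %*% (alpha * yy))
  structure(list(sv = x[sv, , drop = FALSE], coefs = (alpha * yy)[sv],
                 alpha = alpha, y = yy, b = sol$b, C = C, omega = omega,
                 sigma = sigma, tol = tol, objective = obj,
                 converged = sol$converged, epochs = sol$epochs,
                 feature_names = colnames(x)),
            class = "cpp_svm")
}

.as_pm1 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) return(ifelse(y == "CPP", 1, -1))
  if (is.logical(y)) return(ifelse(y, 1, -1))
  y <- as.numeric(y)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1, logical, or CPP/NON_CPP",
                                  call. = FALSE)
  y
}

#' Decision values of a fitted PUK-SVM
#'
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b`, positive for the CPP side.
#'
#' @param object A `cpp_svm` fit.
#' @param newx Matrix (or single vector) of feature rows.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(object, newx) {
  stopifnot(inherits(object, "cpp_svm"))
  if (is.null(dim(newx))) newx <- matrix(newx, nrow = 1L)
  if (ncol(newx) != ncol(object$sv)) {
    stop("DimensionError: model has ", ncol(object$sv), " features, input has ",
         ncol(newx), call. = FALSE)
  }
  Kx <- puk_gram(as.matrix(newx), object$sv, omega = object$omega,
                 sigma = object$sigma)
  drop(Kx %*% object$coefs) + object$b
}

#' @export
#' @rdname decision_values
#' @param type `"class"` for labels, `"decision"` for raw decision values.
#' @param ... Unused.
predict.cpp_svm <- function(object, newx, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  f <- decision_values(object, newx)
  if (type == "decision") return(f)
  ifelse(f > 0, "CPP", "NON_CPP")
}

#' @export
print.cpp_svm <- function(x, ...) {
  cat(sprintf("<cpp_svm> PUK (omega=%g, sigma=%g), C=%g: %d support vectors, b=%.4f\n",
              x$omega, x$sigma, x$C, nrow(x$sv), x$b))
  invisible(x)
}

#' @export
summary.cpp_svm <- function(object, ...) {
  yf <- decision_values(object, object$sv)
  cat(sprintf("PUK-kernel SVM (omega=%g, sigma=%g, C=%g)\n", object$omega,
              object$sigma, object$C))
  cat(sprintf("  support vectors : %d (of %d training rows)\n",
              nrow(object$sv), length(object$alpha)))
  cat(sprintf("  bias b          : %.6f\n", object$b))
  cat(sprintf("  dual objective  : %.6f\n", object$objective))
  cat(sprintf("  sum alpha_i y_i : %.2e\n", sum(object$coefs)))
  cat(sprintf("  converged       : %s (%d epochs)\n", object$converged,
              object$epochs))
  invisible(object)
}

#' @export
coef.cpp_svm <- function(object, ...) {
  list(dual_coefs = object$coefs, b = object$b)
}
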