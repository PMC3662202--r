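#' Radial basis function kernel
#'
#' `k(x, y) = exp(-gamma * ||x - y||^2)`, symmetric and in `(0, 1]`.
#'
#' @param x,y numeric vectors, or matrices with observations in rows.
#' @param gamma kernel width (> 0).
#' @return A scalar for two vectors, otherwise the `nrow(x)` x `nrow(y)`
#'   kernel matrix.
#' @export
rbf_kernel <- function(x, y, gamma) {
  check_number(gamma, "gamma", min = 0, strict = TRUE)
  if (!is.matrix(x) && !is.matrix(y))
    return(exp(-gamma * sum((x - y)^2)))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  Y <- if (is.matrix(y)) y else matrix(y, nrow = 1)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Train a soft-margin RBF support vector machine
#'
#' One-against-rest multi-class SVM. Each binary machine solves the dual
#' problem (maximize `sum(alpha) - 1/2 alpha' Q alpha` subject to
#' `0 <= alpha_i <= C` and `sum(alpha_i y_i) = 0`) by sequential minimal
#' optimization with maximal-violating-pair selection; prediction takes
#' the class whose machine yields the maximum decision value.
#'
#' @param X numeric feature matrix (subjects x features).
#' @param y class labels (>= 2 classes).
#' @param C soft-margin cost (> 0).
#' @param gamma RBF width (> 0; default `1/ncol(X)`).
#' @param tol KKT gap tolerance of the solver.
#' @param max_iter iteration cap; exceeding it raises an error with the
#'   residual KKT gap.
#' @return An object of class `vm_svm` with the training data, the per-class
#'   machines (`alpha`, `dual_coef = alpha * y`, `b`, `objective`,
#'   support-vector indices) and the kernel parameters.
#' @export
svm_train <- function(X, y, C = 1, gamma = NULL, tol = 1e-6,
                      max_iter = 200000L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2L) vm_stop("parameter", "need at least 2 classes")
  check_number(C, "C", min = 0, strict = TRUE)
  gamma <- gamma %||% (1 / ncol(X))
  check_number(gamma, "gamma", min = 0, strict = TRUE)
  K <- rbf_kernel(X, X, gamma)
  # the violating-pair gap scales with the box size, so the stopping
  # tolerance is made scale-aware for very large C
  tol_eff <- tol * max(1, sqrt(C))
  machines <- lapply(levels(y), function(cl) {
    yy <- ifelse(y == cl, 1, -1)
    sol <- .smo_solve(K, yy, C, tol_eff, as.integer(max_iter))
    if (sol$kkt_gap > max(tol_eff, 1e-3) && sol$iterations >= max_iter)
      vm_stop("solver",
              "SMO did not converge for class %s: KKT gap %.3g after %d iterations",
              cl, sol$kkt_gap, sol$iterations)
    sv <- which(sol$alpha > 1e-8)
    list(class = cl, alpha = sol$alpha, dual_coef = sol$alpha * yy,
         b = sol$b, objective = sol$objective, support = sv,
         iterations = sol$iterations, kkt_gap = sol$kkt_gap)
  })
  structure(list(X = X, y = y, classes = levels(y), machines = machines,
                 C = C, gamma = gamma, strategy = "one-against-rest"),
            class = "vm_svm")
}

#' @export
print.vm_svm <- function(x, ...) {
  nsv <- vapply(x$machines, function(m) length(m$support), integer(1))
  cat(sprintf("<vm_svm> %s, C=%.4g gamma=%.4g, SVs per class: %s\n",
              x$strategy, x$C, x$gamma,
              paste(sprintf("%s=%d", x$classes, nsv), collapse = ", ")))
  invisible(x)
}

#' Decision values of the one-against-rest machines
#'
#' @param model a [svm_train] result.
#' @param newdata feature matrix or single vector.
#' @return Matrix (observations x classes) of decision values.
#' @export
svm_decision <- function(model, newdata) {
  Xn <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  if (ncol(Xn) != ncol(model$X))
    vm_stop("parameter", "feature dimension mismatch")
  Kn <- rbf_kernel(Xn, model$X, model$gamma)
  dv <- vapply(model$machines,
               function(m) as.numeric(Kn %*% m$dual_coef + m$b),
               numeric(nrow(Xn)))
  dv <- matrix(dv, nrow = nrow(Xn))
  colnames(dv) <- model$classes
  dv
}

#' @export
predict.vm_svm <- function(object, newdata, ...) {
  dv <- svm_decision(object, newdata)
  factor(object$classes[max.col(dv, ties.method = "first")],
         levels = object$classes)
}
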