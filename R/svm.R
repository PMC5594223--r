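#' Linear 2-norm soft-margin support vector machine
#'
#' Trains the linear (dot-product kernel) SVM with quadratic slack penalty by
#' minimizing the exact convex primal
#' \deqn{0.5 ||w||^2 + C \sum_i \max(0, 1 - y_i (w'x_i + b))^2,}
#' i.e. the 2-norm soft-margin machine. The objective is smooth (C1),
#' piecewise quadratic and strictly convex in w; it is minimized exactly by
#' a finite Newton iteration over active sets (one small ridge solve per
#' step, monotone via a halving line search).
#'
#' The first factor level is coded +1 (the "sensitivity" group of a pairwise
#' comparison), the second -1.
#'
#' @param x n x p numeric feature matrix.
#' @param y two-level factor (or vector coercible to one) of length n.
#' @param cost soft-margin penalty C (default 1).
#' @return Object of class \code{svm2norm} with elements \code{w}, \code{b},
#'   \code{levels}, \code{cost}.
#' @export
trainSVM <- function(x, y, cost = 1) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features contain non-finite values")
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("exactly two classes required; got ", nlevels(y))
  if (length(unique(y)) != 2L) stop("both classes must be present")
  ys <- ifelse(y == levels(y)[1], 1, -1)
  n <- nrow(x); p <- ncol(x)

  # For y = +-1 the squared hinge is max(0, 1 - y f)^2 = (y - f)^2 on the
  # active set {i : y_i f_i < 1}, so the minimizer given an active set A
  # solves the ridge system (D + 2C X_A' X_A) wb = 2C X_A' y_A with
  # D = diag(1, ..., 1, eps) (the intercept is unpenalized up to a tiny
  # ridge for numerical safety). Finite Newton iteration over active sets
  # with a halving line search; exact for this piecewise-quadratic convex
  # objective, typically < 10 solves.
  Xa <- cbind(x, 1)
  D <- c(rep(1, p), 1e-10)
  obj <- function(wb) {
    xi <- pmax(0, 1 - ys * drop(Xa %*% wb))
    0.5 * sum(D * wb^2) + cost * sum(xi^2)
  }
  wb <- numeric(p + 1)
  Aset <- rep(TRUE, n)
  for (it in seq_len(100)) {
    XA <- Xa[Aset, , drop = FALSE]
    H <- diag(D, p + 1) + 2 * cost * crossprod(XA)
    rhs <- 2 * cost * drop(crossprod(XA, ys[Aset]))
    wbNew <- drop(solve(H, rhs))
    # halving line search keeps the objective monotone
    jOld <- obj(wb)
    step <- 1
    while (obj(wb + step * (wbNew - wb)) > jOld + 1e-12 && step > 1e-8)
      step <- step / 2
    wbNext <- wb + step * (wbNew - wb)
    ANew <- ys * drop(Xa %*% wbNext) < 1
    done <- identical(ANew, Aset) && sum((wbNext - wb)^2) < 1e-20
    wb <- wbNext
    Aset <- ANew
    if (done) break
  }
  structure(list(w = wb[seq_len(p)], b = wb[p + 1],
                 levels = levels(y), cost = cost),
            class = "svm2norm")
}

#' Predict method for the 2-norm SVM
#'
#' @param object an \code{svm2norm} fit.
#' @param newdata n x p matrix.
#' @param decision return raw decision values instead of labels.
#' @param ... unused.
#' @return Factor of predicted labels (ties at 0 go to the first level), or
#'   numeric decision values.
#' @export
predict.svm2norm <- function(object, newdata, decision = FALSE, ...) {
  f <- drop(as.matrix(newdata) %*% object$w) + object$b
  if (decision) return(f)
  factor(ifelse(f >= 0, object$levels[1], object$levels[2]),
         levels = object$levels)
}
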