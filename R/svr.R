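# Epsilon support-vector regression, linear kernel.
#
# CPM features are 1- or 2-dimensional network strengths, so a linear
# kernel is the minimal assumption and the dual QP is tiny (2n variables
# for n training subjects). The QP
#   min 1/2 (a - a*)' K (a - a*) + eps * sum(a + a*) - y'(a - a*)
#   s.t. sum(a - a*) = 0,  0 <= a, a* <= C
# is solved with quadprog::solve.QP on the stacked variable u = (a, a*),
# with a small diagonal jitter to make the (singular, PSD) matrix strictly
# positive definite. Deterministic given data and hyperparameters.

#' Fit a linear epsilon-SVR
#'
#' @param x Feature matrix (subjects x d) or vector; d is typically 1
#'   (a single network strength or the summed index) or 2 (positive and
#'   negative strengths).
#' @param y Numeric targets (standardized scores).
#' @param C Box constraint (default 1).
#' @param epsilon Insensitive-tube half-width (default 0.1).
#' @return Object of class `svr_model` with weight vector `w`, offset `b`,
#'   and dual coefficients `beta`.
#' @export
#' @examples
#' x <- matrix(seq(-1, 1, length.out = 20))
#' fit <- fit_svr(x, 2 * x[, 1])
#' predict(fit, x)[1:3]
fit_svr <- function(x, y, C = 1, epsilon = 0.1) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  stopifnot(is.matrix(x), is.numeric(y), nrow(x) == length(y))
  if (nrow(x) < 2L) stop("need at least 2 training points")
  if (!(C > 0) || !(epsilon >= 0)) stop("invalid hyperparameters")
  if (all(matrixStats::colSds(x) < .Machine$double.eps^0.5)) {
    stop("degenerate features: all columns constant")
  }
  n <- nrow(x)
  K <- tcrossprod(x)
  jitter <- 1e-6 * (max(diag(K)) + 1)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(2 * n) * jitter
  dvec <- c(y - epsilon, -y - epsilon)
  A <- cbind(c(rep(1, n), rep(-1, n)), diag(2 * n), -diag(2 * n))
  bvec <- c(0, rep(0, 2 * n), rep(-C, 2 * n))
  sol <- quadprog::solve.QP(D, dvec, A, bvec, meq = 1L)$solution
  alpha <- sol[seq_len(n)]
  alpha_star <- sol[n + seq_len(n)]
  beta <- alpha - alpha_star
  w <- drop(crossprod(x, beta))
  # offset: exact minimizer of the epsilon-insensitive loss in b at fixed w
  # (convex piecewise linear; optimum sits on a breakpoint or flat segment)
  fx <- drop(x %*% w)
  r <- y - fx
  cand <- sort(c(r - epsilon, r + epsilon))
  loss <- vapply(cand, function(b) sum(pmax(abs(r - b) - epsilon, 0)),
                 numeric(1))
  opt <- which(loss <= min(loss) + 1e-12)
  b <- mean(range(cand[opt]))
  structure(list(w = w, b = b, beta = beta, C = C, epsilon = epsilon,
                 d = ncol(x)),
            class = "svr_model")
}

#' Predict from a fitted linear SVR
#' @param object An `svr_model`.
#' @param newdata Feature matrix or vector with the training dimensionality.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (is.vector(newdata)) {
    newdata <- if (object$d == 1L) matrix(newdata, ncol = 1L)
               else matrix(newdata, nrow = 1L)
  }
  if (ncol(newdata) != object$d) {
    stop("expected ", object$d, " feature(s), got ", ncol(newdata))
  }
  drop(newdata %*% object$w) + object$b
}

#' @export
print.svr_model <- function(x, ...) {
  cat(sprintf("<svr_model> linear, d=%d, C=%g, epsilon=%g, |w|=%.4f, b=%.4f\n",
              x$d, x$C, x$epsilon, sqrt(sum(x$w^2)), x$b))
  invisible(x)
}
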