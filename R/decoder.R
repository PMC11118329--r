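#' @include AllClasses.R
NULL

#' Fit the penalized logistic housing-condition decoder
#'
#' Multivariable binary logistic regression by Newton iteration on the
#' ridge-penalized negative log-likelihood
#' \deqn{-\sum_i [y_i \log p_i + (1-y_i)\log(1-p_i)] + \frac{\lambda}{2}\|\beta\|^2,}
#' with an unpenalized intercept and features standardized internally
#' (sample sd) so coefficient magnitudes are comparable across features.
#' The problem is strictly convex for \eqn{\lambda > 0} and the optimizer
#' starts from zero, so the fit is deterministic. Training accuracy is the
#' fraction of the fitting data classified correctly at the 0.5 threshold.
#'
#' @param x numeric feature matrix or data.frame [subjects x features].
#' @param y two-class labels; the second factor level is modeled as 1.
#' @param l2Strength ridge penalty \eqn{\lambda} (> 0). The default (1) is
#'   small relative to any realistic subject count, so fitted probabilities
#'   are barely shrunk, while still pinning down a unique, stable
#'   coefficient direction when classes are separable — without it the
#'   importance ranking on separable cohorts would be arbitrary.
#' @param maxIter maximum Newton iterations.
#' @param tol convergence tolerance on the gradient norm.
#' @return A \linkS4class{DecoderReport}. Constant features are dropped and
#'   recorded in the report.
#' @export
fitLogisticDecoder <- function(x, y, l2Strength = 1, maxIter = 100L,
                               tol = 1e-8) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("feature_", seq_len(ncol(x)))
  y <- factor(y)
  if (nlevels(y) != 2L)
    stop("two classes required, got ", nlevels(y))
  if (any(table(y) < 2L)) stop("need at least 2 subjects per class")
  if (anyNA(x)) stop("features must be complete (no NA)")
  if (l2Strength <= 0) stop("l2Strength must be > 0")
  yy <- as.numeric(y) - 1
  sds <- apply(x, 2, stats::sd)
  dropped <- colnames(x)[!is.finite(sds) | sds == 0]
  keep <- setdiff(colnames(x), dropped)
  if (!length(keep)) stop("all features are constant")
  xs <- scale(x[, keep, drop = FALSE])
  X <- cbind(`(intercept)` = 1, xs)
  p1 <- ncol(X)
  pen <- c(0, rep(l2Strength, p1 - 1L))
  beta <- numeric(p1)
  objective <- function(b) {
    eta <- drop(X %*% b)
    # log(1 + exp(eta)) - y*eta, computed stably
    sum(pmax(eta, 0) + log1p(exp(-abs(eta))) - yy * eta) +
      sum(pen * b^2) / 2
  }
  obj <- objective(beta)
  iter <- 0L
  gnorm <- Inf
  repeat {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X, p - yy)) + pen * beta
    gnorm <- sqrt(sum(g^2))
    if (gnorm < tol || iter >= maxIter) break
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X) + diag(pen, p1)
    step <- solve(H, g)
    # halve the step until the penalized objective decreases
    s <- 1
    repeat {
      cand <- beta - s * step
      candObj <- objective(cand)
      if (candObj <= obj + 1e-12 || s < 1e-8) break
      s <- s / 2
    }
    beta <- beta - s * step
    obj <- candObj
    iter <- iter + 1L
  }
  if (gnorm >= tol)
    stop(sprintf(
      "convergence error: gradient norm %.3e after %d iterations", gnorm,
      iter))
  eta <- drop(X %*% beta)
  pred <- as.integer(eta > 0)
  new("DecoderReport",
      features = keep,
      coefficients = unname(beta[-1]),
      intercept = unname(beta[1]),
      accuracy = mean(pred == yy),
      l2Strength = l2Strength,
      classes = levels(y),
      converged = TRUE,
      iterations = iter,
      gradNorm = gnorm,
      dropped = dropped)
}

#' Penalized log-likelihood gradient at a decoder's reported optimum
#'
#' Recomputes the gradient of the ridge-penalized negative log-likelihood at
#' the coefficients stored in a \linkS4class{DecoderReport}, on the same
#' internally standardized features. Useful for verifying that the reported
#' fit is a stationary point.
#'
#' @param report a \linkS4class{DecoderReport}.
#' @param x,y the data the report was fitted on.
#' @return numeric gradient vector (intercept first).
#' @export
decoderGradient <- function(report, x, y) {
  x <- as.matrix(x)[, report@features, drop = FALSE]
  yy <- as.numeric(factor(y, levels = report@classes)) - 1
  X <- cbind(1, scale(x))
  beta <- c(report@intercept, report@coefficients)
  pen <- c(0, rep(report@l2Strength, length(report@coefficients)))
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  drop(crossprod(X, p - yy)) + pen * beta
}
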