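test_that("a separable feature is decoded with training accuracy 1", {
  set.seed(1)
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1)
  y <- rep(c("GH", "SI"), each = 20)
  fit <- fitLogisticDecoder(x, y, l2Strength = 1e-4)
  expect_equal(trainingAccuracy(fit), 1)
  expect_gt(decoderCoefficients(fit)[1], 0)
})

test_that("the reported optimum is a stationary point of the penalized loss", {
  set.seed(12)
  x <- matrix(rnorm(60 * 4), 60, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- rbinom(60, 1, plogis(x[, 1] - 0.5 * x[, 3]))
  fit <- fitLogisticDecoder(x, factor(y), l2Strength = 0.05)
  g <- decoderGradient(fit, x, factor(y))
  expect_lt(sqrt(sum(g^2)), 1e-6)

  # finite-difference check of the same penalized objective
  xs <- cbind(1, scale(x))
  beta <- c(fit@intercept, fit@coefficients)
  pen <- c(0, rep(fit@l2Strength, 4))
  nll <- function(b) {
    eta <- drop(xs %*% b)
    sum(log1p(exp(eta)) - y * eta) + sum(pen * b^2) / 2
  }
  fd <- vapply(seq_along(beta), function(j) {
    h <- 1e-6; e <- numeric(length(beta)); e[j] <- h
    (nll(beta + e) - nll(beta - e)) / (2 * h)
  }, 0)
  expect_lt(max(abs(fd)), 1e-4)
})

test_that("weak-penalty fits agree with an unpenalized reference fit", {
  set.seed(5)
  x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rbinom(200, 1, plogis(0.8 * x[, 1] - 0.4 * x[, 2]))
  fit <- fitLogisticDecoder(x, factor(y), l2Strength = 1e-8)
  ref <- stats::glm(y ~ scale(x), family = binomial())
  expect_equal(unname(decoderCoefficients(fit)),
               unname(coef(ref)[-1]), tolerance = 1e-4)
  expect_equal(fit@intercept, unname(coef(ref)[1]), tolerance = 1e-4)
})

test_that("permuted labels decode at chance for large n", {
  set.seed(77)
  n <- 400
  x <- matrix(rnorm(n * 2), n, 2)
  y <- rep(0:1, each = n / 2)
  acc <- vapply(1:100, function(i) {
    trainingAccuracy(fitLogisticDecoder(x, factor(sample(y)),
                                        l2Strength = 0.01))
  }, 0)
  band <- 1.96 * sqrt(0.25 / n)
  expect_gt(mean(acc), 0.5 - band)
  expect_lt(mean(acc), 0.5 + band)
})

test_that("stronger ridge penalties trade training fit for shrinkage", {
  set.seed(41)
  x <- matrix(rnorm(50 * 4), 50, 4)
  yy <- rbinom(50, 1, plogis(1.5 * x[, 1] + x[, 2]))
  y <- factor(yy)
  grid <- c(1e-4, 1e-2, 1, 10, 100, 1000)
  fits <- lapply(grid, function(l) fitLogisticDecoder(x, y, l2Strength = l))
  # the unpenalized deviance of the fit is non-decreasing in the penalty
  xs <- cbind(1, scale(x))
  dev <- vapply(fits, function(f) {
    eta <- drop(xs %*% c(f@intercept, f@coefficients))
    2 * sum(log1p(exp(eta)) - yy * eta)
  }, 0)
  expect_true(all(diff(dev) >= -1e-8))
  # coefficients shrink toward zero and accuracy falls toward the majority
  # rate at the strong-penalty end
  norms <- vapply(fits, function(f) sqrt(sum(f@coefficients^2)), 0)
  expect_true(all(diff(norms) <= 1e-8))
  expect_lte(trainingAccuracy(fits[[length(fits)]]),
             trainingAccuracy(fits[[1]]))
})

test_that("degenerate inputs are rejected or recorded", {
  x <- matrix(rnorm(20), ncol = 1)
  expect_error(fitLogisticDecoder(x, rep("GH", 20)), "two classes")
  x2 <- cbind(flat = rep(1, 20), sig = c(rnorm(10, -2), rnorm(10, 2)))
  fit <- fitLogisticDecoder(x2, rep(c("a", "b"), each = 10),
                            l2Strength = 0.01)
  expect_equal(fit@dropped, "flat")
  expect_equal(fit@features, "sig")
})
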