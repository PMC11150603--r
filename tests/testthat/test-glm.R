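test_that("Fourier design matrix has the stated structure", {
  th <- runif(50, -pi, pi)
  expect_equal(fourierDesign(th, 0), matrix(1, 50, 1))
  expect_equal(fourierDesign(0, 1), matrix(c(1, 1, 0), 1))
  expect_equal(fourierDesign(pi / 2, 2), matrix(c(1, 0, 1, -1, 0), 1),
               tolerance = 1e-12)
  expect_error(fourierDesign(th, -1), "invalid order")
})

test_that("the basis is numerically orthogonal on a uniform circular grid", {
  th <- -pi + (0:1023) * 2 * pi / 1024
  X <- fourierDesign(th, 2)
  G <- crossprod(X) / 1024
  # after scaling columns to unit norm the Gram matrix is the identity
  D <- diag(1 / sqrt(diag(G)))
  expect_lt(max(abs(D %*% G %*% D - diag(5))), 1e-10)
})

test_that("NLL matches direct density evaluation and the unit case", {
  expect_equal(gammaNLL(1, 0.3, 0, 1), 1)
  d <- rGlmData(200, c(0.5, 0.3, -0.2), 3)
  w <- c(0.4, 0.2, -0.1)
  a <- 2.5
  L <- drop(fourierDesign(d$theta, 1) %*% w)
  direct <- -sum(stats::dgamma(d$y, shape = a, rate = a * exp(-L),
                               log = TRUE))
  expect_equal(gammaNLL(d$y, d$theta, w, a), direct, tolerance = 1e-10)
  expect_error(gammaNLL(c(-1, d$y[-1]), d$theta, w, a),
               "invalid amplitude")
})

test_that("NLL differences in w equal alpha times partial-objective
           differences", {
  set.seed(4)
  d <- rGlmData(300, c(0.2, 0.4, 0.1), 2)
  obj <- function(w) {
    L <- drop(fourierDesign(d$theta, 1) %*% w)
    sum(d$y * exp(-L) + L)
  }
  a <- 3.7
  w1 <- c(0.1, 0.2, -0.3); w2 <- c(0.5, -0.1, 0.2)
  expect_equal(gammaNLL(d$y, d$theta, w1, a) -
                 gammaNLL(d$y, d$theta, w2, a),
               a * (obj(w1) - obj(w2)), tolerance = 1e-8)
})

test_that("intercept-only weights have the closed form log(mean)", {
  y <- rep(2.5, 100)
  w <- fitWeights(y, runif(100, -pi, pi), 0)
  expect_equal(w, log(2.5), tolerance = 1e-6)
})

test_that("weights and shape are recovered from model-generated data", {
  set.seed(11)
  d <- rGlmData(20000, c(0.5, 0.3, -0.2), 3)
  fit <- fitGammaGlm(d$y, d$theta, 1)
  expect_lt(max(abs(coef(fit) - c(0.5, 0.3, -0.2))), 0.05)
  expect_lt(abs(shape(fit) - 3), 0.15)
})

test_that("the fitted weights beat a random search around the solution", {
  set.seed(12)
  d <- rGlmData(2000, c(0.4, 0.25, -0.15), 4)
  w <- fitWeights(d$y, d$theta, 1)
  X <- fourierDesign(d$theta, 1)
  obj <- function(W) {           # columns of W are candidate weights
    L <- X %*% W
    colSums(d$y * exp(-L) + L)
  }
  cand <- w + matrix(runif(3 * 10000, -0.3, 0.3), 3)
  expect_true(all(obj(matrix(w)) <= obj(cand) + 1e-8))
})

test_that("the shape fit recovers known shapes and matches a grid search", {
  set.seed(13)
  y1 <- rexp(50000)
  a1 <- fitShape(y1, runif(50000, -pi, pi), log(mean(y1)))
  expect_gt(a1, 0.97); expect_lt(a1, 1.03)

  y5 <- rgamma(50000, shape = 5, rate = 5)
  th <- runif(50000, -pi, pi)
  w5 <- fitWeights(y5, th, 0)
  a5 <- fitShape(y5, th, w5)
  expect_gt(a5, 4.8); expect_lt(a5, 5.2)

  # 1-D grid oracle over Eq-9-style profile at fixed link values
  agrid <- exp(seq(log(1e-3), log(100), length.out = 1e5))
  T <- length(y5)
  s1 <- sum(log(y5)); s2 <- sum(y5 * exp(-w5)); s3 <- T * w5
  prof <- T * lgamma(agrid) - (agrid - 1) * s1 + agrid * s2 +
    agrid * s3 - T * agrid * log(agrid)
  aGrid <- agrid[which.min(prof)]
  expect_equal(signif(aGrid, 3), signif(a5, 3))
})

test_that("two-step fit reproduces the sample mean and is deterministic", {
  set.seed(14)
  y <- rgamma(5000, shape = 2, rate = 2 / 3)   # mean 3
  th <- runif(5000, -pi, pi)
  fit <- fitGammaGlm(y, th, 0)
  expect_lt(abs(exp(coef(fit)) / mean(y) - 1), 0.01)
  fit2 <- fitGammaGlm(y, th, 0)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(shape(fit), shape(fit2))
})

test_that("fit is equivariant to amplitude scaling and phase rotation", {
  set.seed(15)
  d <- rGlmData(8000, c(0.3, 0.5, -0.2), 4)
  f0 <- fitGammaGlm(d$y, d$theta, 1)
  fc <- fitGammaGlm(5 * d$y, d$theta, 1)
  expect_lt(abs(coef(fc)[1] - coef(f0)[1] - log(5)), 1e-4)
  expect_lt(max(abs(coef(fc)[-1] - coef(f0)[-1])), 1e-4)
  expect_lt(abs(shape(fc) - shape(f0)), 1e-3)

  delta <- 0.7
  thr <- ((d$theta + delta + pi) %% (2 * pi)) - pi
  fr <- fitGammaGlm(d$y, thr, 1)
  grid <- seq(-pi, pi, length.out = 101)
  m0 <- exp(drop(fourierDesign(grid, 1) %*% coef(f0)))
  mr <- exp(drop(fourierDesign(((grid + delta + pi) %% (2 * pi)) - pi, 1)
                 %*% coef(fr)))
  expect_lt(max(abs(mr - m0) / m0), 0.01)
})

test_that("both stage objectives are midpoint-convex along random segments", {
  set.seed(16)
  d <- rGlmData(500, c(0.2, 0.3, 0.1), 3)
  X <- fourierDesign(d$theta, 1)
  obj <- function(w) { L <- drop(X %*% w); sum(d$y * exp(-L) + L) }
  for (i in 1:20) {
    w1 <- runif(3, -1, 1); w2 <- runif(3, -1, 1)
    expect_lte(obj((w1 + w2) / 2), (obj(w1) + obj(w2)) / 2 + 1e-9)
  }
  L <- drop(X %*% fitWeights(d$y, d$theta, 1))
  profA <- function(a) sum(lgamma(a) - (a - 1) * log(d$y) +
                             a * d$y * exp(-L) + a * L - a * log(a))
  for (i in 1:20) {
    a1 <- runif(1, 0.05, 20); a2 <- runif(1, 0.05, 20)
    expect_lte(profA((a1 + a2) / 2), (profA(a1) + profA(a2)) / 2 + 1e-9)
  }
})

test_that("guards: too few samples, degenerate amplitudes", {
  expect_error(fitWeights(rexp(5), runif(5, -pi, pi), 2), "samples")
  expect_warning(fitWeights(rexp(25), runif(25, -pi, pi), 1),
                 "10 samples per parameter")
  expect_warning(a <- fitShape(rep(2, 50), runif(50, -pi, pi), log(2)),
                 "flat")
  expect_gt(a, 1e6)
})
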