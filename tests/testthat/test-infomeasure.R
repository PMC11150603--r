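test_that("the phase prior is uniform and normalized on any grid", {
  expect_equal(priorPhaseDensity(), 1 / (2 * pi))
  for (M in c(64L, 256L, 1024L)) {
    g <- phaseGrid(M)
    expect_equal(sum(rep(priorPhaseDensity(), M)) * 2 * pi / M, 1,
                 tolerance = 1e-12)
    expect_true(all(diff(g) > 0))
    expect_gte(g[1], -pi)
    expect_lt(g[M], pi)
  }
})

test_that("the phase posterior is a proper density with the expected shape", {
  g <- phaseGrid(256L)
  delta <- 2 * pi / 256

  m0 <- knownModel(0.4, 2)               # intercept-only: posterior = prior
  p0 <- phasePosterior(c(0.5, 2, 7), m0, g)
  expect_lt(max(abs(p0 - 1 / (2 * pi))), 1e-12)

  m1 <- knownModel(c(0, 1, 0), 5)        # mean peaks at theta = 0
  p1 <- phasePosterior(c(0.3, 1.7, 9), m1, g)
  expect_equal(unname(rowSums(p1) * delta), rep(1, 3), tolerance = 1e-10)
  expect_lt(abs(g[which.max(p1[3, ])]), delta)  # mode at 0 for large y
})

test_that("posterior-prior relative entropy is non-negative, zero under
           independence, and grid-converged", {
  g <- phaseGrid(256L)
  m0 <- knownModel(0.4, 2)
  expect_equal(klPosteriorPrior(c(0.5, 3), m0, g), c(0, 0))
  m1 <- knownModel(c(0.2, 0.6, -0.3), 4)
  y <- c(0.2, 0.9, 2.5, 6)
  d <- klPosteriorPrior(y, m1, g)
  expect_true(all(d >= 0 & is.finite(d)))
  dFine <- klPosteriorPrior(y, m1, phaseGrid(25600L))
  expect_lt(max(abs(d - dFine)), 1e-6)
})

test_that("sample-path mutual information matches independent quadrature", {
  w <- c(0, 0.5, 0); a <- 4
  set.seed(31)
  d <- rGlmData(50000, w, a)
  est <- pacValue(mutualInfoPac(d$y, d$theta, knownModel(w, a)))
  expect_lt(abs(est - oracleMI(w, a)), 0.01)
})

test_that("intercept-only models give exactly zero mutual information", {
  set.seed(32)
  d <- rGlmData(500, 0.3, 2)
  expect_identical(pacValue(mutualInfoPac(d$y, d$theta, knownModel(0.3, 2))),
                   0)
  fit <- fitGammaGlm(d$y, d$theta, 0)
  expect_identical(pacValue(mutualInfoPac(d$y, d$theta, fit)), 0)
  expect_error(mutualInfoPac(numeric(0), numeric(0), knownModel(0.3, 2)),
               "empty")
})

test_that("estimated MI increases with the coupling coefficient", {
  fs <- 50
  mis <- sapply(c(0, 0.1, 0.2, 0.3), function(chi) {
    vals <- sapply(1:8, function(s) {
      x <- simulatePac(syntheticSpec(chi = chi, snrDb = Inf, duration = 100,
                                     seed = 100 * s + chi * 10))
      x <- x + 1e-6 * sin(2 * pi * 3 * (seq_along(x)) / fs)  # break exact
      pa <- extractPhaseAmp(x, fs, c(0.03, 0.07), c(8, 12))
      suppressWarnings(
        pacValue(mutualInfoPac(pa$amplitude, pa$phase, K = 2)))
    })
    median(vals)
  })
  expect_true(all(diff(mis) > 0))
})

test_that("MI is invariant to phase rotation before fitting", {
  set.seed(33)
  d <- rGlmData(10000, c(0.3, 0.4, -0.2), 3)
  mi0 <- pacValue(mutualInfoPac(d$y, d$theta, K = 1))
  thr <- ((d$theta + 1.1 + pi) %% (2 * pi)) - pi
  mir <- pacValue(mutualInfoPac(d$y, thr, K = 1))
  expect_lt(abs(mi0 - mir), 1e-3)
})

test_that("marginal amplitude density is correct and normalized", {
  g <- phaseGrid(256L)
  m0 <- knownModel(0.4, 2)
  y <- c(0.1, 0.5, 1, 2, 5)
  expect_equal(marginalAmplitudeDensity(y, m0, g),
               dgamma(y, shape = 2, rate = 2 * exp(-0.4)),
               tolerance = 1e-12)

  m1 <- knownModel(c(0.2, 0.6, -0.3), 4)
  yg <- seq(1e-4, 30, length.out = 20000)
  expect_lt(abs(sum(marginalAmplitudeDensity(yg, m1, g)) *
                  (yg[2] - yg[1]) - 1), 1e-3)

  # Monte-Carlo oracle: f_Y(y) = E_theta[f(y | theta)]
  set.seed(34)
  th <- runif(1e5, -pi, pi)
  L <- drop(fourierDesign(th, 1) %*% c(0.2, 0.6, -0.3))
  for (y0 in c(0.3, 0.8, 1.5, 3, 6)) {
    dens <- dgamma(y0, shape = 4, rate = 4 * exp(-L))
    expect_lt(abs(marginalAmplitudeDensity(y0, m1, g) - mean(dens)),
              3 * sd(dens) / sqrt(1e5))
  }
})

test_that("information density averages to the MI and can be negative", {
  m0 <- knownModel(0.4, 2)
  expect_identical(informationDensity(c(0.5, 1), c(0, 1), m0), c(0, 0))

  w <- c(0, 0.5, 0); a <- 4
  set.seed(35)
  d <- rGlmData(50000, w, a)
  m1 <- knownModel(w, a)
  iMean <- mean(informationDensity(d$y, d$theta, m1))
  mi <- pacValue(mutualInfoPac(d$y, d$theta, m1))
  expect_lt(abs(iMean - mi), 0.01)

  # y near the marginal mode but far from the conditional mean at theta
  yNeg <- exp(0.5)                       # conditional mean at theta = 0
  expect_lt(informationDensity(yNeg, pi, m1), 0)
})

test_that("model-implied MI agrees with the independent oracle", {
  w <- c(0.1, 0.4, -0.2); a <- 3
  expect_lt(abs(modelMutualInfo(knownModel(w, a)) - oracleMI(w, a)), 1e-3)
})
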