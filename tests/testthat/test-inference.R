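test_that("circular shifts preserve marginals and respect the period", {
  fs <- 50
  t <- (0:999) / fs
  x <- sin(2 * pi * 0.1 * t)             # 10 s period = 500 samples
  expect_equal(surrogateShift(x, fs, 1, offset = 500), x, tolerance = 1e-12)
  set.seed(71)
  s <- surrogateShift(x, fs, 2)
  expect_equal(sort(s), sort(x))
  expect_error(surrogateShift(x, fs, 30), "invalid shift")
})

test_that("shift surrogates destroy coupling on an aperiodic oscillator", {
  # frequency-drifting slow wave: a time shift misaligns the phase instead
  # of merely rotating it, which is the premise of shift surrogates
  set.seed(72)
  fs <- 50; n <- 12000
  t <- (0:(n - 1)) / fs
  instF <- 0.05 * (1 + 0.5 * sin(2 * pi * t / 90))
  phSlow <- 2 * pi * cumsum(instF) / fs
  x <- (0.6 * sin(phSlow) + sqrt(2 - 0.36)) * sin(2 * pi * 10 * t) +
    sin(phSlow) + rnorm(n, 0, 0.8)
  pa <- extractPhaseAmp(x, fs, c(0.02, 0.09), c(8, 12))
  meas <- function(a, p) pacValue(mutualInfoPac(a, p, K = 1))
  obs <- meas(pa$amplitude, pa$phase)
  nl <- surrogateNull(pa$amplitude, pa$phase, meas, 30, fs, 10,
                      fitGamma = FALSE)
  expect_lt(median(nl@values), 0.25 * obs)
})

test_that("p-value conventions: tails, degenerate nulls, and gamma mode", {
  nl <- new("SurrogateNull", values = c(0.2, 0.3, 0.4), minShift = 1,
            gammaNull = NULL)
  expect_equal(surrogatePValue(0.1, nl), 1)
  expect_equal(surrogatePValue(0.5, nl), 1 / 4)
  expect_equal(surrogatePValue(0.5, nl, "proportion"), 0)

  set.seed(73)
  vals <- rgamma(200, 4, 10)
  meas <- local({ i <- 0; function(a, p) { i <<- i + 1; vals[i] } })
  nl2 <- surrogateNull(rexp(100), runif(100, -pi, pi), meas, 200, 50, 0.02)
  expect_false(is.null(nl2@gammaNull))
  med <- median(nl2@values)
  expect_lt(abs(surrogatePValue(med, nl2) - 0.5), 0.1)
  pe <- surrogatePValue(quantile(vals, 0.9), nl2, "empirical")
  pg <- surrogatePValue(quantile(vals, 0.9), nl2, "gamma")
  se <- sqrt(0.1 * 0.9 / 200)
  expect_lt(abs(pe - pg), 3 * se + 0.02)

  measC <- function(a, p) 0.5
  expect_warning(nl3 <- surrogateNull(rexp(50), runif(50, -pi, pi),
                                      measC, 30, 50, 0.02), "degenerate")
  expect_equal(surrogatePValue(0.5, nl3), 1)
})

test_that("BH and BY match literal step-up oracles on random inputs", {
  set.seed(74)
  for (i in 1:200) {
    N <- sample(1:60, 1)
    p <- runif(N)^sample(c(1, 2, 0.5), 1)
    q <- runif(1, 0.01, 0.2)
    bh <- benjaminiHochberg(p, q)
    by <- benjaminiYekutieli(p, q)
    expect_identical(bh@rejected, bruteStepUp(p, q))
    expect_identical(by@rejected, bruteStepUp(p, q, by = TRUE))
    expect_true(all(by@rejected <= bh@rejected))   # BY is stricter
    expect_equal(bh@adjusted, sort(p) * N / seq_len(N))
  }
})

test_that("edge cases of the FDR procedures", {
  allNull <- benjaminiHochberg(rep(1, 10), 0.05)
  expect_identical(sum(allNull@rejected), 0L)
  expect_identical(allNull@criticalIndex, 0L)

  one <- benjaminiHochberg(0.03, 0.05)
  expect_true(one@rejected)
  expect_identical(benjaminiYekutieli(0.03, 0.05)@rejected,
                   one@rejected)        # harmonic sum is 1 at N = 1
  expect_identical(length(benjaminiHochberg(numeric(0), 0.05)@rejected), 0L)
  expect_error(benjaminiHochberg(c(0.5, 1.2), 0.05), "lie in")
})

test_that("empirical FDR is controlled in the mixed-null simulation", {
  set.seed(75)
  fdp <- replicate(200, {
    p <- c(runif(900), rbeta(100, 0.05, 1))
    rej <- benjaminiHochberg(p, 0.05)@rejected
    if (!any(rej)) 0 else sum(rej[1:900]) / sum(rej)
  })
  se <- sd(fdp) / sqrt(length(fdp))
  expect_lte(mean(fdp), 0.05 + 2 * se)
})

test_that("band-scan geometry enumerates the published grid", {
  b <- frequencyBands(0.5, 20.5, 4, 2)
  expect_identical(nrow(b), 10L)
  expect_equal(b[, "low"], seq(0.5, 18.5, 2))
  expect_equal(b[1, ], c(low = 0.5, high = 4.5))
  expect_equal(b[10, ], c(low = 18.5, high = 22.5))
})

test_that("a 1x1 comodulogram equals the direct measure call", {
  set.seed(76)
  x <- simulatePac(syntheticSpec(chi = 0.3, snrDb = 0, duration = 60,
                                 seed = 77))
  cm <- comodulogram(x, 50, c(0.03, 0.07, 0.04, 10), c(8, 12, 4, 20),
                     method = "tortmi")
  expect_identical(dim(cm@values), c(1L, 1L))
  pa <- extractPhaseAmp(x, 50, c(0.03, 0.07), c(8, 12))
  expect_equal(cm@values[1, 1],
               suppressWarnings(tortMI(pa$amplitude, pa$phase)))
  expect_true(cm@mask[1, 1])
  expect_error(comodulogram(x, 50, c(0.03, 0.07, 0.04, 10),
                            c(8, 30, 10, 5)), "Nyquist")
})

test_that("surrogate p-values are super-uniform on uncoupled data", {
  # several slow cycles, so the phase decouples from elapsed time and the
  # observed pairing is exchangeable with shifted ones
  set.seed(78)
  ps <- replicate(60, {
    x <- simulatePac(syntheticSpec(chi = 0, snrDb = 0, duration = 100,
                                   seed = NA))
    pa <- extractPhaseAmp(x, 50, c(0.03, 0.07), c(8, 12))
    meas <- function(a, p) suppressWarnings(tortMI(a, p))
    nl <- surrogateNull(pa$amplitude, pa$phase, meas, 19, 50, 1,
                        fitGamma = FALSE)
    surrogatePValue(meas(pa$amplitude, pa$phase), nl)
  })
  for (u in c(0.1, 0.2, 0.5)) {
    se <- sqrt(u * (1 - u) / 60)
    expect_lte(mean(ps <= u), u + 2.5 * se)
  }
})
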