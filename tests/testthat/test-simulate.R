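test_that("the modulated envelope follows its closed form", {
  t <- (0:9999) / 50
  expect_equal(modulatedAmplitude(0, 0.05, t), rep(sqrt(2), 10000))
  a1 <- modulatedAmplitude(1, 0.05, t)
  expect_gte(min(a1), 0)
  expect_lt(min(a1), 1e-3)               # touches zero at the trough
  # mean square over whole cycles: chi^2/2 + (2 - chi^2)
  tc <- (0:99999) / 100                  # 1000 s = 50 slow cycles
  a3 <- modulatedAmplitude(0.3, 0.05, tc)
  expect_equal(mean(a3^2), 2 - 0.3^2 / 2, tolerance = 1e-3)
  expect_error(modulatedAmplitude(1.2, 0.05, t), "invalid coupling")
})

test_that("generated signals hit the requested SNR and are reproducible", {
  for (s in 1:5) {
    sp <- syntheticSpec(chi = 0.3, snrDb = 0, duration = 200, seed = s)
    clean <- simulatePac(syntheticSpec(chi = 0.3, snrDb = Inf,
                                       duration = 200))
    x <- simulatePac(sp)
    snr <- 10 * log10(mean(clean^2) / mean((x - clean)^2))
    expect_lt(abs(snr - 0), 0.5)
  }
  sp <- syntheticSpec(seed = 7)
  expect_identical(simulatePac(sp), simulatePac(sp))
  expect_false(identical(simulatePac(syntheticSpec(seed = 7)),
                         simulatePac(syntheticSpec(seed = 8))))
})

test_that("the noiseless uncoupled signal is the exact two-sine sum", {
  sp <- syntheticSpec(chi = 0, snrDb = Inf, duration = 20)
  t <- (0:999) / 50
  expect_equal(simulatePac(sp),
               sqrt(2) * sin(2 * pi * 10 * t) + sin(2 * pi * 0.05 * t),
               tolerance = 1e-12)
})

test_that("a constant chi vector reproduces the static generator exactly", {
  n <- 1000
  sp1 <- syntheticSpec(chi = 0.4, seed = 9)
  sp2 <- syntheticSpec(chi = rep(0.4, n), seed = 9)
  expect_identical(simulatePac(sp1), simulatePac(sp2))
})

test_that("square-wave coupling modulates the envelope only when on", {
  fs <- 50; dur <- 240; n <- dur * fs
  chi <- couplingProfile(n, fs, "square", hi = 0.8, period = 120)
  sp <- syntheticSpec(chi = chi, snrDb = Inf, duration = dur)
  pa <- extractPhaseAmp(simulatePac(sp), fs, c(0.03, 0.07), c(8, 12))
  on <- which(chi == 0.8); off <- which(chi == 0)
  on <- on[on > n * 0.05 & on < n * 0.95]
  off <- off[off > n * 0.05 & off < n * 0.95]
  expect_gt(var(pa$amplitude[on]) / var(pa$amplitude[off]), 5)
})

test_that("ramp coupling raises the phase-amplitude association over thirds", {
  fs <- 50; dur <- 240; n <- dur * fs
  chi <- couplingProfile(n, fs, "ramp", hi = 0.8)
  sp <- syntheticSpec(chi = chi, snrDb = Inf, duration = dur, seed = 2)
  pa <- extractPhaseAmp(simulatePac(sp), fs, c(0.03, 0.07), c(8, 12))
  thirds <- split(seq_len(n), cut(seq_len(n), 3))
  assoc <- vapply(thirds, function(ix)
    ndpac(pa$amplitude[ix], pa$phase[ix]), numeric(1))
  expect_true(all(diff(assoc) > 0))
})

test_that("the envelope identity holds for constant chi without noise", {
  fs <- 50; dur <- 200; n <- dur * fs
  sp <- syntheticSpec(chi = 0.3, snrDb = Inf, duration = dur)
  pa <- extractPhaseAmp(simulatePac(sp), fs, c(0.03, 0.07), c(8, 12))
  t <- (0:(n - 1)) / fs
  af <- modulatedAmplitude(0.3, 0.05, t)
  int <- seq(round(n * 0.1), round(n * 0.9))
  expect_lt(sqrt(mean((pa$amplitude - af)[int]^2)) / sqrt(mean(af^2)),
            0.05)
})

test_that("trial sets have the right shape, jitter, and alignment behavior", {
  fs <- 50; dur <- 60; n <- dur * fs
  chi <- couplingProfile(n, fs, "square", hi = 0.8, period = 40)
  sp <- syntheticSpec(chi = chi, snrDb = 10, duration = dur, seed = 5)
  tr <- simulateTrials(sp, 100, c(1, 100))
  expect_identical(dim(tr), c(100L, as.integer(n)))
  expect_true(all(tr@jitter >= 1 & tr@jitter <= 100))

  tr1 <- simulateTrials(sp, 1, c(0, 0))
  expect_identical(dim(tr1@data), c(1L, as.integer(n)))

  # aligned trials average to a sharper envelope than jittered ones
  sharp <- function(ts) {
    m <- colMeans(ts@data)
    env <- amplitude(analyticSignal(bandpassFilter(m, c(8, 12), fs), fs))
    var(env[round(n * 0.1):round(n * 0.9)])
  }
  spf <- sp; spf@chi <- rep(0.8, n)
  expect_gt(sharp(simulateTrials(spf, 30, c(0, 0))),
            sharp(simulateTrials(spf, 30, c(1, 100))))
  expect_error(simulateTrials(sp, 5, c(1, n + 1)), "invalid jitter")
})
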