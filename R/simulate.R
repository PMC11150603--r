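## Synthetic phase-amplitude-coupled signal generator:
##   x(t) = A_f(t) sin(2 pi f_high t) + A_s sin(2 pi f_low t) + eta(t)
##   A_f(t) = chi(t) sin(2 pi f_low t) + sqrt(2 - chi(t)^2)
## with Gaussian noise scaled to a target SNR. Defaults mimic gut-brain
## coupling: a 10 Hz (alpha-band-like) carrier modulated by the 0.05 Hz
## gastric slow wave, sampled at 50 Hz, 0 dB SNR.

#' Construct a synthetic coupled-signal specification
#'
#' @param fHigh Fast (carrier) frequency, Hz.
#' @param fLow Slow (modulating) frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param duration Signal length, seconds.
#' @param As Amplitude of the additive slow component.
#' @param chi Coupling coefficient in `[0, 1]`: a scalar, or one value per
#'   sample for time-varying coupling.
#' @param snrDb Target SNR in dB (`Inf` for a noiseless signal).
#' @param seed RNG seed (`NA` to use the current RNG state).
#' @return A [SyntheticSpec-class].
#' @export
syntheticSpec <- function(fHigh = 10, fLow = 0.05, fs = 50, duration = 20,
                          As = 1, chi = 0.3, snrDb = 0, seed = NA) {
  new("SyntheticSpec", fHigh = fHigh, fLow = fLow, fs = fs,
      duration = duration, As = As, chi = chi, snrDb = snrDb,
      seed = as.numeric(seed))
}

#' Modulated carrier amplitude
#'
#' \eqn{A_f(t) = \chi(t) \sin(2\pi f_{low} t) + \sqrt{2 - \chi(t)^2}},
#' strictly positive for \eqn{\chi < 1} and touching zero at the trough when
#' \eqn{\chi = 1}.
#'
#' @param chi Coupling coefficient(s) in `[0, 1]` (scalar or per-sample).
#' @param fLow Slow frequency, Hz.
#' @param t Time vector, seconds.
#' @return Numeric envelope, same length as `t`.
#' @export
modulatedAmplitude <- function(chi, fLow, t) {
  if (any(chi < 0 | chi > 1))
    stop("invalid coupling: chi must lie in [0, 1]", call. = FALSE)
  chi * sin(2 * pi * fLow * t) + sqrt(2 - chi^2)
}

#' Generate a synthetic coupled signal
#'
#' Deterministic given the spec's seed. The noise variance is set so that
#' \eqn{10 \log_{10}(P_{signal}/\sigma^2)} equals the requested SNR, with
#' \eqn{P_{signal}} the empirical mean square of the noiseless sum.
#' Time-varying coupling is obtained by supplying a per-sample `chi` in the
#' spec; a constant `chi` reproduces the static generator exactly.
#'
#' @param spec A [SyntheticSpec-class].
#' @return Numeric signal of length `round(duration * fs)`.
#' @examples
#' x <- simulatePac(syntheticSpec(chi = 0.3, seed = 7))
#' length(x)  # 20 s at 50 Hz
#' @export
simulatePac <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  n <- round(spec@duration * spec@fs)
  t <- (seq_len(n) - 1) / spec@fs
  af <- modulatedAmplitude(spec@chi, spec@fLow, t)
  clean <- af * sin(2 * pi * spec@fHigh * t) +
    spec@As * sin(2 * pi * spec@fLow * t)
  if (!is.finite(spec@snrDb)) return(clean)
  sigma <- sqrt(mean(clean^2) / 10^(spec@snrDb / 10))
  if (!is.na(spec@seed)) set.seed(as.integer(spec@seed))
  clean + stats::rnorm(n, 0, sigma)
}

#' Time-varying coupling profiles
#'
#' Square-wave or ramp coupling coefficient sequences used to probe
#' time-resolved PAC estimation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @param type `"square"` (alternating `lo`/`hi`, starting at `lo`),
#'   `"ramp"` (linear `lo` to `hi`), or `"constant"` (`hi` throughout).
#' @param hi,lo Coupling levels in `[0, 1]`.
#' @param period Square-wave period in seconds (one `lo` plus one `hi`
#'   segment); ignored otherwise.
#' @return Numeric vector of per-sample chi values.
#' @export
couplingProfile <- function(n, fs, type = c("square", "ramp", "constant"),
                            hi = 0.8, lo = 0, period = NULL) {
  type <- match.arg(type)
  t <- (seq_len(n) - 1) / fs
  switch(type,
    square = {
      if (is.null(period)) period <- 2 * n / fs / 4
      ifelse((t %/% (period / 2)) %% 2 == 0, lo, hi)
    },
    ramp = lo + (hi - lo) * (seq_len(n) - 1) / (n - 1),
    constant = rep(hi, n))
}

#' Generate a jittered multi-trial dataset
#'
#' Each trial is an independent noise realization of the (possibly
#' time-varying-coupling) generator, then circularly shifted by a per-trial
#' jitter drawn uniformly from `jitterRange` (in samples), emulating stimulus
#' timing jitter in event-related recordings. Per-trial noise seeds are
#' derived from the master seed by a counter, so generation is reproducible
#' trial-by-trial.
#'
#' @param spec A [SyntheticSpec-class].
#' @param nTrials Number of trials.
#' @param jitterRange Integer (min, max) jitter in samples; `c(0, 0)` for
#'   perfectly aligned trials.
#' @param jitterMode `"circular"` (wrap-around shift) or `"delay"` (onset
#'   delay, zero-padded at the start).
#' @return A [TrialSet-class].
#' @export
simulateTrials <- function(spec, nTrials, jitterRange = c(1L, 100L),
                           jitterMode = c("circular", "delay")) {
  stopifnot(is(spec, "SyntheticSpec"), nTrials >= 1L)
  jitterMode <- match.arg(jitterMode)
  n <- round(spec@duration * spec@fs)
  if (any(jitterRange < 0) || jitterRange[1] > jitterRange[2])
    stop("invalid jitter: need 0 <= min <= max", call. = FALSE)
  if (jitterRange[2] >= n)
    stop("invalid jitter: exceeds trial length", call. = FALSE)
  if (!is.na(spec@seed)) set.seed(as.integer(spec@seed))
  jit <- if (jitterRange[1] == jitterRange[2])
    rep(as.integer(jitterRange[1]), nTrials)
  else
    sample(seq.int(jitterRange[1], jitterRange[2]), nTrials, replace = TRUE)
  data <- matrix(NA_real_, nTrials, n)
  for (i in seq_len(nTrials)) {
    speci <- spec
    if (!is.na(spec@seed)) speci@seed <- spec@seed + i
    xi <- simulatePac(speci)
    data[i, ] <- if (jit[i] == 0L) xi
    else if (jitterMode == "circular")
      c(xi[(n - jit[i] + 1L):n], xi[1:(n - jit[i])])
    else
      c(numeric(jit[i]), xi[1:(n - jit[i])])
  }
  new("TrialSet", data = data, fs = spec@fs, jitter = as.integer(jit),
      spec = spec)
}
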