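#' Analytic signal: instantaneous amplitude and phase
#'
#' Computes the analytic signal \eqn{z(t) = x(t) + j H\{x(t)\}} by the
#' frequency-domain construction (negative frequencies zeroed, positive
#' doubled) and returns the instantaneous amplitude \eqn{A(t) = |z(t)|} and
#' phase \eqn{\phi(t) = \arg z(t)} wrapped to \eqn{[-\pi, \pi)}.
#'
#' @param x Real numeric signal of length at least 2.
#' @param fs Sampling rate in Hz.
#' @param band Optional passband annotation (Hz) carried on the result.
#' @return An [AnalyticSeries-class].
#' @examples
#' fs <- 100
#' t <- seq(0, 2, by = 1 / fs)
#' z <- analyticSignal(cos(2 * pi * 7 * t), fs)
#' range(amplitude(z)[20:180])  # ~1 away from edges
#' @export
analyticSignal <- function(x, fs, band = NULL) {
  checkFinite(x, "signal")
  n <- length(x)
  if (n < 2L) stop("invalid input: signal must have length >= 2",
                   call. = FALSE)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(stats::fft(x) * h, inverse = TRUE) / n
  amp <- Mod(z)
  if (max(amp) < 1e-300)
    message("degenerate signal: zero amplitude everywhere, phase undefined")
  new("AnalyticSeries", amplitude = amp, phase = wrapPhase(Arg(z)),
      fs = fs, band = band)
}

#' Extract a phase/amplitude pair from a broadband signal
#'
#' Band-filters the signal around the slow and fast bands (zero-phase
#' Butterworth, second-order sections) and returns the instantaneous phase of
#' the slow band together with the instantaneous amplitude envelope of the
#' fast band, time-aligned and of equal length. These are the inputs of every
#' PAC measure in the package.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lowBand Length-2 slow (phase) passband in Hz.
#' @param highBand Length-2 fast (amplitude) passband in Hz.
#' @param order Butterworth prototype order.
#' @param passes Forward-backward passes (1 or 2).
#' @return List with `phase` (numeric), `amplitude` (numeric), and the two
#'   underlying [AnalyticSeries-class] objects `slow` and `fast`.
#' @examples
#' spec <- syntheticSpec(chi = 0.3, snrDb = Inf, seed = 1)
#' x <- simulatePac(spec)
#' pa <- extractPhaseAmp(x, fs = 50, c(0.03, 0.07), c(8, 12))
#' @export
extractPhaseAmp <- function(x, fs, lowBand, highBand, order = 4,
                            passes = 1) {
  if (isTRUE(all(lowBand == highBand)))
    stop("invalid bands: slow and fast bands must differ", call. = FALSE)
  slow <- analyticSignal(bandpassFilter(x, lowBand, fs, order, passes),
                         fs, band = lowBand)
  fast <- analyticSignal(bandpassFilter(x, highBand, fs, order, passes),
                         fs, band = highBand)
  list(phase = phase(slow), amplitude = amplitude(fast),
       slow = slow, fast = fast)
}
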