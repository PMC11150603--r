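## Reference PAC / cross-frequency coupling measures used as comparators.

#' Phase-locking value
#'
#' \eqn{PLV = T^{-1} |\sum_t e^{i(\phi_1(t) - \phi_2(t))}|}: the modulus of
#' the mean unit phasor of the phase difference. A phase-phase coupling
#' measure, blind to amplitude, and therefore a negative control for
#' phase-amplitude coupling.
#'
#' @param phi1,phi2 Phase sequences (radians), equal length.
#' @return Value in `[0, 1]`.
#' @export
plv <- function(phi1, phi2) {
  if (length(phi1) == 0L) stop("invalid input: empty phase", call. = FALSE)
  stopifnot(length(phi1) == length(phi2))
  Mod(mean(exp(1i * (phi1 - phi2))))
}

#' Mean vector length
#'
#' \eqn{MVL = T^{-1} |\sum_t a_1(t) e^{i\phi_2(t)}|}: the modulus of the
#' amplitude-weighted mean phasor.
#'
#' @param a1 Non-negative amplitude sequence.
#' @param phi2 Phase sequence, equal length.
#' @return Non-negative value (homogeneous of degree 1 in the amplitude).
#' @export
mvl <- function(a1, phi2) {
  if (length(a1) == 0L) stop("invalid input: empty amplitude", call. = FALSE)
  stopifnot(length(a1) == length(phi2))
  Mod(mean(a1 * exp(1i * phi2)))
}

#' Normalized direct PAC
#'
#' The mean vector length of the standardized amplitude series (mean
#' subtracted, unit variance), which removes the scale and offset dependence
#' of the raw MVL.
#'
#' @inheritParams mvl
#' @return Non-negative value.
#' @export
ndpac <- function(a1, phi2) {
  if (length(a1) == 0L) stop("invalid input: empty amplitude", call. = FALSE)
  stopifnot(length(a1) == length(phi2))
  s <- stats::sd(a1)
  if (!is.finite(s) || s == 0)
    stop("degenerate input: amplitude has zero variance", call. = FALSE)
  mvl0 <- Mod(mean((a1 - mean(a1)) / s * exp(1i * phi2)))
  mvl0
}

#' Tort modulation index
#'
#' Bins phase into `nBins` equal bins on \eqn{[-\pi, \pi)}, averages the
#' amplitude per bin, normalizes the profile to a probability mass function
#' `P`, and returns \eqn{D(P \| U)/\log N} — the KL divergence from the
#' uniform profile, scaled to `[0, 1]`.
#'
#' @param a Non-negative amplitude sequence.
#' @param theta Phase sequence in \eqn{[-\pi, \pi)}, equal length.
#' @param nBins Number of phase bins (default 18, the convention of the
#'   original modulation-index literature).
#' @return Value in `[0, 1]`.
#' @export
tortMI <- function(a, theta, nBins = 18L) {
  if (nBins < 2L) stop("need at least 2 bins", call. = FALSE)
  stopifnot(length(a) == length(theta))
  edges <- seq(-pi, pi, length.out = nBins + 1L)
  bin <- findInterval(theta, edges, rightmost.closed = FALSE,
                      all.inside = TRUE)
  meanAmp <- numeric(nBins)
  counts <- tabulate(bin, nBins)
  if (any(counts == 0L))
    warning("empty phase bin(s); treated as zero-mass (0 log 0 = 0)")
  sums <- vapply(seq_len(nBins), function(b) sum(a[bin == b]), numeric(1))
  meanAmp[counts > 0L] <- sums[counts > 0L] / counts[counts > 0L]
  tot <- sum(meanAmp)
  if (tot <= 0) return(0)
  P <- meanAmp / tot
  kl <- sum(ifelse(P > 0, P * log(P * nBins), 0))
  kl / log(nBins)
}

#' One-call PAC by any supported measure
#'
#' Convenience dispatcher computing a scalar PAC value from a phase and an
#' amplitude series (or two phase series for `"plv"`).
#'
#' @param amplitude Fast-band amplitude envelope (ignored for `"plv"` unless
#'   `phiFast` is missing).
#' @param phase Slow-band phase.
#' @param method One of `"gamma-mi"`, `"plv"`, `"mvl"`, `"ndpac"`,
#'   `"tortmi"`.
#' @param phiFast Fast-band phase series, required for `"plv"`.
#' @param K Fourier order (or candidate set, see `selectK`) for
#'   `"gamma-mi"`.
#' @param selectK When `TRUE`, `K` is treated as a candidate set and the
#'   order is chosen by [selectOrder()].
#' @param nBins Bins for `"tortmi"`.
#' @param gridSize Phase grid for `"gamma-mi"`.
#' @return A [PacResult-class].
#' @export
pacMeasure <- function(amplitude, phase, method = c("gamma-mi", "plv",
                       "mvl", "ndpac", "tortmi"), phiFast = NULL, K = 2,
                       selectK = FALSE, nBins = 18L, gridSize = 256L) {
  method <- match.arg(method)
  val <- switch(method,
    "gamma-mi" = {
      model <- if (selectK) bestFit(selectOrder(amplitude, phase, K))
               else fitGammaGlm(amplitude, phase, K)
      return(mutualInfoPac(amplitude, phase, model, gridSize = gridSize))
    },
    "plv" = {
      if (is.null(phiFast))
        stop("plv needs the fast-band phase (phiFast)", call. = FALSE)
      plv(phiFast, phase)
    },
    "mvl" = mvl(amplitude, phase),
    "ndpac" = ndpac(amplitude, phase),
    "tortmi" = tortMI(amplitude, phase, nBins))
  new("PacResult", method = method, value = val)
}
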