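## Significance machinery: circular-shift surrogate nulls, p-values,
## step-up false-discovery-rate control, and the comodulogram band scan.

#' Circular time shift of a series
#'
#' Shifts a series circularly by a random offset of at least `minShiftS`
#' seconds (in either direction). Used to build surrogate data: shifting the
#' slow signal destroys its temporal alignment with the fast amplitude while
#' preserving it as a physically plausible oscillator (the marginal
#' distribution is exactly unchanged).
#'
#' @param x Numeric series (the slow signal or its phase).
#' @param fs Sampling rate, Hz.
#' @param minShiftS Minimum shift in seconds.
#' @param offset Optional explicit offset in samples (bypasses the RNG).
#' @return Shifted series, same length.
#' @export
surrogateShift <- function(x, fs, minShiftS, offset = NULL) {
  n <- length(x)
  minSamp <- ceiling(minShiftS * fs)
  if (minSamp >= n)
    stop("invalid shift: minimum shift must be below the duration",
         call. = FALSE)
  if (is.null(offset)) {
    lo <- max(minSamp, 1L)
    offset <- sample(seq.int(lo, n - lo), 1L)
  }
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(x)
  c(x[(n - offset + 1L):n], x[1:(n - offset)])
}

#' Surrogate null distribution of a PAC measure
#'
#' Recomputes a PAC measure after repeated random circular shifts of the
#' phase series. Optionally fits a gamma distribution to the surrogate
#' values (for tail p-values from few surrogates); the fit is retained only
#' when a Kolmogorov-Smirnov check against it does not reject at the 0.05
#' level.
#'
#' @param amplitude Fast-band amplitude sequence.
#' @param phase Slow-band phase sequence.
#' @param measure Function `(amplitude, phase) -> numeric` computing the
#'   PAC value (it refits any model internally).
#' @param nSurrogates Number of surrogates (at least 20 for gamma fitting).
#' @param fs Sampling rate, Hz.
#' @param minShiftS Minimum shift in seconds.
#' @param fitGamma Attempt the parametric gamma null.
#' @return A [SurrogateNull-class].
#' @export
surrogateNull <- function(amplitude, phase, measure, nSurrogates, fs,
                          minShiftS, fitGamma = TRUE) {
  vals <- vapply(seq_len(nSurrogates), function(i)
    measure(amplitude, surrogateShift(phase, fs, minShiftS)), numeric(1))
  gam <- NULL
  if (stats::sd(vals) < 1e-14) {
    warning("degenerate surrogate null: all values equal")
  } else if (fitGamma && nSurrogates >= 20L) {
    gam <- tryCatch({
      est <- suppressWarnings(
        MASS::fitdistr(vals, "gamma",
                       start = momentGammaStart(vals), lower = 1e-10))
      ks <- suppressWarnings(
        stats::ks.test(vals, "pgamma", shape = est$estimate[["shape"]],
                       rate = est$estimate[["rate"]]))
      if (ks$p.value < 0.05) {
        warning("gamma null rejected by KS check; ",
                "falling back to empirical p-values")
        NULL
      } else list(shape = est$estimate[["shape"]],
                  rate = est$estimate[["rate"]], ksP = ks$p.value)
    }, error = function(e) NULL)
  }
  new("SurrogateNull", values = vals, minShift = minShiftS,
      gammaNull = gam)
}

momentGammaStart <- function(x) {
  m <- mean(x); v <- stats::var(x)
  list(shape = max(m^2 / v, 1e-3), rate = max(m / v, 1e-3))
}

#' P-value against a surrogate null
#'
#' Empirical mode uses the add-one convention
#' \eqn{p = (1 + \#\{surrogates \ge observed\}) / (1 + N)}, which avoids
#' p = 0; `proportion` reports the raw exceedance proportion. Gamma mode uses
#' the upper tail of the fitted gamma null (only available when the KS check
#' accepted it).
#'
#' @param observed Observed PAC value.
#' @param null A [SurrogateNull-class].
#' @param mode `"auto"` (gamma when accepted, else empirical),
#'   `"gamma"`, `"empirical"`, or `"proportion"`.
#' @return P-value in `(0, 1]` (`[0, 1]` for `"proportion"`).
#' @export
surrogatePValue <- function(observed, null,
                            mode = c("auto", "gamma", "empirical",
                                     "proportion")) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (!is.null(null@gammaNull)) "gamma" else "empirical"
  if (mode == "gamma") {
    if (is.null(null@gammaNull))
      stop("no accepted gamma null available", call. = FALSE)
    return(stats::pgamma(observed, shape = null@gammaNull$shape,
                         rate = null@gammaNull$rate, lower.tail = FALSE))
  }
  k <- sum(null@values >= observed)
  if (mode == "proportion") k / length(null@values)
  else (1 + k) / (1 + length(null@values))
}

nullSummaryList <- function(observed, null, mode = "auto") {
  list(n = length(null@values), mean = mean(null@values),
       sd = stats::sd(null@values),
       p = surrogatePValue(observed, null, mode))
}

fdrStepUp <- function(p, q, method) {
  N <- length(p)
  if (N == 0L)
    return(new("FdrReport", p = numeric(0), pSorted = numeric(0),
               adjusted = numeric(0), criticalIndex = 0L,
               rejected = logical(0), q = q, method = method))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  level <- if (method == "BY") q / sum(1 / seq_len(N)) else q
  ord <- order(p)
  ps <- p[ord]
  i <- seq_len(N)
  below <- which(ps < level * i / N)
  cIdx <- if (length(below)) max(below) else 0L
  rejected <- logical(N)
  if (cIdx > 0L) rejected[ord[seq_len(cIdx)]] <- TRUE
  new("FdrReport", p = p, pSorted = ps, adjusted = ps * N / i,
      criticalIndex = as.integer(cIdx), rejected = rejected, q = q,
      method = method)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up procedure: with sorted p-values, the critical index is the
#' largest rank i with \eqn{p_{(i)} < q i / N}; every hypothesis of rank up
#' to the critical index is rejected — including any whose p-value lies
#' above the line at a smaller rank. Adjusted values \eqn{p_{(i)} N / i} are
#' reported as computed (not monotonized).
#'
#' @param p Vector of p-values.
#' @param q Target FDR level (default 0.05).
#' @return An [FdrReport-class].
#' @export
benjaminiHochberg <- function(p, q = 0.05) fdrStepUp(p, q, "BH")

#' Benjamini-Yekutieli FDR control
#'
#' The Benjamini-Hochberg step-up run at the deflated level
#' \eqn{q / \sum_{i=1}^N 1/i}, valid under arbitrary dependence of the
#' p-values and therefore stricter.
#'
#' @inheritParams benjaminiHochberg
#' @return An [FdrReport-class].
#' @export
benjaminiYekutieli <- function(p, q = 0.05) fdrStepUp(p, q, "BY")

#' Band-scan geometry
#'
#' Enumerates passbands of a fixed width whose centers step from
#' `start + width/2` up to `stop`, the scan geometry used for
#' comodulograms (e.g. width 4, step 2 from 0.5 to 20.5 Hz gives ten slow
#' bands starting at 0.5, 2.5, ..., 18.5 Hz).
#'
#' @param start First band's lower edge, Hz.
#' @param stop Last allowed band center, Hz.
#' @param width Band width, Hz.
#' @param step Center-to-center step, Hz.
#' @return Matrix with columns `low`, `high`.
#' @export
frequencyBands <- function(start, stop, width, step) {
  starts <- seq(start, stop - width / 2, by = step)
  cbind(low = starts, high = starts + width)
}

#' Comodulogram band scan
#'
#' Computes a PAC measure over every pair of slow and fast passbands,
#' optionally with circular-shift surrogate p-values per cell and an FDR
#' significance mask. Cell values are independent of scan order.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @param lowSpec `c(start, stop, width, step)` in Hz for the slow bands
#'   (see [frequencyBands()]).
#' @param highSpec `c(start, fUpper, width, step)` in Hz for the fast
#'   bands; `fUpper` (the highest allowed band center) is supplied by the
#'   user, e.g. from a prior spectral-peak analysis.
#' @param method PAC measure, see [pacMeasure()].
#' @param K Fourier order for `"gamma-mi"` cells.
#' @param nBins Bins for `"tortmi"`.
#' @param nSurrogates Surrogates per cell (0 disables inference: all cells
#'   significant, p-values NA).
#' @param minShiftS Minimum surrogate shift, seconds.
#' @param pMode P-value mode, see [surrogatePValue()].
#' @param fdrMethod `"BH"` or `"BY"`.
#' @param q FDR level.
#' @param filterOrder,passes Filter settings.
#' @param gridSize Phase grid for `"gamma-mi"`.
#' @return A [Comodulogram-class].
#' @export
comodulogram <- function(x, fs, lowSpec, highSpec,
                         method = c("gamma-mi", "tortmi", "mvl", "ndpac",
                                    "plv"),
                         K = 2, nBins = 18L, nSurrogates = 0L,
                         minShiftS = 1, pMode = "auto", fdrMethod = "BH",
                         q = 0.05, filterOrder = 4, passes = 1,
                         gridSize = 256L) {
  method <- match.arg(method)
  lowBands <- frequencyBands(lowSpec[1], lowSpec[2], lowSpec[3], lowSpec[4])
  highBands <- frequencyBands(highSpec[1], highSpec[2], highSpec[3],
                              highSpec[4])
  if (max(highBands) >= fs / 2 || max(lowBands) >= fs / 2)
    stop("invalid spec: bands collide with the Nyquist frequency",
         call. = FALSE)
  m <- nrow(lowBands); n <- nrow(highBands)

  slowPhase <- lapply(seq_len(m), function(i) {
    s <- bandpassFilter(x, lowBands[i, ], fs, filterOrder, passes)
    phase(analyticSignal(s, fs))
  })
  fast <- lapply(seq_len(n), function(j) {
    f <- bandpassFilter(x, highBands[j, ], fs, filterOrder, passes)
    z <- analyticSignal(f, fs)
    list(amp = amplitude(z), phi = phase(z))
  })

  cellValue <- function(amp, phi, phiFast) {
    switch(method,
      "gamma-mi" = pacValue(mutualInfoPac(amp, phi, K = K,
                                          gridSize = gridSize)),
      "tortmi" = tortMI(amp, phi, nBins),
      "mvl" = mvl(amp, phi),
      "ndpac" = ndpac(amp, phi),
      "plv" = plv(phiFast, phi))
  }

  values <- matrix(NA_real_, m, n)
  pvals <- matrix(NA_real_, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    amp <- fast[[j]]$amp
    phi <- slowPhase[[i]]
    values[i, j] <- cellValue(amp, phi, fast[[j]]$phi)
    if (nSurrogates > 0L) {
      null <- surrogateNull(amp, phi,
        function(a, p) cellValue(a, p, fast[[j]]$phi),
        nSurrogates, fs, minShiftS)
      pvals[i, j] <- surrogatePValue(values[i, j], null, pMode)
    }
  }

  if (nSurrogates > 0L) {
    rep_ <- fdrStepUp(as.numeric(pvals), q, match.arg(fdrMethod,
                                                      c("BH", "BY")))
    mask <- matrix(rep_@rejected, m, n)
  } else {
    mask <- matrix(TRUE, m, n)
  }
  new("Comodulogram", lowBands = lowBands, highBands = highBands,
      values = values, pValues = pvals, mask = mask, method = method)
}
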