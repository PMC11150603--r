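## Time-resolved PAC: the information density evaluated along the sample
## path (idPAC), and the multi-trial event-related variant (ERPAC) that at
## each time point pools a full slow-oscillation cycle across trials.

#' Raw information-density PAC trace
#'
#' \eqn{idPAC(t) = i(y_t, \theta_t)}: the information density evaluated at
#' every sample pair under the fitted model. May be negative; its time mean
#' approximates the mutual information of the same data and model.
#'
#' @param y Positive amplitude sequence.
#' @param theta Phase sequence, same length.
#' @param model A [GammaGlmFit-class]; when `NULL`, fit on the data at
#'   order `K`.
#' @param K Fourier order used when `model` is `NULL`.
#' @param gridSize Phase grid resolution for the marginal density.
#' @param chunk Block size for the grid evaluation.
#' @return Numeric vector of raw idPAC values (nats).
#' @export
idPac <- function(y, theta, model = NULL, K = 2, gridSize = 256L,
                  chunk = 8192L) {
  stopifnot(length(y) == length(theta))
  y <- clipAmplitude(y)
  if (is.null(model)) model <- fitGammaGlm(y, theta, K, clip = FALSE)
  grid <- phaseGrid(gridSize)
  out <- numeric(length(y))
  idx <- seq_along(y)
  for (blk in split(idx, ceiling(idx / chunk)))
    out[blk] <- informationDensity(y[blk], theta[blk], model, grid)
  out
}

#' Post-process a raw idPAC trace
#'
#' The slow-oscillation frequency leaks into the raw information density, so
#' the trace is smoothed below the phase frequency — either a zero-phase
#' Butterworth lowpass with cutoff below `phaseFreq`, or a Gaussian kernel of
#' standard deviation `sigma` seconds — and then truncated at zero (the
#' mutual information is non-negative; negative pointwise excursions are
#' estimation noise).
#'
#' @param raw Raw idPAC trace.
#' @param fs Sampling rate of the trace, Hz.
#' @param phaseFreq Frequency of the phase (slow) signal, Hz.
#' @param mode `"lowpass"` or `"gaussian"`.
#' @param cutoff Lowpass cutoff in Hz (default `0.8 * phaseFreq`); must be
#'   below `phaseFreq`.
#' @param sigma Gaussian kernel standard deviation in seconds
#'   (default 0.08).
#' @return An [IdPacTrace-class].
#' @export
postprocessIdPac <- function(raw, fs, phaseFreq,
                             mode = c("lowpass", "gaussian"),
                             cutoff = 0.8 * phaseFreq, sigma = 0.08) {
  mode <- match.arg(mode)
  if (phaseFreq >= fs / 2)
    stop("phaseFreq must be below the Nyquist frequency", call. = FALSE)
  if (mode == "lowpass") {
    if (cutoff >= phaseFreq)
      stop("invalid cutoff: must be below the phase frequency",
           call. = FALSE)
    sm <- lowpassFilter(raw, cutoff, fs)
    pp <- list(mode = "lowpass", cutoff = cutoff)
  } else {
    sm <- gaussianSmooth(raw, fs, sigma)
    pp <- list(mode = "gaussian", sigma = sigma)
  }
  new("IdPacTrace", raw = raw, processed = pmax(sm, 0), fs = fs,
      postproc = pp)
}

# zero-lag Gaussian kernel smoothing with reflection padding
gaussianSmooth <- function(x, fs, sigma) {
  half <- max(1L, ceiling(4 * sigma * fs))
  k <- stats::dnorm(seq(-half, half) / fs, sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  half <- min(half, n - 1L)
  k <- k[(length(k) + 1L) %/% 2L + seq(-half, half)]
  k <- k / sum(k)
  xp <- c(x[seq(half + 1L, 2L)], x, x[seq(n - 1L, n - half)])
  as.numeric(stats::filter(xp, k, sides = 2L))[half + seq_len(n)]
}

#' Phase and amplitude matrices of a trial set
#'
#' Filters every trial to the slow and fast bands and extracts per-trial
#' phase and amplitude, returning matrices shaped like the trial data.
#'
#' @param trials A [TrialSet-class] or a numeric trials-by-time matrix.
#' @param fs Sampling rate (taken from the `TrialSet` when omitted).
#' @param lowBand,highBand Passbands in Hz.
#' @param order,passes Filter settings, see [bandpassFilter()].
#' @return List with matrices `phase` and `amplitude`.
#' @export
trialPhaseAmp <- function(trials, lowBand, highBand, fs = NULL, order = 4,
                          passes = 1) {
  if (is(trials, "TrialSet")) {
    fs <- trials@fs
    trials <- trials@data
  }
  if (is.null(fs)) stop("fs required for a plain matrix", call. = FALSE)
  ph <- am <- matrix(NA_real_, nrow(trials), ncol(trials))
  for (i in seq_len(nrow(trials))) {
    pa <- extractPhaseAmp(trials[i, ], fs, lowBand, highBand, order, passes)
    ph[i, ] <- pa$phase
    am[i, ] <- pa$amplitude
  }
  list(phase = ph, amplitude = am)
}

mirrorPad <- function(m, pad) {
  n <- ncol(m)
  if (pad <= 0L) return(m)
  if (pad >= n) stop("padding request exceeds trial length", call. = FALSE)
  cbind(m[, seq(pad + 1L, 2L), drop = FALSE], m,
        m[, seq(n - 1L, n - pad), drop = FALSE])
}

#' Event-related PAC at one time point
#'
#' Pools `windowLen` consecutive samples (one full slow cycle) centered at
#' column `t` across all trials, fits one gamma GLM on the pooled
#' phase/amplitude samples, and evaluates the information density at column
#' `t` for each trial.
#'
#' @param phaseMat,ampMat Trials-by-time phase and amplitude matrices.
#' @param t Center column (1-based).
#' @param windowLen Odd window length in samples.
#' @param K Fourier order of the pooled fit.
#' @param gridSize Phase grid resolution.
#' @return Numeric vector of length `nrow(phaseMat)` of raw idPAC values.
#' @export
erpacAt <- function(phaseMat, ampMat, t, windowLen, K = 2,
                    gridSize = 256L) {
  h <- (windowLen - 1L) %/% 2L
  if (windowLen %% 2L != 1L)
    stop("windowLen must be odd", call. = FALSE)
  if (t - h < 1L || t + h > ncol(phaseMat))
    stop("window exceeds matrix extent; pad the matrices", call. = FALSE)
  cols <- (t - h):(t + h)
  yw <- clipAmplitude(as.numeric(ampMat[, cols]))
  thw <- as.numeric(phaseMat[, cols])
  fit <- fitGammaGlm(yw, thw, K, clip = FALSE)
  informationDensity(clipAmplitude(ampMat[, t]), phaseMat[, t], fit,
                     phaseGrid(gridSize))
}

#' Event-related PAC trace
#'
#' Applies the pooled-window ERPAC estimator at every `stride`-th column of
#' the trial matrices, after mirror-padding the edges so the window fits
#' everywhere. Each trial's raw trace is then smoothed below the slow
#' frequency and truncated at zero, and the trial mean is reported. Window
#' length is one slow cycle, `round(fs / fLow)` forced odd so the evaluated
#' column is the exact window midpoint.
#'
#' @inheritParams erpacAt
#' @param fs Sampling rate, Hz.
#' @param fLow Slow (phase) frequency, Hz.
#' @param stride Evaluate every `stride`-th column (1 = every column).
#' @param padLen Samples mirrored at each edge (default half a window).
#' @param cutoff Post-processing lowpass cutoff, Hz (default `0.8 * fLow`).
#' @return An [ErpacResult-class].
#' @export
erpacTrace <- function(phaseMat, ampMat, fs, fLow, K = 2, stride = 1L,
                       padLen = NULL, cutoff = 0.8 * fLow,
                       gridSize = 256L) {
  stopifnot(all(dim(phaseMat) == dim(ampMat)))
  wlen <- round(fs / fLow)
  if (wlen %% 2L == 0L) wlen <- wlen + 1L
  h <- (wlen - 1L) %/% 2L
  if (is.null(padLen)) padLen <- h
  if (padLen < h)
    stop("padLen must cover half a window", call. = FALSE)
  padLen <- as.integer(padLen)
  php <- mirrorPad(phaseMat, padLen)
  amp <- mirrorPad(ampMat, padLen)
  n <- ncol(phaseMat)
  cols <- seq(1L, n, by = as.integer(stride))
  nTrials <- nrow(phaseMat)
  raw <- matrix(NA_real_, nTrials, length(cols))

  # pooled fits warm-started from the previous column's weights
  grid <- phaseGrid(gridSize)
  w0 <- NULL
  for (j in seq_along(cols)) {
    tcol <- cols[j] + padLen
    win <- (tcol - h):(tcol + h)
    yw <- clipAmplitude(as.numeric(amp[, win]))
    thw <- as.numeric(php[, win])
    w <- fitWeights(yw, thw, K, init = w0)
    w0 <- w
    alpha <- fitShape(yw, thw, w)
    fit <- new("GammaGlmFit", order = as.integer(K), coef = w,
               shape = alpha, nll = NA_real_, nobs = length(yw),
               angularScale = 1)
    raw[, j] <- informationDensity(clipAmplitude(amp[, tcol]),
                                   php[, tcol], fit, grid)
  }

  fsEff <- fs / stride
  proc <- t(apply(raw, 1L, function(r)
    postprocessIdPac(r, fsEff, fLow, cutoff = cutoff)@processed))
  new("ErpacResult", perTrial = proc, meanTrace = colMeans(proc),
      time = as.integer(cols), windowLen = as.integer(wlen),
      pad = padLen)
}
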