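#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("listOrNULL", c("list", "NULL"))

#' Instantaneous amplitude and phase of a band-filtered signal
#'
#' Holds the analytic-signal decomposition of a narrowband signal: the
#' instantaneous amplitude \eqn{A(t) = |z(t)|} and the instantaneous phase
#' \eqn{\phi(t) = \arg z(t)} of the analytic signal
#' \eqn{z(t) = x(t) + j H\{x(t)\}}, together with the sampling rate and the
#' passband the signal was filtered to.
#'
#' @slot amplitude Non-negative numeric vector, signal units.
#' @slot phase Numeric vector of phases in \eqn{[-\pi, \pi)}, radians.
#' @slot fs Sampling rate in Hz.
#' @slot band Numeric length-2 passband (low, high) in Hz, or `NULL` when the
#'   signal was not band-filtered by this package.
#'
#' @seealso [analyticSignal()], [extractPhaseAmp()]
#' @export
setClass("AnalyticSeries",
  representation(
    amplitude = "numeric",
    phase = "numeric",
    fs = "numeric",
    band = "numericOrNULL"
  )
)

setValidity("AnalyticSeries", function(object) {
  msg <- NULL
  if (length(object@amplitude) != length(object@phase))
    msg <- c(msg, "amplitude and phase must have equal length")
  if (any(object@amplitude < 0))
    msg <- c(msg, "amplitude must be non-negative")
  p <- object@phase
  if (length(p) && (min(p) < -pi || max(p) >= pi))
    msg <- c(msg, "phase must lie in [-pi, pi)")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (!is.null(object@band) &&
      (length(object@band) != 2L || object@band[1] >= object@band[2]))
    msg <- c(msg, "band must be (low, high) with low < high")
  if (is.null(msg)) TRUE else msg
})

#' Fitted gamma GLM of amplitude given phase
#'
#' The conditional model \eqn{Y | \Theta = \theta \sim
#' \mathrm{Gamma}(\alpha, \beta(\theta))} with log link
#' \eqn{\log E[Y|\theta] = L(w;\theta) = R(\theta)^\top w}, where
#' \eqn{R(\theta)} is a Fourier basis of order `K` and the implied rate is
#' \eqn{\beta(\theta) = \alpha e^{-L(w;\theta)}}.
#'
#' @slot order Integer, number of Fourier sine/cosine pairs K.
#' @slot coef Numeric vector of length 2K+1, link-scale weights w
#'   (intercept, then cos/sin pairs).
#' @slot shape Positive scalar, the gamma shape \eqn{\alpha}.
#' @slot nll Value of the negative log-likelihood at the optimum.
#' @slot nobs Number of samples used in the fit.
#' @slot angularScale Multiplier applied to phase inside the basis
#'   (compatibility switch; 1 gives the periodic basis cos(k*theta)).
#'
#' @seealso [fitGammaGlm()], [selectOrder()]
#' @export
setClass("GammaGlmFit",
  representation(
    order = "integer",
    coef = "numeric",
    shape = "numeric",
    nll = "numeric",
    nobs = "integer",
    angularScale = "numeric"
  ),
  prototype(angularScale = 1)
)

setValidity("GammaGlmFit", function(object) {
  msg <- NULL
  if (object@order < 0L) msg <- c(msg, "order must be >= 0")
  if (length(object@coef) != 2L * object@order + 1L)
    msg <- c(msg, "coef must have length 2K+1")
  if (length(object@shape) != 1L || !is.finite(object@shape) ||
      object@shape <= 0)
    msg <- c(msg, "shape must be a positive finite scalar")
  if (is.null(msg)) TRUE else msg
})

#' Model order selection report
#'
#' Result of scanning candidate Fourier orders with the minimum description
#' length criterion: the penalized normalized negative log-likelihood
#' \deqn{PNNLL(K) = NLL/T + (2K+1) \log(T) / (2T)}
#' is minimized over the candidate set, ties broken toward smaller K.
#'
#' @slot candidates Integer vector of candidate orders.
#' @slot pnnll Numeric vector of PNNLL values, parallel to `candidates`.
#' @slot chosenK The selected order.
#' @slot fits List of [GammaGlmFit-class] objects, parallel to `candidates`.
#' @export
setClass("ModelOrderReport",
  representation(
    candidates = "integer",
    pnnll = "numeric",
    chosenK = "integer",
    fits = "list"
  )
)

#' A scalar PAC value
#'
#' One phase-amplitude coupling value with the method that produced it
#' (`"gamma-mi"` in nats; `"plv"`, `"mvl"`, `"ndpac"`, `"tortmi"`
#' dimensionless), optionally carrying the fitted model and a surrogate null
#' summary.
#'
#' @slot method Character method tag.
#' @slot value The PAC value.
#' @slot model The [GammaGlmFit-class] behind a gamma-MI value, or `NULL`.
#' @slot nullSummary Optional list with elements `n`, `mean`, `sd`, `p`.
#' @export
setClass("PacResult",
  representation(
    method = "character",
    value = "numeric",
    model = "ANY",
    nullSummary = "listOrNULL"
  ),
  prototype(model = NULL, nullSummary = NULL)
)

setValidity("PacResult", function(object) {
  ok <- object@method %in% c("gamma-mi", "plv", "mvl", "ndpac", "tortmi")
  if (!ok) return("unknown method tag")
  if (object@method %in% c("plv", "tortmi") &&
      (object@value < 0 || object@value > 1 + 1e-12))
    return("plv/tortmi values must lie in [0, 1]")
  if (object@value < -1e-9) return("PAC values must be non-negative")
  TRUE
})

#' Synthetic coupled-signal specification
#'
#' Parameters of the phase-amplitude-coupled generator
#' \deqn{x(t) = A_f(t) \sin(2\pi f_{high} t) + A_s \sin(2\pi f_{low} t)
#'   + \eta(t),}
#' \deqn{A_f(t) = \chi(t) \sin(2\pi f_{low} t) + \sqrt{2 - \chi(t)^2},}
#' with \eqn{\eta(t) \sim N(0, \sigma^2)} scaled to a target SNR.
#'
#' @slot fHigh Carrier (fast) frequency, Hz.
#' @slot fLow Modulating (slow) frequency, Hz.
#' @slot fs Sampling rate, Hz.
#' @slot duration Length in seconds.
#' @slot As Amplitude of the additive slow component.
#' @slot chi Coupling coefficient in [0, 1]; a scalar, or a vector of
#'   per-sample values for time-varying coupling.
#' @slot snrDb Target signal-to-noise ratio in dB (`Inf` for noiseless).
#' @slot seed Integer RNG seed (NA for the current RNG state).
#' @export
setClass("SyntheticSpec",
  representation(
    fHigh = "numeric",
    fLow = "numeric",
    fs = "numeric",
    duration = "numeric",
    As = "numeric",
    chi = "numeric",
    snrDb = "numeric",
    seed = "numeric"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (any(object@chi < 0 | object@chi > 1))
    msg <- c(msg, "chi must lie in [0, 1]")
  if (!(object@fLow < object@fHigh))
    msg <- c(msg, "fLow must be below fHigh")
  if (!(object@fHigh < object@fs / 2))
    msg <- c(msg, "fHigh must be below the Nyquist frequency fs/2")
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  n <- round(object@duration * object@fs)
  if (length(object@chi) != 1L && length(object@chi) != n)
    msg <- c(msg, "chi must be scalar or one value per sample")
  if (is.null(msg)) TRUE else msg
})

#' Multi-trial synthetic dataset
#'
#' A trials-by-time matrix of independently generated coupled signals, each
#' circularly shifted by a per-trial jitter (in samples), emulating the timing
#' jitter of event-related recordings.
#'
#' @slot data Numeric matrix, trials in rows.
#' @slot fs Sampling rate, Hz.
#' @slot jitter Integer vector of per-trial sample offsets.
#' @slot spec The [SyntheticSpec-class] the trials were drawn from.
#' @export
setClass("TrialSet",
  representation(
    data = "matrix",
    fs = "numeric",
    jitter = "integer",
    spec = "SyntheticSpec"
  )
)

setValidity("TrialSet", function(object) {
  msg <- NULL
  if (nrow(object@data) != length(object@jitter))
    msg <- c(msg, "one jitter value per trial required")
  if (is.null(msg)) TRUE else msg
})

#' Time-resolved PAC trace (information density)
#'
#' The information density \eqn{i(y_t, \theta_t) = \log f(y_t|\theta_t) -
#' \log f(y_t)} evaluated along the sample path (`raw`, may be negative), and
#' its post-processed version (smoothed below the phase frequency and
#' truncated at zero).
#'
#' @slot raw Numeric vector, nats.
#' @slot processed Non-negative numeric vector, same length.
#' @slot fs Sampling rate, Hz.
#' @slot postproc List describing the smoothing applied (mode, parameter).
#' @export
setClass("IdPacTrace",
  representation(
    raw = "numeric",
    processed = "numeric",
    fs = "numeric",
    postproc = "list"
  )
)

setValidity("IdPacTrace", function(object) {
  msg <- NULL
  if (length(object@raw) != length(object@processed))
    msg <- c(msg, "raw and processed must have equal length")
  if (length(object@processed) && min(object@processed) < 0)
    msg <- c(msg, "processed trace must be non-negative")
  if (is.null(msg)) TRUE else msg
})

#' Event-related PAC result
#'
#' Per-trial time-resolved PAC obtained by, at each evaluated time point,
#' pooling one full slow-oscillation cycle of phase/amplitude samples across
#' trials, fitting the gamma GLM, and evaluating the information density at
#' the window midpoint for each trial.
#'
#' @slot perTrial Trials-by-time matrix of post-processed idPAC values.
#' @slot meanTrace Column mean of `perTrial`.
#' @slot time Column indices (1-based, into the unpadded trial matrix) at
#'   which the ERPAC was evaluated.
#' @slot windowLen Window length in samples (odd; one slow cycle).
#' @slot pad Samples mirrored at each edge.
#' @export
setClass("ErpacResult",
  representation(
    perTrial = "matrix",
    meanTrace = "numeric",
    time = "integer",
    windowLen = "integer",
    pad = "integer"
  )
)

setValidity("ErpacResult", function(object) {
  msg <- NULL
  if (ncol(object@perTrial) != length(object@meanTrace))
    msg <- c(msg, "meanTrace must match perTrial columns")
  if (object@windowLen %% 2L != 1L)
    msg <- c(msg, "windowLen must be odd")
  if (is.null(msg)) TRUE else msg
})

#' Surrogate null distribution of a PAC measure
#'
#' PAC values recomputed after circular time shifts of the slow (phase)
#' series, each by at least `minShift` seconds, optionally summarized by a
#' fitted gamma null (retained only when a Kolmogorov-Smirnov check does not
#' reject it at the 0.05 level).
#'
#' @slot values Numeric vector of surrogate PAC values.
#' @slot minShift Minimum shift in seconds.
#' @slot gammaNull `NULL`, or list with `shape`, `rate`, `ksP`.
#' @export
setClass("SurrogateNull",
  representation(
    values = "numeric",
    minShift = "numeric",
    gammaNull = "listOrNULL"
  ),
  prototype(gammaNull = NULL)
)

#' False discovery rate report
#'
#' Step-up FDR control. With sorted p-values \eqn{p_{(1)} \le \dots \le
#' p_{(N)}}, the critical index is \eqn{c = \max\{i : p_{(i)} < q i / N\}}
#' (Benjamini-Hochberg) and all hypotheses of rank at most c are rejected,
#' including any below-c p-values lying above the line. Adjusted values
#' \eqn{p_{(i)} N / i} are reported as computed, without monotonicity
#' enforcement. The Benjamini-Yekutieli variant divides the level by
#' \eqn{\sum_{i=1}^N 1/i}.
#'
#' @slot p Original p-values, input order.
#' @slot pSorted Ascending p-values.
#' @slot adjusted \eqn{p_{(i)} N / i}, parallel to `pSorted`.
#' @slot criticalIndex The critical rank c (0 when nothing is rejected).
#' @slot rejected Logical vector in input order.
#' @slot q Nominal FDR level.
#' @slot method `"BH"` or `"BY"`.
#' @export
setClass("FdrReport",
  representation(
    p = "numeric",
    pSorted = "numeric",
    adjusted = "numeric",
    criticalIndex = "integer",
    rejected = "logical",
    q = "numeric",
    method = "character"
  )
)

#' Comodulogram
#'
#' PAC values over a grid of (slow band, fast band) pairs, with surrogate
#' p-values and an FDR significance mask. Masked (non-significant) cells are
#' zeroed in `display`.
#'
#' @slot lowBands m-by-2 matrix of slow passbands (Hz).
#' @slot highBands n-by-2 matrix of fast passbands (Hz).
#' @slot values m-by-n PAC matrix.
#' @slot pValues m-by-n p-value matrix (all NA when no surrogates were run).
#' @slot mask m-by-n logical significance matrix.
#' @slot method PAC measure used.
#' @export
setClass("Comodulogram",
  representation(
    lowBands = "matrix",
    highBands = "matrix",
    values = "matrix",
    pValues = "matrix",
    mask = "matrix",
    method = "character"
  )
)

setValidity("Comodulogram", function(object) {
  msg <- NULL
  if (!all(dim(object@values) ==
           c(nrow(object@lowBands), nrow(object@highBands))))
    msg <- c(msg, "values must be (low bands) x (high bands)")
  if (!all(dim(object@values) == dim(object@pValues)) ||
      !all(dim(object@values) == dim(object@mask)))
    msg <- c(msg, "values, pValues and mask must share dimensions")
  if (is.null(msg)) TRUE else msg
})
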