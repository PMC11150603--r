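## Goodness-of-fit by the probability integral transform (PIT): if the model
## is correct, U_t = F_{Y|Theta}(Y_t | Theta_t) is i.i.d. Uniform[0, 1].

#' Conditional amplitude CDF under the fitted model
#'
#' \eqn{F_{Y|\Theta}(y|\theta)}: the regularized lower incomplete gamma
#' function at shape \eqn{\alpha} and rate \eqn{\alpha e^{-L(\theta)}}.
#'
#' @param y Non-negative amplitude value(s).
#' @param theta Phase value(s), same length as `y` (or length 1, recycled).
#' @param model A [GammaGlmFit-class].
#' @return CDF values in `[0, 1]`.
#' @export
conditionalAmplitudeCdf <- function(y, theta, model) {
  if (any(y < 0)) stop("amplitude must be non-negative", call. = FALSE)
  a <- model@shape
  rate <- a * exp(-linkValues(model, theta))
  stats::pgamma(y, shape = a, rate = rate)
}

#' Probability integral transform of an amplitude series
#'
#' Plugs each observed amplitude into its fitted conditional CDF. Under a
#' correct model the result is uniform on `[0, 1]`.
#'
#' @inheritParams conditionalAmplitudeCdf
#' @return Numeric vector of PIT values \eqn{U_t \in [0, 1]}.
#' @export
pitResiduals <- function(y, theta, model) {
  stopifnot(length(y) == length(theta))
  u <- conditionalAmplitudeCdf(y, theta, model)
  if (stats::sd(u) < 1e-12)
    warning("degenerate PIT: residuals are (near) constant")
  u
}

#' Empirical CDF of PIT residuals with Kolmogorov-Smirnov band
#'
#' Evaluates \eqn{\hat F(u) = T^{-1} \sum_t 1\{U_t \le u\}} on a grid and
#' attaches the pointwise asymptotic 95% acceptance band
#' \eqn{u \pm c(0.95)/\sqrt{T}} around the diagonal, with
#' \eqn{c(0.95) \approx 1.358} the two-sided KS critical value.
#'
#' @param u PIT residuals in `[0, 1]`.
#' @param grid Evaluation grid in `[0, 1]` (default 101 equispaced points).
#' @param level Band confidence level (default 0.95).
#' @return List with `grid`, `ecdf`, `lower`, `upper`, `n`.
#' @export
pitEcdf <- function(u, grid = seq(0, 1, length.out = 101L), level = 0.95) {
  if (length(u) < 1L) stop("need at least one residual", call. = FALSE)
  Fh <- vapply(grid, function(g) mean(u <= g), numeric(1))
  crit <- ksCritical(level)
  half <- crit / sqrt(length(u))
  list(grid = grid, ecdf = Fh, lower = pmax(grid - half, 0),
       upper = pmin(grid + half, 1), n = length(u))
}

# two-sided asymptotic KS critical value: K^{-1}(level) of the Kolmogorov
# distribution (1.358 at 95%)
ksCritical <- function(level = 0.95) {
  kolm <- function(x) {
    k <- 1:100
    1 - 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  }
  stats::uniroot(function(x) kolm(x) - level, c(0.3, 3), tol = 1e-10)$root
}

#' One-sample KS test of PIT residuals against Uniform[0, 1]
#'
#' @param u PIT residuals.
#' @return List with the KS statistic `D` and asymptotic p-value `p`.
#' @export
ksUniformTest <- function(u) {
  if (length(u) < 1L) stop("need at least one residual", call. = FALSE)
  n <- length(u)
  us <- sort(u)
  i <- seq_len(n)
  D <- max(i / n - us, us - (i - 1) / n)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * (sqrt(n) * D)^2))
  list(D = D, p = min(max(p, 0), 1))
}

#' Segmented goodness-of-fit assessment
#'
#' For long recordings: fits the model on consecutive non-overlapping
#' windows, computes per-window PIT residuals, and summarizes per-window
#' empirical CDFs as pointwise percentiles together with the pooled ECDF and
#' the KS acceptance band (the conventional probability-plot display).
#'
#' @param y Amplitude sequence.
#' @param theta Phase sequence.
#' @param fs Sampling rate in Hz.
#' @param windowSec Window length in seconds (default 1).
#' @param K Fourier order for the per-window fits.
#' @param grid ECDF evaluation grid.
#' @return List with `grid`, `meanEcdf`, `loEnvelope`, `hiEnvelope`
#'   (pointwise 2.5/97.5 percentiles of the per-window ECDFs), `band`
#'   (KS band around the diagonal for one window's sample size), and
#'   `perWindowD` (KS statistics).
#' @export
gofSegments <- function(y, theta, fs, windowSec = 1, K = 2,
                        grid = seq(0, 1, length.out = 101L)) {
  wlen <- round(windowSec * fs)
  nwin <- floor(length(y) / wlen)
  if (nwin < 1L) stop("recording shorter than one window", call. = FALSE)
  ecdfs <- matrix(NA_real_, nwin, length(grid))
  Ds <- numeric(nwin)
  for (w in seq_len(nwin)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    fit <- fitGammaGlm(y[idx], theta[idx], K)
    u <- pitResiduals(y[idx], theta[idx], fit)
    ecdfs[w, ] <- vapply(grid, function(g) mean(u <= g), numeric(1))
    Ds[w] <- ksUniformTest(u)$D
  }
  half <- ksCritical(0.95) / sqrt(wlen)
  list(grid = grid,
       meanEcdf = colMeans(ecdfs),
       loEnvelope = apply(ecdfs, 2L, stats::quantile, probs = 0.025),
       hiEnvelope = apply(ecdfs, 2L, stats::quantile, probs = 0.975),
       band = list(lower = pmax(grid - half, 0),
                   upper = pmin(grid + half, 1)),
       perWindowD = Ds)
}
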