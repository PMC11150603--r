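---
title: "Model-based phase-amplitude coupling with gamma GLMs"
author: "gammapac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based phase-amplitude coupling with gamma GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammapac)
```

## The model

Phase-amplitude coupling (PAC) is the dependence of a fast oscillation's
amplitude envelope $Y \ge 0$ on the phase $\Theta \in [-\pi, \pi)$ of a
slower oscillation. Both series come from the analytic signal of the
band-filtered recording: $z(t) = x(t) + jH\{x(t)\}$, with $A(t) = |z(t)|$
and $\phi(t) = \arg z(t)$.

`gammapac` models the conditional distribution of amplitude given phase as
a gamma generalized linear model with a log link and a Fourier basis of
phase regressors,

$$Y \mid \Theta = \theta \;\sim\; \mathrm{Gamma}\!\big(\alpha,\;
\beta(\theta) = \alpha e^{-L(w;\theta)}\big), \qquad
L(w;\theta) = R(\theta)^\top w,$$

where $R(\theta) = (1, \cos\theta, \sin\theta, \dots, \cos K\theta,
\sin K\theta)^\top$, so that $E[Y \mid \theta] = e^{L(w;\theta)}$. The
phase prior is uniform, $f_\Theta = 1/2\pi$, the natural choice for the
phase of a narrowband oscillation. The PAC statistic is the mutual
information of the fitted joint,

$$I(Y;\Theta) = E_Y\big[ D(P_{\Theta \mid Y=y} \,\|\, P_\Theta) \big],$$

which is non-negative and zero exactly when amplitude and phase are
independent (i.e. when the fitted mean function is constant). The inner
relative entropy is an integral over the circle and is computed by a
midpoint Riemann sum; the outer expectation is the empirical average along
the observed sample path. Units are nats (natural logarithms throughout).

### Fitting

The negative log-likelihood separates so that the weights can be fit
without knowing the shape:

$$\hat w = \arg\min_w \sum_t \big( y_t e^{-L(w;\theta_t)} +
L(w;\theta_t) \big),$$

a convex problem solved by BFGS with the analytic gradient
$X^\top(1 - y e^{-L})$, initialized at $w_0 = (\log \bar y, 0, \dots)$.
Given $\hat L_t$, the shape solves the one-dimensional stationarity
condition

$$\psi(\alpha) - \log\alpha = 1 + \tfrac1T \sum_t \big( \log y_t -
\hat L_t - y_t e^{-\hat L_t} \big),$$

whose right-hand side is non-positive by $\log x \le x - 1$; the root is
bracketed on $\log\alpha$, which enforces positivity. Both steps are
deterministic, so refitting reproduces a model exactly.

The Fourier order $K$ is selected by minimum description length: minimize
$\mathrm{PNNLL}(K) = \mathrm{NLL}/T + (2K+1)\log(T)/(2T)$ over a candidate
set (default $\{0, \dots, 5\}$), ties broken toward smaller $K$.

The basis uses $\cos(k\theta), \sin(k\theta)$ in radians, the orthogonal
Fourier system on the circle; an `angularScale` argument exists for
compatibility with conventions that rescale the angle, but the default is
the periodic basis.

## Time-resolved PAC

The pointwise information density
$i(y, \theta) = \log f_{Y\mid\Theta}(y \mid \theta) - \log f_Y(y)$
evaluated along the sample path (`idPac()`) gives a per-sample coupling
trace whose time average approximates $I(Y;\Theta)$. Because the slow
oscillation leaks into the raw trace, `postprocessIdPac()` smooths it
below the phase frequency (zero-phase Butterworth lowpass at
$0.8 f_{low}$ by default, or a Gaussian kernel, default $\sigma = 0.08$ s,
for short epoched data) and truncates negatives at zero.

For event-related designs, `erpacTrace()` pools, at each time point, one
full slow cycle of phase/amplitude samples across all trials
(window $= \mathrm{round}(f_s/f_{low})$ forced odd so the evaluated column
is the exact midpoint), fits one model per window, and evaluates the
information density at the center column of every trial. Edges are
covered by mirroring half a window of the phase/amplitude matrices. Two
choices here are deliberately fixed for determinism and speed: the window
model order is a fixed $K$ (default 2) rather than per-window MDL, and a
`stride` argument evaluates every stride-th column (window fits are
warm-started from the previous column). Interior values are unaffected by
the padding or the stride.

## Goodness of fit

`pitResiduals()` pushes each amplitude through its fitted conditional CDF
(a regularized incomplete gamma function). Under a correct model the
result is i.i.d. uniform; `pitEcdf()` compares its empirical CDF with the
diagonal inside the pointwise asymptotic 95% Kolmogorov-Smirnov band
$\pm 1.358/\sqrt{T}$, and `ksUniformTest()` gives the test. For long
recordings `gofSegments()` fits consecutive non-overlapping windows
(default 1 s) and reports the pointwise 2.5-97.5 percentile envelope of
per-window ECDFs. The bands are pointwise, not simultaneous, and are
labeled as such.

## Significance and multiple comparisons

Surrogate nulls circularly shift the slow phase series by a random offset
of at least `minShiftS` seconds, preserving its marginal distribution and
oscillatory character while destroying its temporal alignment with the
amplitude. P-values are empirical with the add-one convention
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$ (a raw-proportion mode
exists), or, for small surrogate counts, upper-tail probabilities of a
gamma distribution fitted to the null values — retained only when a KS
check does not reject it at 0.05. FDR control is the Benjamini-Hochberg
step-up (critical index $c = \max\{i: p_{(i)} < q i/N\}$, all ranks
$\le c$ rejected), with the Benjamini-Yekutieli deflation
$q / \sum_i 1/i$ as the dependence-robust variant; adjusted values
$p_{(i)} N / i$ are reported without monotonicity enforcement.
`comodulogram()` scans fixed-width bands (e.g. 4 Hz slow bands stepped by
2 Hz from 0.5 Hz, 10 Hz fast bands stepped by 5 Hz up to a user-supplied
upper frequency), computes the chosen measure per band pair, and masks
cells that fail FDR.

An important caveat for *synthetic* data: on a strictly sinusoidal slow
component, a circular time shift is exactly a constant phase rotation, and
every measure offered here (gamma-MI, Tort MI, MVL, PLV) is invariant to
phase rotation. Shift surrogates therefore cannot destroy coupling in
such signals and their nulls concentrate at the observed value. The
machinery is meaningful for real oscillators, whose phase drifts; the test
suite demonstrates coupling destruction on a frequency-drifting synthetic
oscillator instead.

## The synthetic generator

`simulatePac()` draws

$$x(t) = A_f(t)\sin(2\pi f_{high} t) + A_s \sin(2\pi f_{low} t) +
\eta(t), \qquad A_f(t) = \chi(t) \sin(2\pi f_{low} t) +
\sqrt{2 - \chi(t)^2},$$

with i.i.d. Gaussian noise scaled so that
$10\log_{10}(P_{signal}/\sigma^2)$ equals the requested SNR, where
$P_{signal}$ is the empirical mean square of the noiseless sum. Defaults
emulate gut-brain coupling: a 10 Hz carrier, the 0.05 Hz gastric slow
wave, 50 Hz sampling, 20 s, $A_s = 1$, 0 dB SNR. The coupling
coefficient may be a per-sample sequence (square wave or ramp via
`couplingProfile()`), and `simulateTrials()` builds jittered multi-trial
sets (uniform jitter in samples, circular shift by default, onset-delay
mode available; per-trial seeds derived from the master seed by a
counter).

What the generator emulates: sinusoidal carrier-envelope coupling at a
controlled SNR and timing jitter. What it does not: aperiodic phase
(see the surrogate caveat above), 1/f background spectra, non-sinusoidal
waveform shape, or artifacts — so passing tests demonstrate estimator
correctness and statistical behavior under idealized coupling, not
robustness to the confounds of real recordings.

## Numerical choices

* **Filtering.** Zero-phase Butterworth band filters are applied, by
  default, as an exact spectral multiplication by the squared
  (bilinear-prewarped) magnitude response on a reflection-padded copy of
  the signal; a time-domain second-order-sections forward-backward cascade
  is available (`method = "sos"`). The spectral path was chosen because at
  the very low normalized bands this package targets (0.03-0.07 Hz at
  50 Hz sampling) even a biquad cascade hits a double-precision round-off
  floor around -32 dB, while the spectral form keeps exact stopband
  behavior. Padding uses *even* (symmetric) reflection of about three
  ring time constants of the band: odd reflection of a fast oscillation
  rectifies it into a low-frequency pedestal that lies inside very low
  passbands and leaks visibly. Edge samples are still the least reliable
  part of any zero-phase filter output; analyses in the tests discard a
  10% margin where it matters.
* **Amplitude bands for AM signals.** The fast band should contain the
  carrier's modulation sidebands with margin (e.g. $[30, 50]$ Hz for a
  40 Hz carrier modulated at 5 Hz); placing sidebands at the band's -3 dB
  edges attenuates the very modulation being measured.
* **Phase grid.** $M = 256$ midpoint nodes by default; MI estimates at
  $M = 256$ versus finer grids agree to well under $10^{-4}$ nats for the
  models arising here. Densities are evaluated in log space and
  normalized by log-sum-exp, so large shapes do not overflow.
* **Degenerate amplitudes.** Values below $10^{-12}$ are clipped (with a
  message) before fitting, since $\log y$ enters the likelihood; a
  near-perfect deterministic fit caps the shape at $10^8$ with a warning.
* **Tolerances.** Weight fits target a per-sample gradient norm of
  $10^{-8}$ (iteration cap 500); the shape root is found to $10^{-12}$ on
  $\log\alpha$; MI values in $(-10^{-9}, 0)$ from floating error are
  reported as 0.
* **Tort MI bins.** $N = 18$ by default, the convention of the original
  modulation-index literature; empty bins contribute $0\log 0 = 0$ with a
  warning.

## Known limitations

* **MDL under autocorrelation.** The PNNLL penalty assumes independent
  samples. Band-filtered envelopes are strongly autocorrelated, which
  inflates the apparent likelihood gain of extra harmonics; on 20 s
  single-slow-cycle signals the selector routinely prefers large $K$ even
  without coupling, and this does not vanish with longer recordings. When
  scanning short windows, prefer a small fixed $K$ or interpret selected
  orders cautiously.
* **Single-cycle recordings.** With only one slow cycle, phase is a
  monotone function of elapsed time, so any slow envelope drift (including
  filtered noise) masquerades as phase modulation for every PAC measure.
* **Shift surrogates on periodic signals.** See above; use surrogates only
  when the slow phase is aperiodic.
* **One-shot idPAC on short epochs.** Filter edge effects and per-epoch
  overfitting can produce spurious excursions; the trial-pooled ERPAC
  estimator is preferable when repeatable trials exist.
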