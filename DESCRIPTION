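Package: gammapac
Title: Phase-Amplitude Coupling via Gamma Generalized Linear Models and
    Mutual Information
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based estimation of phase-amplitude coupling (PAC) in
    electrophysiological recordings. The conditional distribution of a fast
    oscillation's amplitude envelope given the phase of a slow oscillation is
    modeled as a gamma generalized linear model with a log link and a Fourier
    basis of phase regressors, fitted by a two-step convex maximum-likelihood
    procedure with minimum-description-length model-order selection. The
    mutual information between amplitude and phase under the fitted model is
    the PAC statistic; the pointwise information density provides a
    time-resolved variant (idPAC) and an event-related variant (ERPAC).
    Includes zero-phase Butterworth band filtering via second-order sections,
    analytic-signal phase/amplitude extraction, goodness-of-fit assessment by
    the probability integral transform, reference PAC measures (PLV, MVL,
    ndPAC, Tort modulation index), a synthetic coupled-signal simulator,
    circular-shift surrogate null distributions, false-discovery-rate control,
    and comodulogram band scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, graphics, MASS
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
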