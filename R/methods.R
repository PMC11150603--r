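#' @rdname AnalyticSeries-class
#' @export
setMethod("amplitude", "AnalyticSeries", function(x) x@amplitude)

#' @rdname AnalyticSeries-class
#' @export
setMethod("phase", "AnalyticSeries", function(x) x@phase)

#' @rdname AnalyticSeries-class
#' @export
setMethod("samplingRate", "AnalyticSeries", function(x) x@fs)

#' @rdname AnalyticSeries-class
#' @export
setMethod("length", "AnalyticSeries", function(x) length(x@amplitude))

setMethod("show", "AnalyticSeries", function(object) {
  band <- if (is.null(object@band)) "unfiltered"
          else sprintf("[%g, %g] Hz", object@band[1], object@band[2])
  cat(sprintf("AnalyticSeries: %d samples at %g Hz, band %s\n",
              length(object), object@fs, band))
  cat(sprintf("  amplitude range [%.4g, %.4g]\n",
              min(object@amplitude), max(object@amplitude)))
})

#' @rdname GammaGlmFit-class
#' @export
setMethod("shape", "GammaGlmFit", function(x) x@shape)

#' @rdname GammaGlmFit-class
#' @export
setMethod("modelOrder", "GammaGlmFit", function(x) x@order)

#' @rdname GammaGlmFit-class
#' @export
setMethod("coef", "GammaGlmFit", function(object, ...) object@coef)

#' @rdname GammaGlmFit-class
#' @export
setMethod("logLik", "GammaGlmFit", function(object, ...) {
  structure(-object@nll, df = 2L * object@order + 2L,
            nobs = object@nobs, class = "logLik")
})

setMethod("show", "GammaGlmFit", function(object) {
  cat(sprintf("GammaGlmFit: K = %d, shape alpha = %.4g, T = %d\n",
              object@order, object@shape, object@nobs))
  cat(sprintf("  NLL = %.6g\n", object@nll))
  cat("  coef:", format(object@coef, digits = 4), "\n")
})

setMethod("show", "ModelOrderReport", function(object) {
  cat("ModelOrderReport (PNNLL over candidate Fourier orders)\n")
  for (i in seq_along(object@candidates))
    cat(sprintf("  K = %d: PNNLL = %.6g%s\n", object@candidates[i],
                object@pnnll[i],
                if (object@candidates[i] == object@chosenK) "  <- chosen"
                else ""))
})

#' @rdname PacResult-class
#' @export
setMethod("pacValue", "PacResult", function(x) x@value)

#' @rdname PacResult-class
#' @export
setMethod("modelOrder", "PacResult", function(x) {
  if (is.null(x@model)) NA_integer_ else x@model@order
})

setMethod("show", "PacResult", function(object) {
  unit <- if (object@method == "gamma-mi") " nats" else ""
  cat(sprintf("PacResult [%s]: %.6g%s\n", object@method, object@value, unit))
  if (!is.null(object@nullSummary))
    cat(sprintf("  surrogate null: n = %d, mean = %.4g, sd = %.4g, p = %.4g\n",
                object@nullSummary$n, object@nullSummary$mean,
                object@nullSummary$sd, object@nullSummary$p))
})

setMethod("show", "SyntheticSpec", function(object) {
  chi <- if (length(object@chi) == 1L) sprintf("%g", object@chi)
         else sprintf("time-varying in [%g, %g]", min(object@chi),
                      max(object@chi))
  cat(sprintf(
    "SyntheticSpec: fHigh = %g Hz, fLow = %g Hz, fs = %g Hz, %g s\n",
    object@fHigh, object@fLow, object@fs, object@duration))
  cat(sprintf("  As = %g, chi = %s, SNR = %g dB, seed = %s\n", object@As,
              chi, object@snrDb,
              if (is.na(object@seed)) "NA" else format(object@seed)))
})

#' @rdname TrialSet-class
#' @export
setMethod("samplingRate", "TrialSet", function(x) x@fs)

#' @rdname TrialSet-class
#' @param x A `TrialSet`.
#' @export
setMethod("dim", "TrialSet", function(x) dim(x@data))

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet: %d trials x %d samples at %g Hz\n",
              nrow(object@data), ncol(object@data), object@fs))
  cat(sprintf("  jitter range [%d, %d] samples\n",
              min(object@jitter), max(object@jitter)))
})

setMethod("show", "IdPacTrace", function(object) {
  cat(sprintf("IdPacTrace: %d samples at %g Hz (%s smoothing)\n",
              length(object@raw), object@fs,
              object@postproc$mode %||% "no"))
  cat(sprintf("  raw mean = %.4g nats, processed max = %.4g\n",
              mean(object@raw), max(object@processed)))
})

setMethod("show", "ErpacResult", function(object) {
  cat(sprintf(
    "ErpacResult: %d trials, %d time points, window %d samples, pad %d\n",
    nrow(object@perTrial), ncol(object@perTrial), object@windowLen,
    object@pad))
})

setMethod("show", "SurrogateNull", function(object) {
  cat(sprintf("SurrogateNull: %d surrogates, min shift %g s\n",
              length(object@values), object@minShift))
  if (!is.null(object@gammaNull))
    cat(sprintf("  gamma null: shape = %.4g, rate = %.4g (KS p = %.3g)\n",
                object@gammaNull$shape, object@gammaNull$rate,
                object@gammaNull$ksP))
  else
    cat("  no accepted gamma null (empirical p-values)\n")
})

setMethod("show", "FdrReport", function(object) {
  cat(sprintf("FdrReport [%s]: N = %d, q = %g, %d rejected (c = %d)\n",
              object@method, length(object@p), object@q,
              sum(object@rejected), object@criticalIndex))
})

setMethod("show", "Comodulogram", function(object) {
  cat(sprintf("Comodulogram [%s]: %d low bands x %d high bands\n",
              object@method, nrow(object@lowBands),
              nrow(object@highBands)))
  cat(sprintf("  %d significant cells after FDR\n", sum(object@mask)))
})

#' Displayed comodulogram values
#'
#' PAC matrix with non-significant cells set to zero, as conventionally shown
#' in comodulogram heatmaps.
#'
#' @param x A [Comodulogram-class].
#' @return Numeric matrix, same shape as `x@values`.
#' @export
comodDisplay <- function(x) {
  stopifnot(is(x, "Comodulogram"))
  out <- x@values
  out[!x@mask] <- 0
  out
}

#' @describeIn Comodulogram-class heatmap of FDR-masked PAC values.
#' @param y Ignored.
#' @param ... Passed to [graphics::image()].
#' @export
setMethod("plot", signature("Comodulogram", "missing"), function(x, y, ...) {
  lowMid <- rowMeans(x@lowBands)
  highMid <- rowMeans(x@highBands)
  graphics::image(lowMid, highMid, comodDisplay(x),
                  xlab = "phase frequency (Hz)",
                  ylab = "amplitude frequency (Hz)", ...)
  invisible(x)
})
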