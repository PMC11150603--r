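`%||%` <- function(a, b) if (is.null(a)) b else a

# log(sum(exp(x))) along rows of a matrix, guarded against overflow
# (max.col is C-level; columns with -Inf are safe since exp(-Inf) = 0)
rowLogSumExp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

# wrap angles to [-pi, pi)
wrapPhase <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out >= pi] <- -pi  # guard against floating residue at the seam
  out
}

checkFinite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric values", call. = FALSE)
  invisible(x)
}

# amplitudes below this floor are clipped before entering the likelihood,
# since log(y) appears in the NLL
.AMP_FLOOR <- 1e-12

clipAmplitude <- function(y, floor = .AMP_FLOOR) {
  nlow <- sum(y < floor)
  if (nlow > 0L) {
    message(sprintf("clipping %d amplitude value(s) below %g", nlow, floor))
    y[y < floor] <- floor
  }
  y
}
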