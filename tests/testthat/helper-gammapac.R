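# shared fixtures and independent oracles

# construct a GammaGlmFit with known parameters (bypasses fitting)
knownModel <- function(w, alpha) {
  K <- (length(w) - 1L) / 2L
  new("GammaGlmFit", order = as.integer(K), coef = w, shape = alpha,
      nll = NA_real_, nobs = 0L, angularScale = 1)
}

# draw (theta, y) from the gamma GLM with uniform phase
rGlmData <- function(T, w, alpha) {
  K <- (length(w) - 1L) / 2L
  theta <- stats::runif(T, -pi, pi)
  L <- drop(fourierDesign(theta, K) %*% w)
  y <- stats::rgamma(T, shape = alpha, rate = alpha * exp(-L))
  list(theta = theta, y = y)
}

# independent 2-D quadrature oracle for the mutual information of a gamma
# GLM joint: I = sum_{th,y} f(y|th) (1/2pi) log(f(y|th)/f_Y(y)) dy dth,
# built directly on dgamma, not on the package's estimator path
oracleMI <- function(w, alpha, nTheta = 1024L, nY = 4000L) {
  K <- (length(w) - 1L) / 2L
  th <- -pi + (seq_len(nTheta) - 0.5) * 2 * pi / nTheta
  L <- drop(fourierDesign(th, K) %*% w)
  rates <- alpha * exp(-L)
  yMax <- max(stats::qgamma(1 - 1e-9, shape = alpha, rate = rates))
  y <- seq(yMax / nY / 2, yMax, length.out = nY)
  dy <- y[2] - y[1]
  f <- vapply(seq_len(nTheta), function(i)
    stats::dgamma(y, shape = alpha, rate = rates[i]), numeric(nY))
  fy <- rowMeans(f)                      # marginal over uniform phase
  ratio <- log(sweep(f, 1L, fy, "/"))
  sum(f * ratio, na.rm = TRUE) / nTheta * dy
}

# literal step-up FDR oracle, loop form
bruteStepUp <- function(p, q, by = FALSE) {
  N <- length(p)
  lvl <- if (by) q / sum(1 / seq_len(N)) else q
  ord <- order(p)
  ps <- p[ord]
  c <- 0L
  for (i in seq_len(N)) if (ps[i] < lvl * i / N) c <- i
  rej <- logical(N)
  if (c > 0L) rej[ord[1:c]] <- TRUE
  rej
}

quietTort <- function(...) suppressWarnings(tortMI(...))
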