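# Independent brute-force oracles, coded straight from the defining
# formulas with per-threshold loops; they share no code path with the
# package's vectorized implementations.

otsuBruteForce <- function(h) {
  x <- 0:255
  best <- -Inf; bestT <- NA_integer_
  for (t in 0:255) {
    lo <- x <= t
    w0 <- sum(h[lo]); w1 <- sum(h[!lo])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(x[lo] * h[lo]) / w0
    mu1 <- sum(x[!lo] * h[!lo]) / w1
    tot <- w0 + w1
    v <- (w0 / tot) * (w1 / tot) * (mu0 - mu1)^2
    if (v > best) { best <- v; bestT <- t }
  }
  list(threshold = bestT, value = best)
}

otsuObjectiveAt <- function(h, t) {
  x <- 0:255; lo <- x <= t
  w0 <- sum(h[lo]); w1 <- sum(h[!lo])
  if (w0 == 0 || w1 == 0) return(-Inf)
  mu0 <- sum(x[lo] * h[lo]) / w0
  mu1 <- sum(x[!lo] * h[!lo]) / w1
  (w0 / (w0 + w1)) * (w1 / (w0 + w1)) * (mu0 - mu1)^2
}

ghtBruteForce <- function(h, nu, tau, kappa, omega) {
  x <- 0:255; eps <- 1e-30
  f <- numeric(255)
  for (t in 1:255) {
    n0 <- h[1:t]; n1 <- h[(t + 1):256]
    x0 <- x[1:t]; x1 <- x[(t + 1):256]
    w0 <- max(sum(n0), eps); w1 <- max(sum(n1), eps)
    p0 <- w0 / (w0 + w1); p1 <- w1 / (w0 + w1)
    mu0 <- sum(x0 * n0) / w0; mu1 <- sum(x1 * n1) / w1
    d0 <- max(sum(x0^2 * n0) - w0 * mu0^2, 0)
    d1 <- max(sum(x1^2 * n1) - w1 * mu1^2, 0)
    v0 <- max((p0 * nu * tau^2 + d0) / (p0 * nu + w0), eps)
    v1 <- max((p1 * nu * tau^2 + d1) / (p1 * nu + w1), eps)
    f[t] <- -d0 / v0 - w0 * log(v0) + 2 * (w0 + kappa * omega) * log(w0) -
      d1 / v1 - w1 * log(v1) + 2 * (w1 + kappa * (1 - omega)) * log(w1)
  }
  list(threshold = (0:254)[which.max(f)], objective = f)
}

randomHistogram <- function(nBins = 256L) {
  h <- numeric(nBins)
  k <- sample(2:30, 1)
  bins <- sample(nBins, k)
  h[bins] <- sample(1:500, k, replace = TRUE)
  h
}

randomBimodalHistogram <- function() {
  m1 <- sample(20:80, 1); m2 <- sample(160:230, 1)
  x <- 0:255
  h <- 600 * exp(-(x - m1)^2 / (2 * sample(3:12, 1)^2)) +
    600 * exp(-(x - m2)^2 / (2 * sample(3:12, 1)^2))
  round(h)
}

# double box mean, coded directly (the guided-filter degenerate limit)
doubleBoxMean <- function(m, r) {
  box <- function(mm) {
    p <- depthseg:::padReflect(mm, r)
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_len(nrow(mm)))
      for (j in seq_len(ncol(mm)))
        out[i, j] <- mean(p[i:(i + 2 * r), j:(j + 2 * r)])
    out
  }
  box(box(m))
}

# truncated spatial Gaussian convolution (the JBF sigma_color -> Inf limit)
spatialGaussian <- function(m, r, sigmaSpace) {
  wk <- outer(-r:r, -r:r, function(a, b)
    exp(-(a^2 + b^2) / (2 * sigmaSpace^2)))
  p <- depthseg:::padReflect(m, r)
  out <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(ncol(m)))
      out[i, j] <- sum(wk * p[i:(i + 2 * r), j:(j + 2 * r)]) / sum(wk)
  out
}
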