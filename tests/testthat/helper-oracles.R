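# Independent brute-force oracles: plain-R, exhaustive implementations of
# the k-NN machinery, kept deliberately separate from the package's compiled
# path so the two can be compared on small instances.

# exhaustive max-norm k-NN with temporal exclusion; ties by smaller index
bfKnn <- function(X, n, k, theiler = 0) {
  X <- as.matrix(X)
  d <- apply(X, 1L, function(r) max(abs(r - X[n, ])))
  adm <- which(abs(seq_len(nrow(X)) - n) > theiler)
  ord <- adm[order(d[adm], adm)]
  sel <- ord[seq_len(k)]
  list(index = sel, dist = d[sel])
}

bfLpPredict <- function(X, y, k, theiler = 0) {
  vapply(seq_len(nrow(X)), function(n) {
    nb <- bfKnn(X, n, k, theiler)
    if (any(nb$dist == 0)) return(mean(y[nb$index[nb$dist == 0]]))
    w <- 1 / nb$dist
    sum(w * y[nb$index]) / sum(w)
  }, numeric(1))
}

# explicit pair-loop CE: per-row neighbor images, unordered distinct pairs
bfCe <- function(X, y, k, theiler, eps) {
  npairs <- k * (k - 1) / 2
  ce <- vapply(seq_len(nrow(X)), function(n) {
    img <- y[bfKnn(X, n, k, theiler)$index]
    cnt <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k)
        if (abs(img[a] - img[b]) <= eps) cnt <- cnt + 1
    p <- cnt / npairs
    if (p <= 0) p <- 1 / npairs
    -log(p)
  }, numeric(1))
  mean(ce)
}

bfPairProb <- function(v, eps) {
  n <- length(v)
  cnt <- 0
  for (a in seq_len(n - 1))
    for (b in (a + 1):n)
      if (abs(v[a] - v[b]) <= eps) cnt <- cnt + 1
  cnt / (n * (n - 1) / 2)
}

# unit-variance AR(1) series wrapped in a normalized single-series universe
arUniverse <- function(n, a, seed, label = "Y") {
  set.seed(seed)
  x <- as.numeric(stats::arima.sim(list(ar = a), n, sd = sqrt(1 - a^2)))
  normalizeSeries(beatUniverse(list(beatSeries(x, label, unit = "a.u."))))
}

# bivariate unidirectional linear coupling: X white, Y(n) = g X(n-1) + w,
# innovation variances chosen so both series are near unit variance
linearPairUniverse <- function(n, g = 0.8, seed = 1) {
  sim <- simulateCoupled(n = n, labels = c("X", "Y"),
    selfCoefs = list(X = 0, Y = 0),
    couplings = data.frame(from = "X", to = "Y", lag = 1, gain = g,
                           type = "linear"),
    noiseSD = c(1, sqrt(max(1 - g^2, 0.1))), drift = 0, seed = seed)
  normalizeSeries(sim$universe)
}

# bivariate quadratic coupling: X white, Y(n) = X(n-1)^2 + w
quadraticPairUniverse <- function(n, seed = 1) {
  sim <- simulateCoupled(n = n, labels = c("X", "Y"),
    selfCoefs = list(X = 0, Y = 0),
    couplings = data.frame(from = "X", to = "Y", lag = 1, gain = 1,
                           type = "quadratic"),
    noiseSD = c(1, 0.5), drift = 0, seed = seed)
  normalizeSeries(linearDetrend(sim$universe))
}

pairSpec <- function(effect = "Y", p = 8) {
  other <- setdiff(c("X", "Y"), effect)
  tau <- c(1, 1)
  names(tau) <- c(effect, other)
  embeddingSpec(effect, tau, p = p)
}
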