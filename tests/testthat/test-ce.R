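test_that("the unconditional entropy estimator handles degenerate and floored cases", {
  expect_equal(shannonEntropy(rep(2, 10), eps = 0.1), 0)
  # no pair within eps: probability floored at one pair
  expect_equal(shannonEntropy(c(0, 10, 20), eps = 1), -log(1 / 3))
  # stability across seeds for Gaussian data under the percentile rule
  se <- vapply(1:10, function(seed) {
    set.seed(seed)
    v <- rnorm(2048)
    shannonEntropy(normalizeSeries(v))
  }, numeric(1))
  expect_lt(sd(se) / mean(se), 0.05)
})

test_that("the tolerance rule is ten percent of the 84-16 percentile span", {
  set.seed(61)
  v <- rnorm(4096)
  q <- quantile(v, c(0.16, 0.84), names = FALSE)
  expect_equal(epsTolerance(v), 0.1 * (q[2] - q[1]), tolerance = 1e-12)
  # for a unit-variance Gaussian the span is close to 2 SD
  expect_equal(epsTolerance(normalizeSeries(v)),
               0.1 * (qnorm(0.84) - qnorm(0.16)), tolerance = 0.05)
})

test_that("conditional entropy matches the explicit pair-loop implementation", {
  for (seed in 1:6) {
    set.seed(600 + seed)
    N <- sample(80:200, 1)
    q <- sample(1:3, 1)
    X <- matrix(rnorm(N * q), N, q)
    y <- rnorm(N)
    eps <- epsTolerance(y)
    k <- 10L; theiler <- 2L
    got <- conditionalEntropy(X, y, k = k, theiler = theiler, eps = eps)
    expect_equal(got, bfCe(X, y, k, theiler, eps), tolerance = 1e-10)
  }
})

test_that("an empty conditioning set reduces CE to the unconditional entropy", {
  set.seed(62)
  u <- normalizeSeries(beatUniverse(
    list(beatSeries(rnorm(128), "Y", unit = "a.u."))))
  em <- fullEmbedding(u, embeddingSpec("Y", c(Y = 1), p = 3))
  eps <- epsTolerance(beatValues(u)[, "Y"])
  expect_identical(conditionalEntropy(subsetEmbedding(em, integer(0)), eps = eps),
                   shannonEntropy(em@target, eps))
})

test_that("conditioning on an informative lag collapses the distribution", {
  # noiseless deterministic map: one self lag pins the future almost exactly,
  # so the conditional distributions are near point masses
  x <- numeric(2148); x[1] <- 0.3141
  for (n in 2:2148) x[n] <- 4 * x[n - 1] * (1 - x[n - 1])
  x <- x[101:2148]
  u <- normalizeSeries(beatUniverse(list(beatSeries(x, "Y", unit = "a.u."))))
  em <- fullEmbedding(u, embeddingSpec("Y", c(Y = 1), p = 1))
  eps <- epsTolerance(beatValues(u)[, "Y"])
  se <- shannonEntropy(em@target, eps)
  ce <- conditionalEntropy(em, eps = eps)
  expect_lt(ce, 0.25 * se)
})

test_that("CE forward selection is greedy, pruned and parsimonious on null data", {
  firstPick <- 0L
  for (seed in 1:10) {
    u <- arUniverse(512, 0.9, seed = 700 + seed)
    tr <- forwardSelectCE(u, embeddingSpec("Y", c(Y = 1), p = 8))
    sel <- tr@components
    if (sel$source[1] == "Y" && sel$lag[1] == 1) firstPick <- firstPick + 1L
    for (s in unique(sel$source))
      expect_true(all(diff(sel$lag[sel$source == s]) > 0))
  }
  expect_gte(firstPick, 9L)

  # white noise: no addition removes much information
  for (seed in 1:3) {
    set.seed(800 + seed)
    u <- normalizeSeries(beatUniverse(
      list(beatSeries(rnorm(256), "Y", unit = "a.u."))))
    tr <- forwardSelectCE(u, embeddingSpec("Y", c(Y = 1), p = 8))
    expect_gte(min(tr@criterion), 0.8 * tr@baseline)
  }
})

test_that("the CE complexity index normalizes by the Shannon entropy", {
  comps <- data.frame(source = c("Y", "X"), lag = c(1, 0))
  mk <- function(crit, baseline, optimalDim)
    new("SelectionTrace", method = "CE", effect = "Y", components = comps,
        criterion = crit, baseline = baseline, optimalDim = optimalDim,
        k = 30, theiler = 8, eps = 0.2)
  # no reduction: NCI = 1 at dimension 0
  expect_equal(nci(nciCE(mk(c(2.1, 2.2), baseline = 2, optimalDim = 0))), 1)
  # total reduction: NCI = 0
  expect_equal(nci(nciCE(mk(c(0.5, 0), baseline = 2, optimalDim = 2))), 0)
  expect_equal(nci(nciCE(mk(c(1.0, 1.4), baseline = 2, optimalDim = 1))), 0.5)

  # predictability ordering: strongly autocorrelated series carry less
  # residual information than weakly autocorrelated ones
  wins <- 0L
  for (seed in 1:10) {
    sp <- embeddingSpec("Y", c(Y = 1), p = 8)
    hi <- nci(nciCE(forwardSelectCE(arUniverse(1024, 0.9, seed = 900 + seed), sp)))
    lo <- nci(nciCE(forwardSelectCE(arUniverse(1024, 0.2, seed = 900 + seed), sp)))
    if (hi < lo) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})

test_that("the CE causality ratio obeys the exact-zero rule and detects linear coupling", {
  u <- linearPairUniverse(2048, g = 0.8, seed = 71)
  spY <- pairSpec("Y")
  tr <- forwardSelectCE(u, spY)
  crXY <- crCE(u, spY, "X", trace = tr)
  if (any(selectedComponents(tr)$source == "X")) {
    expect_lt(crValue(crXY), 0)
  } else {
    expect_identical(crValue(crXY), 0)
  }

  # constructed trace without the cause: exactly zero
  comps <- data.frame(source = "Y", lag = 1)
  tr0 <- new("SelectionTrace", method = "CE", effect = "Y",
             components = comps, criterion = 0.9, baseline = 1.2,
             optimalDim = 1, k = 30, theiler = 8, eps = 0.2)
  expect_identical(crValue(crCE(u, spY, "X", trace = tr0)), 0)
})
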