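test_that("the linear fit recovers exact recursions and matches normal equations", {
  # noiseless y(n) = 0.5 y(n-1): coefficient 0.5, zero residual
  # (kept on the raw scale: normalization would shift the mean and the
  # recursion has no intercept)
  y <- numeric(200); y[1] <- 1
  for (n in 2:200) y[n] <- 0.5 * y[n - 1]
  u <- beatUniverse(list(beatSeries(y, "Y", unit = "a.u.")))
  f <- fitMvar(u, embeddingSpec("Y", c(Y = 1), p = 1))
  expect_equal(unname(f@coefficients), 0.5, tolerance = 1e-8)
  expect_lt(f@lambda2, 1e-12)

  # normal-equation oracle on random multivariate instances
  for (seed in 1:8) {
    sim <- simulateCoupled(n = 300, labels = c("A", "B"),
      selfCoefs = list(A = 0.4, B = c(0.3, 0.2)),
      couplings = data.frame(from = "A", to = "B", lag = 1, gain = 0.5,
                             type = "linear"),
      drift = 0, seed = seed)
    u <- normalizeSeries(sim$universe)
    sp <- embeddingSpec("B", c(A = 1, B = 1), p = 3)
    f <- fitMvar(u, sp)
    em <- fullEmbedding(u, sp)
    oracle <- solve(crossprod(em@Z), crossprod(em@Z, em@target))
    expect_equal(unname(f@coefficients), as.numeric(oracle),
                 tolerance = 1e-8)
    expect_equal(f@lambda2,
                 mean((em@target - em@Z %*% oracle)^2), tolerance = 1e-10)
  }

  # an unpredictable target keeps lambda^2 near 1
  set.seed(100)
  u <- normalizeSeries(beatUniverse(
    list(beatSeries(rnorm(10000), "Y", unit = "a.u."),
         beatSeries(rnorm(10000), "X", unit = "a.u."))))
  f <- fitMvar(u, embeddingSpec("Y", c(Y = 1, X = 1), p = 2))
  expect_equal(f@lambda2, 1, tolerance = 0.05)
})

test_that("lambda^2 is non-increasing in the order and the Akaike penalty creates a minimum", {
  u <- arUniverse(2048, 0.8, seed = 21)
  sp <- embeddingSpec("Y", c(Y = 1), p = 8)
  prof <- akaikeOrder(u, sp)$profile
  # each order drops one early row from the sample, so monotonicity holds up
  # to a boundary term of order 1/N
  expect_true(all(diff(prof$lambda2) <= 10 / 2048))
  expect_true(all(diff(prof$q) > 0))

  # single-order range is honored trivially
  expect_identical(akaikeOrder(u, sp, orders = 3)$order, 3)

  # AR(2) with a strong lag-2 term: the selected order is 2 almost always
  hits <- 0L
  for (seed in 1:25) {
    set.seed(seed)
    x <- as.numeric(stats::arima.sim(list(ar = c(0.3, 0.55)), 4096))
    u2 <- normalizeSeries(beatUniverse(list(beatSeries(x, "Y", unit = "a.u."))))
    if (akaikeOrder(u2, sp)$order == 2) hits <- hits + 1L
  }
  # classical AIC is not consistent: with six higher orders competing it
  # overfits with probability near 0.3, so the true order wins about 70%
  # of the time at any sample size
  expect_gte(hits, 15L)

  # white noise: the penalty keeps the order at the low end
  low <- 0L
  for (seed in 1:15) {
    set.seed(seed)
    u3 <- normalizeSeries(beatUniverse(
      list(beatSeries(rnorm(1024), "Y", unit = "a.u."))))
    if (akaikeOrder(u3, sp)$order <= 2) low <- low + 1L
  }
  expect_gte(low, 12L)
})

test_that("the model-based NCI matches analytic residual variance", {
  # AR(1) |a| = 0.9, unit variance: residual variance 1 - a^2 = 0.19
  u <- arUniverse(8192, 0.9, seed = 31)
  res <- nciMB(u, embeddingSpec("Y", c(Y = 1), p = 8))
  expect_equal(nci(res), 0.19, tolerance = 0.03)
  expect_s4_class(res, "ComplexityResult")

  # white noise: NCI near the maximal-complexity bound
  set.seed(32)
  u2 <- normalizeSeries(beatUniverse(
    list(beatSeries(rnorm(8192), "Y", unit = "a.u."),
         beatSeries(rnorm(8192), "X", unit = "a.u."))))
  expect_gte(nci(nciMB(u2, embeddingSpec("Y", c(Y = 1, X = 1), p = 8))), 0.95)

  # noiseless recursion: null complexity (raw scale, single-order range)
  y <- numeric(300); y[1] <- 1
  for (n in 2:300) y[n] <- 0.9 * y[n - 1]
  u3 <- beatUniverse(list(beatSeries(y, "Y", unit = "a.u.")))
  expect_lte(nci(nciMB(u3, embeddingSpec("Y", c(Y = 1), p = 1), orders = 1)),
             1e-8)
})

test_that("the model-based causality ratio detects directed coupling and never exceeds zero", {
  u <- linearPairUniverse(4096, g = 0.8, seed = 41)
  spY <- pairSpec("Y"); spX <- pairSpec("X")
  fwd <- crMB(u, spY, "X")
  rev <- crMB(u, spX, "Y")
  expect_lt(crValue(fwd), -0.1)
  expect_gte(crValue(rev), -0.02)
  expect_identical(fwd@form, "fractional")

  # independent series: both directions essentially null
  set.seed(42)
  u2 <- normalizeSeries(beatUniverse(
    list(beatSeries(rnorm(8192), "X", unit = "a.u."),
         beatSeries(rnorm(8192), "Y", unit = "a.u."))))
  expect_gte(crValue(crMB(u2, pairSpec("Y"), "X")), -0.02)
  expect_lte(crValue(crMB(u2, pairSpec("Y"), "X")), 0)

  # nesting invariant over random instances
  for (seed in 1:10) {
    sim <- simulateTrivariate(n = 256, seed = seed)
    u3 <- normalizeSeries(linearDetrend(sim$universe))
    sp <- cardioSpecs()$HP
    expect_lte(crValue(crMB(u3, sp, "SAP")), 1e-10)
    expect_lte(crValue(crMB(u3, sp, "RESP")), 1e-10)
  }

  # absolute-difference variant is the plain NCI difference
  ab <- crMB(u, spY, "X", form = "absolute")
  expect_equal(ab@cr, ab@nciFull - ab@nciReduced, tolerance = 1e-12)
  expect_error(crMB(u, spY, "Y"), class = "cvcSpecError")
})
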