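test_that("SAP ramp detection applies every criterion strictly", {
  r <- findSapRamps(c(100, 101, 102.5, 104))
  expect_identical(nrow(r), 1L)
  expect_identical(r$direction, 1L)
  expect_equal(r$delta, 4)

  # total change at the 1 mmHg boundary is rejected (strict inequality)
  expect_identical(nrow(findSapRamps(c(100, 100.2, 100.5, 100.9))), 0L)
  expect_identical(nrow(findSapRamps(c(100, 100.3, 100.6, 101))), 0L)

  # a long monotone run yields overlapping ramps, one per window
  r3 <- findSapRamps(c(120, 118, 116, 114, 112, 110))
  expect_identical(nrow(r3), 3L)
  expect_identical(r3$start, 1:3)
  expect_true(all(r3$direction == -1L))

  expect_identical(nrow(findSapRamps(c(100, 103))), 0L)
})

test_that("baroreflex sequences require concordance and both thresholds", {
  sap <- c(100, 101, 102.5, 104)
  hp <- c(800, 810, 822, 835)
  s <- findBaroreflexSequences(hp, sap)
  expect_identical(nrow(s), 1L)
  # hand least-squares in the [SAP, HP] plane: Sxy = 79.375, Sxx = 9.1875
  expect_equal(s$slope, 79.375 / 9.1875, tolerance = 1e-12)
  expect_equal(s$slope, 8.639456, tolerance = 1e-6)

  # HP change of only 4 ms fails the 5 ms rule
  expect_identical(nrow(findBaroreflexSequences(c(800, 801, 802, 804), sap)), 0L)
  # discordant directions never qualify
  expect_identical(nrow(findBaroreflexSequences(rev(hp), sap)), 0L)
  expect_error(findBaroreflexSequences(hp[1:3], sap), class = "cvcInputError")

  # slopes are invariant to constant shifts of either series
  s2 <- findBaroreflexSequences(hp + 100, sap - 20)
  expect_equal(s2$slope, s$slope, tolerance = 1e-12)
})

test_that("BRS and BEI aggregate sequences with undefined-result sentinels", {
  one <- data.frame(start = 1L, direction = 1L, slope = 8.639, r = 1)
  two <- data.frame(start = c(1L, 9L), direction = c(1L, -1L),
                    slope = c(6, 10), r = c(1, 1))
  none <- one[0, ]
  ramps2 <- data.frame(start = c(1L, 9L), direction = c(1L, -1L),
                       delta = c(4, -4), r = c(1, -1))
  expect_equal(brs(one), 8.639)
  expect_equal(brs(two), 8)
  expect_true(is.na(brs(none)))
  expect_equal(bei(one, ramps2), 0.5)
  expect_equal(bei(two, ramps2), 1)
  expect_equal(bei(none, ramps2), 0)
  expect_true(is.na(bei(one, ramps2[0, ])))
})

test_that("the toy generator's ground truth matches the detectors exactly", {
  toy <- simulateBaroreflexToy(nRamps = 4, fractionEffective = 0.5, slopes = 8)
  res <- baroreflexAnalysis(toy$hp, toy$sap)
  expect_identical(res$nRamps, 4L)
  expect_identical(res$nSequences, 2L)
  expect_equal(res$bei, 0.5)
  expect_equal(res$brs, 8, tolerance = 1e-10)

  # every ramp effective, mixed slopes
  toy2 <- simulateBaroreflexToy(nRamps = 6, fractionEffective = 1,
                                slopes = c(6, 10))
  res2 <- baroreflexAnalysis(toy2$hp, toy2$sap)
  expect_identical(res2$nSequences, 6L)
  expect_equal(res2$bei, 1)
  expect_equal(res2$brs, 8, tolerance = 1e-10)

  # no effective ramp: BRS undefined, BEI zero
  toy0 <- simulateBaroreflexToy(nRamps = 3, fractionEffective = 0)
  res0 <- baroreflexAnalysis(toy0$hp, toy0$sap)
  expect_identical(res0$nSequences, 0L)
  expect_true(is.na(res0$brs))
  expect_equal(res0$bei, 0)

  # a slope too shallow to clear the 5 ms criterion is an infeasible spec
  expect_error(simulateBaroreflexToy(nRamps = 2, fractionEffective = 1,
                                     slopes = 1), class = "cvcSpecError")
})

test_that("every sequence's SAP limb is a ramp, so BEI never exceeds one", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 300
    sap <- 120 + cumsum(rnorm(n, 0, 1.2))
    hp <- 900 + cumsum(rnorm(n, 0, 8))
    seqs <- findBaroreflexSequences(hp, sap)
    ramps <- findSapRamps(sap)
    if (nrow(seqs) > 0)
      expect_true(all(seqs$start %in% ramps$start))
    if (nrow(ramps) > 0)
      expect_lte(bei(seqs, ramps), 1)
  }
})
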