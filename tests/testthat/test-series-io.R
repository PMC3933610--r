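test_that("beat tables round-trip through read/write", {
  set.seed(11)
  series <- list(beatSeries(800 + rnorm(256), "HP"),
                 beatSeries(120 + rnorm(256), "SAP"),
                 beatSeries(rnorm(256), "RESP"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeBeatTable(series, f)
  back <- readBeatTable(f)
  expect_named(back, c("HP", "SAP", "RESP"))
  expect_equal(vapply(back, nBeats, integer(1)),
               c(HP = 256L, SAP = 256L, RESP = 256L))
  for (i in 1:3)
    expect_equal(beatValues(back[[i]]), beatValues(series[[i]]),
                 tolerance = 1e-12)
  expect_equal(seriesUnit(back$SAP), "mmHg")
})

test_that("malformed beat tables are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("HP\tSAP\tRESP", f)
  expect_error(readBeatTable(f), class = "cvcInputError")

  set.seed(2)
  m <- matrix(round(rnorm(30), 3), 10, 3,
              dimnames = list(NULL, c("HP", "SAP", "RESP")))
  m <- as.data.frame(m)
  m$SAP <- as.character(m$SAP)
  m$SAP[7] <- "bad"
  write.table(m, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readBeatTable(f), "row 7", class = "cvcInputError")

  writeLines(c("a\tb", "1\t2"), f)
  expect_error(readBeatTable(f), class = "cvcConfigError")
  expect_error(readBeatTable(f, columns = c(HP = "missing")),
               class = "cvcConfigError")
})

test_that("normalization uses the population convention and is idempotent", {
  expect_equal(normalizeSeries(c(1, 2, 3)),
               c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-12)
  set.seed(3)
  v <- rnorm(100, 5, 2)
  z <- normalizeSeries(v)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)
  expect_equal(normalizeSeries(z), z, tolerance = 1e-12)
  expect_error(normalizeSeries(c(5, 5, 5)), class = "cvcDegenerateError")

  u <- normalizeSeries(beatUniverse(list(beatSeries(v, "HP"),
                                         beatSeries(rnorm(100), "SAP"))))
  expect_true(u@normalized)
  expect_true(validObject(u))
})

test_that("linear detrending removes exactly the least-squares line", {
  expect_equal(linearDetrend(c(1, 2, 3, 4)), rep(0, 4), tolerance = 1e-12)
  set.seed(4)
  v <- rnorm(200)
  n <- seq_along(v)
  expect_equal(linearDetrend(v + 0.3 * n - 2), linearDetrend(v),
               tolerance = 1e-10)
  # residuals orthogonal to the [1, n] regressors
  for (seed in 1:5) {
    set.seed(seed)
    w <- linearDetrend(rnorm(128) + seed * 0.1 * seq_len(128))
    expect_lt(abs(sum(w)), 1e-8 * 128)
    expect_lt(abs(sum(w * seq_len(128))), 1e-6 * 128)
  }
  # closed-form OLS line comparison on white noise
  set.seed(5)
  v <- rnorm(64)
  fit <- lm(v ~ seq_along(v))
  expect_equal(linearDetrend(v), unname(residuals(fit)), tolerance = 1e-10)
})

test_that("window selection is reproducible, in-bounds and stationarity-aware", {
  set.seed(6)
  v <- rnorm(256)
  expect_identical(selectWindow(v, length = 256)$start, 1L)

  long <- rnorm(1000)
  w1 <- selectWindow(long, length = 256, seed = 99)
  w2 <- selectWindow(long, length = 256, seed = 99)
  expect_identical(w1$start, w2$start)
  for (seed in 1:20) {
    w <- selectWindow(long, length = 256, seed = seed)
    expect_gte(w$start, 1L)
    expect_lte(w$start, 1000 - 256 + 1)
  }
  expect_error(selectWindow(rnorm(100), length = 256),
               class = "cvcInputError")

  # a large step at midpoint: chosen windows avoid the step (windows
  # touching it by a handful of boundary beats carry no evident
  # nonstationarity, so they count as clean)
  stepped <- c(rnorm(600), rnorm(600) + 8)
  hits <- 0L
  for (seed in 1:200) {
    w <- suppressWarnings(selectWindow(stepped, length = 256, seed = seed))
    before <- max(min(600 - w$start + 1, 256), 0)
    if (min(before, 256 - before) <= 8) hits <- hits + 1L
  }
  expect_gte(hits, 190L)
})

test_that("prepareUniverse windows, detrends then normalizes", {
  set.seed(7)
  series <- list(HP = beatSeries(800 + cumsum(rnorm(400, 0, 2)), "HP"),
                 SAP = beatSeries(120 + rnorm(400), "SAP"),
                 RESP = beatSeries(rnorm(400), "RESP"))
  prep <- suppressWarnings(prepareUniverse(series, seed = 1))
  expect_s4_class(prep$universe, "BeatUniverse")
  expect_true(prep$universe@normalized)
  expect_identical(nBeats(prep$universe), 256L)
  expect_identical(nBeats(prep$raw$HP), 256L)
  # raw window preserves original units and values
  idx <- prep$window$start:(prep$window$start + 255)
  expect_equal(beatValues(prep$raw$HP), beatValues(series$HP)[idx])
})
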