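# Synthetic beat-to-beat series with known causal structure. These stand in
# for recorded HP/SAP/RESP windows: coupled stochastic autoregressions with
# Gaussian innovations, optional quadratic (nonlinear) links, optional
# instantaneous (lag-0) links, and an optional slow linear drift emulating
# the weak nonstationarity of real recordings (removed downstream by the
# detrending step).

#' Simulate coupled stochastic series with known causal structure
#'
#' Generates M series from linear autoregressions driven by i.i.d. Gaussian
#' noise plus directed couplings described one per row of \code{couplings}:
#' a linear link adds \code{gain * source(n - lag)} to the target equation,
#' a quadratic link adds \code{gain * source(n - lag)^2} (invisible to
#' linear analysis since a Gaussian source is uncorrelated with its square).
#' Instantaneous links (lag 0) must form an acyclic graph (series are
#' generated in a topological order of the within-beat links). The linear
#' part must be stable (companion-matrix spectral radius < 1).
#'
#' @param n series length in beats (default 256, the conventional analysis
#'   window; >= 64).
#' @param labels series labels, in order.
#' @param selfCoefs named list of autoregressive coefficient vectors (lag 1
#'   upward), one per series.
#' @param couplings data.frame with columns \code{from}, \code{to},
#'   \code{lag}, \code{gain} and optionally \code{type}
#'   (\code{"linear"}/\code{"quadratic"}).
#' @param noiseSD innovation standard deviations (recycled over series).
#' @param drift slow linear trend added to each series, expressed as a
#'   fraction of its SD over the whole record (default 0.1, a weak
#'   nonstationarity).
#' @param seed optional integer seed (reproducible output).
#' @param burnIn transient samples discarded (default 200).
#' @return list with \code{universe} (raw \linkS4class{BeatUniverse}),
#'   \code{truth} (M x M logical matrix, \code{truth[from, to]} TRUE iff a
#'   nonzero-gain link from -> to exists) and \code{couplings}.
#' @examples
#' sim <- simulateCoupled(n = 256, labels = c("X", "Y"),
#'   selfCoefs = list(X = 0.5, Y = 0.5),
#'   couplings = data.frame(from = "X", to = "Y", lag = 1, gain = 0.8),
#'   seed = 1)
#' sim$truth
#' @export
simulateCoupled <- function(n = 256, labels = c("HP", "SAP", "RESP"),
                            selfCoefs = NULL, couplings = NULL,
                            noiseSD = 1, drift = 0.1, seed = NULL,
                            burnIn = 200) {
  if (n < 64) .cvcStop("need n >= 64 beats", "cvcSpecError")
  M <- length(labels)
  if (is.null(selfCoefs))
    selfCoefs <- stats::setNames(rep(list(0.5), M), labels)
  if (is.null(couplings))
    couplings <- data.frame(from = character(0), to = character(0),
                            lag = integer(0), gain = numeric(0))
  if (is.null(couplings$type) && nrow(couplings) > 0)
    couplings$type <- "linear"
  noiseSD <- rep_len(noiseSD, M)
  # generation order: topological in the lag-0 (instantaneous) link graph
  inst <- couplings[couplings$lag == 0, , drop = FALSE]
  ord <- integer(0)
  left <- seq_len(M)
  while (length(left)) {
    free <- left[vapply(left, function(i)
      !any(inst$to == labels[i] & inst$from %in% labels[left]), logical(1))]
    if (!length(free))
      .cvcStop("instantaneous (lag-0) links form a cycle", "cvcSpecError")
    ord <- c(ord, free[1])
    left <- setdiff(left, free[1])
  }
  # stability of the linear part via the companion matrix
  L <- max(1L, unlist(lapply(selfCoefs, length)),
           if (nrow(couplings)) couplings$lag else 0L)
  B0 <- matrix(0, M, M, dimnames = list(labels, labels))
  Bl <- lapply(seq_len(L), function(l)
    matrix(0, M, M, dimnames = list(labels, labels)))
  for (i in seq_len(M)) {
    ac <- selfCoefs[[labels[i]]]
    for (l in seq_along(ac)) Bl[[l]][i, i] <- ac[l]
  }
  if (nrow(couplings)) {
    lin <- couplings[couplings$type == "linear", , drop = FALSE]
    for (r in seq_len(nrow(lin))) {
      i <- match(lin$to[r], labels)
      j <- match(lin$from[r], labels)
      if (lin$lag[r] == 0) B0[i, j] <- B0[i, j] + lin$gain[r]
      else Bl[[lin$lag[r]]][i, j] <- Bl[[lin$lag[r]]][i, j] + lin$gain[r]
    }
  }
  inv <- solve(diag(M) - B0)
  A <- lapply(Bl, function(b) inv %*% b)
  comp <- matrix(0, M * L, M * L)
  for (l in seq_len(L))
    comp[seq_len(M), (l - 1) * M + seq_len(M)] <- A[[l]]
  if (L > 1)
    comp[(M + 1):(M * L), seq_len(M * (L - 1))] <- diag(M * (L - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    .cvcStop(sprintf("unstable linear system (spectral radius %.3f >= 1)", rho),
             "cvcSpecError")
  if (!is.null(seed)) set.seed(seed)
  total <- n + burnIn
  x <- matrix(0, total, M)
  eps <- matrix(rnorm(total * M), total, M) %*% diag(noiseSD, M)
  for (t in seq_len(total)) {
    for (i in ord) {
      v <- eps[t, i]
      ac <- selfCoefs[[labels[i]]]
      for (l in seq_along(ac))
        if (t - l >= 1) v <- v + ac[l] * x[t - l, i]
      if (nrow(couplings)) {
        ci <- couplings[couplings$to == labels[i], , drop = FALSE]
        for (r in seq_len(nrow(ci))) {
          tl <- t - ci$lag[r]
          if (tl >= 1) {
            s <- x[tl, match(ci$from[r], labels)]
            v <- v + ci$gain[r] * if (ci$type[r] == "quadratic") s^2 else s
          }
        }
      }
      x[t, i] <- v
    }
  }
  x <- x[(burnIn + 1):total, , drop = FALSE]
  if (drift != 0) {
    tr <- (seq_len(n) - (n + 1) / 2) / n
    for (i in seq_len(M)) x[, i] <- x[, i] + drift * sd(x[, i]) * tr
  }
  colnames(x) <- labels
  truth <- matrix(FALSE, M, M, dimnames = list(labels, labels))
  if (nrow(couplings))
    for (r in seq_len(nrow(couplings)))
      if (couplings$gain[r] != 0)
        truth[couplings$from[r], couplings$to[r]] <- TRUE
  list(universe = beatUniverse(x), truth = truth, couplings = couplings)
}

#' Simulate a trivariate cardiovascular-like recording
#'
#' Default study conditions: three coupled series of 256 beats labeled HP,
#' SAP and RESP, with a fast within-beat (lag-0) link SAP -> HP (baroreflex
#' arm) and RESP -> HP (respiratory sinus arrhythmia), a delayed link
#' HP -> SAP (runoff/Frank-Starling pathway, lag 1) and a within-beat
#' mechanical link RESP -> SAP. RESP is an oscillatory AR(2); all
#' innovations are Gaussian.
#'
#' @inheritParams simulateCoupled
#' @param ... further arguments passed to \code{\link{simulateCoupled}}.
#' @return as \code{\link{simulateCoupled}}.
#' @export
simulateTrivariate <- function(n = 256, seed = NULL, ...) {
  simulateCoupled(
    n = n, labels = c("HP", "SAP", "RESP"),
    selfCoefs = list(HP = 0.6, SAP = 0.5, RESP = c(1.2, -0.6)),
    couplings = data.frame(
      from = c("SAP", "RESP", "HP", "RESP"),
      to = c("HP", "HP", "SAP", "SAP"),
      lag = c(0, 0, 1, 0),
      gain = c(0.3, 0.3, -0.3, 0.3),
      type = "linear"),
    seed = seed, ...)
}

#' Construct an HP/SAP toy pair with exact baroreflex ground truth
#'
#' Builds raw-unit HP and SAP series embedding exactly \code{nRamps}
#' criterion-satisfying SAP ramps (alternating directions, 1.5 mmHg steps,
#' perfectly linear so the within-ramp correlation is 1), of which the first
#' \code{round(nRamps * fractionEffective)} are paired with concordant HP
#' runs of exact slope \code{slopes} (ms/mmHg). Filler beats alternate in
#' sign with sub-threshold steps, so they can never complete a ramp or a
#' sequence; hence the detector counts equal the constructed ground truth
#' and BEI equals \code{fractionEffective} exactly.
#'
#' @param nRamps number of SAP ramps to embed (>= 1).
#' @param fractionEffective fraction of ramps paired with an HP response in
#'   [0, 1]; \code{nRamps * fractionEffective} should be an integer.
#' @param slopes baroreflex slope(s) in ms/mmHg for the effective ramps
#'   (recycled); each must exceed 5/4.5 so the 5 ms HP-change criterion is
#'   met over a 4.5 mmHg ramp.
#' @param seed accepted for interface symmetry; the construction is
#'   deterministic.
#' @return list with \code{hp}, \code{sap} (\linkS4class{BeatSeries}),
#'   \code{nRamps}, \code{nSequences}, \code{slopes} (per effective
#'   sequence), \code{brs} (expected mean slope, NA when no sequence) and
#'   \code{bei} (expected ratio).
#' @export
simulateBaroreflexToy <- function(nRamps = 4, fractionEffective = 0.5,
                                  slopes = 8, seed = NULL) {
  if (nRamps < 1) .cvcStop("need at least one ramp", "cvcSpecError")
  if (fractionEffective < 0 || fractionEffective > 1)
    .cvcStop("fractionEffective must lie in [0, 1]", "cvcSpecError")
  nEff <- round(nRamps * fractionEffective)
  slopes <- rep_len(slopes, max(nEff, 1L))[seq_len(nEff)]
  if (any(slopes <= 5 / 4.5))
    .cvcStop("slopes must exceed 5/4.5 ms/mmHg for the HP criterion over a 4.5 mmHg ramp",
             "cvcSpecError")
  sapStep <- 1.5
  ds <- numeric(0)   # SAP diffs
  dh <- numeric(0)   # HP diffs
  filler <- function(m) {
    for (i in seq_len(m)) {
      ds <<- c(ds, if (length(ds)) -sign(ds[length(ds)]) * 0.3 else 0.3)
      dh <<- c(dh, if (length(dh)) -sign(dh[length(dh)]) * 1 else 1)
    }
  }
  filler(6)
  eff <- 0L
  for (r in seq_len(nRamps)) {
    dir <- if (r %% 2 == 1) 1 else -1
    if (sign(ds[length(ds)]) == dir) filler(1)
    effective <- r <= nEff
    for (s in 1:3) {
      ds <- c(ds, dir * sapStep)
      dh <- c(dh, if (effective) dir * sapStep * slopes[r]
              else -sign(dh[length(dh)]) * 1)
    }
    if (effective) eff <- eff + 1L
    filler(6)
  }
  sap <- 120 + cumsum(c(0, ds))
  hp <- 900 + cumsum(c(0, dh))
  list(hp = beatSeries(hp, "HP"), sap = beatSeries(sap, "SAP"),
       nRamps = as.integer(nRamps), nSequences = as.integer(nEff),
       slopes = slopes,
       brs = if (nEff > 0) mean(slopes) else NA_real_,
       bei = nEff / nRamps)
}

#' Simulate a cohort table of index versus age
#'
#' Ages are uniform on [21, 70] (the conventional adult span); the index is
#' \code{slope * age + N(0, noiseSD^2)}.
#'
#' @param nSubjects number of subjects (>= 10).
#' @param slope index-versus-age slope.
#' @param noiseSD Gaussian noise SD.
#' @param seed optional seed.
#' @return data.frame with \code{subject}, \code{age}, \code{index}.
#' @export
simulateCohort <- function(nSubjects = 100, slope = 0, noiseSD = 1,
                           seed = NULL) {
  if (nSubjects < 10) .cvcStop("need at least 10 subjects", "cvcSpecError")
  if (!is.null(seed)) set.seed(seed)
  age <- runif(nSubjects, 21, 70)
  data.frame(subject = sprintf("S%03d", seq_len(nSubjects)), age = age,
             index = slope * age + rnorm(nSubjects, 0, noiseSD))
}
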