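# Temperature series: assembly, the intermediate-state maximum, and the
# high-temperature release / trap-and-destroy classification.

mkEntries <- function(Ts, phis, dis = rep(1, length(Ts))) {
  lapply(seq_along(Ts), function(i) {
    w <- as.numeric(phis[i, ])
    res <- new("DecompositionResult",
               weights = c(free = w[1], intermediate = w[2], strong = w[3]),
               weightErrors = rep(0.01, 3), refinedParams = list(),
               rmsdPct = 1, fittedTrace = numeric(1), baseline = numeric(1),
               conditionNumber = 1)
    list(temperatureK = Ts[i], result = res, totalDI = dis[i])
  })
}

test_that("series assembly sorts, averages duplicates and flags frozen rows", {
  Ts <- c(283.15, 263.15, 303.15, 293.15, 293.15, 323.15)
  phis <- matrix(rep(c(0.3, 0.5, 0.2), each = 6), ncol = 3)
  ts <- buildTemperatureSeries(mkEntries(Ts, phis, dis = c(2, 2, 2, 2, 2, 2)))
  tab <- ts@table
  expect_false(is.unsorted(tab$temperatureK))
  expect_equal(nrow(tab), 5)             # duplicates averaged
  expect_false(tab$analyzed[tab$temperatureK < 273.15])
  # total DI normalized to the lowest analyzed temperature
  expect_equal(tab$totalDI[tab$analyzed][1], 1)

  # constant truth gives flat fraction columns
  expect_equal(var(tab$phiIntermediate), 0)

  # shuffling the input does not change the result
  perm <- sample(seq_along(Ts))
  ts2 <- buildTemperatureSeries(mkEntries(Ts[perm], phis[perm, , drop = FALSE],
                                          dis = rep(2, 6)))
  expect_equal(ts2@table, tab)

  expect_error(buildTemperatureSeries(mkEntries(c(275, 280, 285),
                                                matrix(1 / 3, 3, 3))),
               "insufficient-series")
})

test_that("the intermediate maximum is located by quadratic interpolation", {
  Ts <- seq(273.15, 363.15, by = 5)
  # smooth interior peak at 310 K
  phiI <- exp(-((Ts - 310) / 25)^2)
  phis <- cbind((1 - phiI) / 2, phiI, (1 - phiI) / 2)
  ts <- buildTemperatureSeries(mkEntries(Ts, phis))
  ts <- intermediateMaximum(ts)
  expect_lt(abs(ts@tIntermediateMax - 310), 2.5)
  expect_false(ts@evidence$intermediateMax$edge)

  # monotone column: maximum at the edge, warning, no interpolation
  phisMono <- cbind(1 - seq(0.2, 0.8, length.out = length(Ts)),
                    seq(0.2, 0.8, length.out = length(Ts)), 0)
  tsm <- buildTemperatureSeries(mkEntries(Ts, phisMono))
  expect_warning(tsm <- intermediateMaximum(tsm), "edge warning")
  expect_equal(tsm@tIntermediateMax, max(Ts))

  # exact ties break towards the lower temperature and are flagged
  phiTie <- rep(0.4, length(Ts))
  phiTie[c(5, 9)] <- 0.6
  tst <- buildTemperatureSeries(mkEntries(Ts, cbind(1 - phiTie - 0.1, phiTie, 0.1)))
  expect_warning(tst <- intermediateMaximum(tst), "tie")
  expect_lte(tst@tIntermediateMax, Ts[6])
})

test_that("high-temperature rules separate release, destruction and dynamics", {
  Ts <- seq(273.15, 363.15, by = 5)
  n <- length(Ts)

  # release: free fraction rises, integral retained
  free <- 0.05 + 0.5 * pmax(Ts - 323.15, 0) / 40
  phis <- cbind(free, 0.7 - free / 2, 0.3 - free / 2)
  rel <- classifyHighT(buildTemperatureSeries(mkEntries(Ts, phis)))
  expect_equal(rel@classification, "release")
  expect_gte(rel@evidence$classification$freeRise, 0.15)

  # destruction: integral collapses without free-fraction rise
  dis <- ifelse(Ts > 328.15, pmax(0.3, 1 - 0.02 * (Ts - 328.15)), 1)
  phisD <- matrix(rep(c(0.05, 0.55, 0.4), each = n), ncol = 3)
  des <- classifyHighT(buildTemperatureSeries(mkEntries(Ts, phisD, dis)))
  expect_equal(des@classification, "trap_destroy")

  # constant series: dynamics only
  con <- classifyHighT(buildTemperatureSeries(mkEntries(Ts, phisD)))
  expect_equal(con@classification, "dynamics_only")

  # classification is invariant to uniform rescaling of all intensities
  des2 <- classifyHighT(buildTemperatureSeries(mkEntries(Ts, phisD, dis * 37)))
  expect_equal(des2@classification, "trap_destroy")

  shortTs <- seq(273.15, 313.15, by = 10)
  expect_error(
    classifyHighT(buildTemperatureSeries(
      mkEntries(shortTs, matrix(1 / 3, length(shortTs), 3)))),
    "333.15")
})

test_that("generated spectra round-trip through decomposition to the truth maximum", {
  # weaker-affinity truth shifts the intermediate maximum to ~310 K;
  # located first by direct evaluation, then recovered through the full
  # generate -> decompose -> assemble chain
  p <- truthParams(preset = "fabp3_like", K_I = 18, noiseSnr = 200, seed = 4)
  Tfine <- seq(293.15, 333.15, by = 0.5)
  phiFine <- vapply(Tfine, function(T) truthFractions(100, 20, p, T)[["intermediate"]],
                    numeric(1))
  tTrue <- Tfine[which.max(phiFine)]
  expect_lt(abs(tTrue - 310), 8)

  ser <- synthTemperatureSeries(p, fieldMT = testAxis())
  lib <- fabpComponents(p$protein, p$probe)
  entries <- lapply(ser, function(s) {
    f <- fitWeights(s$trace, lib)
    list(temperatureK = s$temperatureK, result = f,
         totalDI = fittedDoubleIntegral(f, fieldAxis(s$trace)))
  })
  ts <- intermediateMaximum(buildTemperatureSeries(entries))
  expect_lt(abs(ts@tIntermediateMax - tTrue), 5.1)  # within ~one grid step
})
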