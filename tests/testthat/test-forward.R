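# Forward simulation: resonance positions, motional linewidths, single
# components, mixtures, and the engine fidelity contract.

test_that("fast-motion resonance positions follow h*nu/(g*muB) and the hyperfine spacing", {
  # centre field from fundamental constants
  pos0 <- resonancePositionsFast(2.0060, 0, 9.4)
  expect_equal(pos0, rep(334.79, 3), tolerance = 1e-4)

  # 44.1 MHz isotropic coupling -> 1.571 mT adjacent-line spacing
  pos <- resonancePositionsFast(2.0060, 44.1, 9.4)
  expect_equal(diff(pos), rep(1.5707, 2), tolerance = 1e-3)

  # first-order symmetry for arbitrary parameters
  for (a in c(10, 44.1, 90)) {
    p <- resonancePositionsFast(2.0045, a, 9.8)
    expect_equal(diff(p)[1], diff(p)[2], tolerance = 1e-12)
  }
  expect_error(resonancePositionsFast(-2, 44, 9.4), "invalid-parameter")
  expect_error(resonancePositionsFast(2.006, 44, 0), "invalid-parameter")
})

test_that("fast-motion linewidths carry the A + B*mI + C*mI^2 structure", {
  B0 <- centreField(2.0060, 9.47)

  # isotropic tensors: anisotropy terms vanish, three equal widths
  iso <- spinComponent("free", gTensor = rep(2.0060, 3),
                       ATensor = rep(44.1, 3), tauC = 0.1, lwLorentz = 0.05)
  wIso <- fastMotionLinewidths(iso, B0)
  expect_equal(unname(wIso[1]), unname(wIso[2]))
  expect_equal(unname(wIso[2]), unname(wIso[3]))

  # nitroxide-typical tensors: high-field (mI = -1) line broadest
  nx <- spinComponent("free", tauC = 0.1)
  w <- fastMotionLinewidths(nx, B0)
  expect_true(all(w > 0))
  expect_gt(w[["mI-1"]], w[["mI+1"]])

  # the motional contribution is linear in tau_c up to the small
  # nonsecular spectral-density terms
  co1 <- spinbind:::.redfieldCoefficients(nx@gTensor, nx@ATensor, B0, 0.1)
  co2 <- spinbind:::.redfieldCoefficients(nx@gTensor, nx@ATensor, B0, 0.2)
  expect_equal(co2$B / co1$B, 2, tolerance = 0.05)
  expect_equal(co2$C / co1$C, 2, tolerance = 0.05)

  expect_warning(fastMotionLinewidths(spinComponent("free", tauC = 5), B0),
                 "fast-regime")
})

test_that("a free nitroxide component gives three sharp derivative lines", {
  B <- testAxis()
  y <- simulateComponent(spinComponent("free", tauC = 0.1, lwGauss = 0.135),
                         B, 9.47)
  expect_true(all(is.finite(y)))
  # three lines <=> six extrema (sign changes of the trace's slope)
  dy <- diff(y)
  dy <- dy[abs(dy) > max(abs(dy)) * 1e-4]
  expect_equal(sum(diff(sign(dy)) != 0), 6)
  # unit-spins normalization
  expect_equal(doubleIntegral(B, y), 1, tolerance = 1e-9)
})

test_that("the rigid limit converges to an outer splitting of 2*Azz within 2 percent", {
  Bw <- seq(330, 346, length.out = 2048)
  comp <- spinComponent("strong", ATensor = c(15.5, 15.5, 90), tauC = 1000,
                        lwLorentz = 0.1)
  y <- simulateComponent(comp, Bw, 9.47, engine = "slow")
  sep <- outerExtremaSplitting(Bw, y)
  expect_equal(sep, 2 * mhzToMilliTesla(90, comp@gTensor[3]), tolerance = 0.02)
})

test_that("Gaussian broadening leaves the double integral unchanged", {
  Bw <- seq(326, 348, length.out = 4096)
  for (tau in c(0.1, 4.8)) {
    base <- spinComponent("free", tauC = tau, lwLorentz = 0.1)
    broad <- spinComponent("free", tauC = tau, lwLorentz = 0.1, lwGauss = 0.14)
    d1 <- doubleIntegral(Bw, simulateComponent(base, Bw, 9.47, normalize = "none"))
    d2 <- doubleIntegral(Bw, simulateComponent(broad, Bw, 9.47, normalize = "none"))
    expect_equal(d2 / d1, 1, tolerance = 0.005)
  }
})

test_that("double integral is conserved across tau_c and exchange on a wide window", {
  Bw <- seq(315, 360, length.out = 4096)
  variants <- list(
    spinComponent("free", tauC = 0.1, lwGauss = 0.135),
    spinComponent("free", tauC = 0.1, lwGauss = 0.135, exchangeFreq = 2.7),
    spinComponent("intermediate", tauC = 4.8, exchangeFreq = 2.7,
                  eulerDeg = c(0, 50, 0)),
    spinComponent("strong", tauC = 17.9, lwLorentz = 0.1,
                  eulerDeg = c(0, 50, 0))
  )
  dis <- vapply(variants, function(cc) {
    doubleIntegral(Bw, simulateComponent(cc, Bw, 9.47, normalize = "none"))
  }, numeric(1))
  expect_true(all(abs(dis / dis[1] - 1) < 0.005 + 0.01))
  expect_true(all(abs(dis - 1) < 0.02))
})

test_that("fast and slow engines agree in the motional-narrowing regime", {
  B <- testAxis()
  for (tau in c(0.1, 0.3)) {
    comp <- spinComponent("free", tauC = tau, lwGauss = 0.135)
    yf <- simulateComponent(comp, B, 9.47, engine = "fast")
    ys <- simulateComponent(comp, B, 9.47, engine = "slow")
    rms <- sqrt(mean((yf - ys)^2)) / (max(yf) - min(yf))
    expect_lt(rms, 0.05)
  }
})

test_that("central-line broadening is monotone in tau_c", {
  B <- testAxis()
  taus <- c(0.1, 0.3, 0.5, 1, 2, 3, 5, 8, 12, 20, 30)
  widths <- vapply(taus, function(t) {
    y <- simulateComponent(spinComponent("free", tauC = t, lwGauss = 0.1), B, 9.47)
    n <- length(B)
    idx <- (n %/% 3):(2 * n %/% 3)
    B[idx][which.min(y[idx])] - B[idx][which.max(y[idx])]
  }, numeric(1))
  expect_true(all(diff(widths) >= -1e-9))
})

test_that("a grossly truncated window raises a window error", {
  Bnarrow <- seq(336, 338, length.out = 128)
  expect_error(
    simulateComponent(spinComponent("strong", tauC = 17.9, lwLorentz = 0.1),
                      Bnarrow, 9.47),
    "window error")
})

test_that("mixtures are linear in the weights and recover them as DI shares", {
  B <- testAxis()
  lib <- fabp3Lib()

  # identity at a pure weight vector
  one <- simulateMixture(lib, c(1, 0, 0), B)
  single <- simulateComponent(lib$free, B, 9.47)
  expect_equal(intensity(one), single, tolerance = 1e-12)

  # linearity
  half <- simulateMixture(lib[1:2], c(0.5, 0.5), B)
  avg <- (simulateComponent(lib$free, B, 9.47) +
            simulateComponent(lib$intermediate, B, 9.47)) / 2
  expect_equal(intensity(half), avg, tolerance = 1e-12)

  # three-state mixture: double-integral shares recover the weights
  w <- c(0.27, 0.55, 0.18)
  comps <- lapply(seq_along(lib), function(i) {
    w[i] * simulateComponent(lib[[i]], B, 9.47)
  })
  expect_equal(unname(fractionsFromDoubleIntegrals(comps, B)), w,
               tolerance = 1e-6)

  expect_error(simulateMixture(lib, c(0.5, 0.2, 0.2), B), "normalization error")
  expect_error(simulateMixture(lib, c(-0.1, 0.6, 0.5), B), "normalization error")
})

test_that("optional pseudo-modulation broadens without destroying the area", {
  B <- testAxis()
  comp <- spinComponent("free", tauC = 0.1, lwGauss = 0.135)
  y0 <- simulateComponent(comp, B, 9.47, normalize = "none")
  ym <- simulateComponent(comp, B, 9.47, normalize = "none", modAmpMT = 0.1)
  expect_equal(doubleIntegral(B, ym) / doubleIntegral(B, y0), 1,
               tolerance = 0.005)
  expect_lt(max(abs(ym)), max(abs(y0)))
})
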