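# Mass-action and van't Hoff thermodynamics: concentrations, KD/KA,
# Gibbs energies, three-state transitions and error propagation.

test_that("state concentrations are fractions times the total ligand", {
  x <- concentrationsFromFractions(
    c(free = 0.27, intermediate = 0.55, strong = 0.18), 20)
  expect_equal(unname(x), c(5.4, 11.0, 3.6))
  expect_equal(sum(x), 20, tolerance = 1e-9)

  allFree <- concentrationsFromFractions(
    c(free = 1, intermediate = 0, strong = 0), 20)
  expect_equal(unname(allFree), c(20, 0, 0))

  # the worked equimolar case: 72.2 percent bound of 20 uM
  expect_equal(0.722 * 20, 14.44)
  expect_equal((1 - 0.722) * 20, 5.56)
})

test_that("KD from a bound fraction matches hand-computed mass action", {
  expect_equal(kdFromMassAction(20, 20, 0.722), 2.14, tolerance = 1e-3)
  expect_equal(kdFromMassAction(100, 20, 0.9), (100 - 18) * (20 - 18) / 18,
               tolerance = 1e-12)
  # Phi -> 1 with protein excess drives KD -> 0+
  expect_lt(kdFromMassAction(100, 20, 0.999999), 1e-3)
  expect_error(kdFromMassAction(20, 20, 0), "no-binding")
  expect_error(kdFromMassAction(20, 20, 1), "stoichiometry")
  expect_error(kdFromMassAction(10, 20, 0.6), "stoichiometry")
})

test_that("phi/KD round-trip holds across concentration ratios", {
  for (ratio in c(0.25, 1, 2.5, 5, 10)) {
    cP <- 20 * ratio
    for (phi in c(0.01, 0.2, 0.5, 0.722, 0.99)) {
      if (phi >= min(1, cP / 20)) next
      kd <- kdFromMassAction(cP, 20, phi)
      expect_gt(kd, 0)
      expect_equal(phiFromKd(cP, 20, kd), phi, tolerance = 1e-9)
    }
  }
})

test_that("van't Hoff Gibbs energies reproduce the printed report chains", {
  expect_equal(gibbsFromK(1, 310.15), 0)

  # MST rows at 295.15 K: KD 3.5 uM -> -30.8 kJ/mol
  expect_equal(gibbsFromK(1 / 3.5e-6, 295.15), -30.8, tolerance = 0.05)

  # EPR-derived rows at 310.15 K: KD 2.06 uM -> -33.8 kJ/mol
  expect_equal(gibbsFromK(1 / 2.06e-6, 310.15), -33.8, tolerance = 0.05)

  # strictly decreasing in KA, exergonic for all paper-like inputs
  kas <- 10^seq(3, 7, by = 0.5)
  dgs <- gibbsFromK(kas, 310.15)
  expect_true(all(diff(dgs) < 0))
  expect_true(all(dgs < 0))
  expect_error(gibbsFromK(0, 310.15), "domain error")
})

test_that("three-state transitions compose the mass-action rules", {
  phi <- c(free = 0.1, intermediate = 0.6, strong = 0.3)
  tab <- equilibriumConstantsThreeState(100, 20, phi, 310.15)
  expect_equal(tab$transition, c("F-T", "F-I", "F-S", "I-S"))
  expect_equal(tab$KD_uM[tab$transition == "F-T"], 9.111111, tolerance = 1e-6)
  expect_equal(tab$K_IS[tab$transition == "I-S"], 0.5)

  # equal populations: K_IS = 1, dG_IS = 0
  tabEq <- equilibriumConstantsThreeState(
    100, 20, c(free = 0.4, intermediate = 0.3, strong = 0.3), 310.15)
  expect_equal(tabEq$dG_kJ_mol[4], 0, tolerance = 1e-12)

  # absent strong component: K_IS = 0, dG_IS undefined
  tab0 <- equilibriumConstantsThreeState(
    100, 20, c(free = 0.3, intermediate = 0.7, strong = 0), 310.15)
  expect_equal(tab0$K_IS[4], 0)
  expect_true(is.na(tab0$dG_kJ_mol[4]))
  expect_true(is.na(tab0$KD_uM[tab0$transition == "F-S"]))

  expect_error(equilibriumConstantsThreeState(
    100, 20, c(free = 0.7, intermediate = 0, strong = 0.3), 310.15),
    "K_IS undefined")
})

test_that("the I-S Gibbs energy is reported along both computation routes", {
  phi <- c(free = 0.1, intermediate = 0.6, strong = 0.3)
  tab <- equilibriumConstantsThreeState(100, 20, phi, 310.15)
  direct <- tab$dG_kJ_mol[tab$transition == "I-S"]
  chain <- tab$dG_chain_kJ_mol[tab$transition == "I-S"]
  expect_true(is.finite(direct) && is.finite(chain))
  # the dimensionless-ratio route and the mass-action chain are different
  # models of the same transition and need not coincide
  expect_false(isTRUE(all.equal(direct, chain, tolerance = 1e-6)))
})

test_that("first-order error propagation matches a finite-difference oracle", {
  phi <- c(free = 0.278, intermediate = 0.5, strong = 0.222)
  err <- propagateErrors(20, 20, phi, 0.02, 310.15)
  fd <- (kdFromMassAction(20, 20, 0.722 + 1e-6) -
           kdFromMassAction(20, 20, 0.722 - 1e-6)) / 2e-6
  expect_equal(err$sd_KD_uM[err$transition == "F-T"], abs(fd) * 0.02,
               tolerance = 0.01)

  # zero fraction error propagates to zero everywhere
  err0 <- propagateErrors(20, 20, phi, 0, 310.15)
  expect_true(all(err0$sd_KD_uM[1:3] == 0))

  # sigma_dG is linear in T at fixed relative KD error
  e1 <- propagateErrors(20, 20, phi, 0.02, 300)
  e2 <- propagateErrors(20, 20, phi, 0.02, 600)
  expect_equal(e2$sd_dG_kJ_mol[1] / e1$sd_dG_kJ_mol[1], 2, tolerance = 1e-9)
})

test_that("the MST chain propagates a KD error through KA, lnKA and dG", {
  ch <- thermoChainFromKd(3.5, 295.15, kdErrUM = 0.4)
  expect_equal(ch$sd_lnKA, 0.4 / 3.5, tolerance = 1e-12)
  expect_equal(ch$sd_dG_kJ_mol, 8.314 * 295.15 * (0.4 / 3.5) / 1000,
               tolerance = 1e-12)
})
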