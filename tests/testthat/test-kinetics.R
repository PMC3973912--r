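test_that("thermokinetic force handles stoichiometric multiplicities", {
  ab_c <- reaction("r", c(a = -1, b = -1, c = 1))
  expect_equal(force(ab_c, c(a = 1, b = 1, c = 1)), 0)
  expect_equal(force(ab_c, c(a = 2, b = 3, c = 5)), 1)
  # 2A <-> B: product over multiplicities, 3^2 - 4
  aa_b <- reaction("r2", c(a = -2, b = 1))
  expect_equal(force(aa_b, c(a = 3, b = 4)), 5)
  expect_error(force(ab_c, c(a = 1, b = 1)), "no potential.*'c'")
})

test_that("resistance derives from reactant capacities and k = 10^x", {
  r1 <- reaction("r1", c(s = -1, p = 1), log10_k_plus = 0)
  expect_equal(resistance(r1, capacities = c(s = 1, p = 1)), 1)
  r2 <- reaction("r2", c(s = -1, p = 1), log10_k_plus = 3)
  expect_equal(resistance(r2, capacities = c(s = 0.1, p = 1)), 0.01)
  r3 <- reaction("r3", c(a = -1, b = -1, c = 1), log10_k_plus = 1)
  expect_equal(resistance(r3, capacities = c(a = 0.5, b = 2, c = 1)), 0.1)
  qe <- reaction("q", c(a = -1, b = 1), kind = "qe")
  expect_error(resistance(qe, capacities = c(a = 1)), "no finite resistance")
})

test_that("modifier terms act multiplicatively on the resistance", {
  act <- reaction("r", c(a = -1, b = 1), log10_k_plus = 0,
                  modifiers = list(list(metabolite = "m", type = "activator",
                                        theta = 1)))
  base <- resistance(reaction("r0", c(a = -1, b = 1)), capacities = c(a = 1))
  expect_equal(resistance(act, capacities = c(a = 1), xi = c(m = 1)), base / 2)
  inh <- reaction("ri", c(a = -1, b = 1), log10_k_plus = 0,
                  modifiers = list(list(metabolite = "m", type = "inhibitor",
                                        theta = 1)))
  expect_equal(resistance(inh, capacities = c(a = 1), xi = c(m = 3)), base * 4)
})

test_that("flux is c_E * F / R with the sign of the force", {
  rxn <- reaction("r", c(a = -1, b = 1), log10_k_plus = 0)
  caps <- c(a = 1, b = 1)
  expect_equal(flux(rxn, c(a = 1, b = 1), caps, c_E = 1), 0)
  expect_equal(flux(rxn, c(a = 2, b = 1), caps, c_E = 0), 0)
  expect_equal(flux(rxn, c(a = 3, b = 1), caps, c_E = 2), 4)
  expect_error(flux(rxn, c(a = 1, b = 1), caps, c_E = -1), "non-negative")
})

test_that("flux is linear in enzyme level and force at fixed resistance", {
  rxn <- reaction("r", c(a = -1, b = -1, c = 2), log10_k_plus = 2)
  caps <- c(a = 0.3, b = 1.7, c = 0.9)
  xi <- c(a = 1.2, b = 0.7, c = 0.4)
  J1 <- flux(rxn, xi, caps, c_E = 1)
  expect_equal(flux(rxn, xi, caps, c_E = 3.5), 3.5 * J1)
  # doubling the force (via a state with twice the force) doubles the flux
  FF <- force(rxn, xi)
  R <- resistance(rxn, caps)
  expect_equal(J1, FF / R)
})

test_that("flux and force never oppose each other (J*F >= 0)", {
  set.seed(42)
  rxns <- list(
    reaction("u", c(a = -1, b = 1), log10_k_plus = 1),
    reaction("v", c(a = -1, b = -1, c = 1), log10_k_plus = 0),
    reaction("w", c(a = -2, c = 1, d = 1), log10_k_plus = -1))
  caps <- c(a = 0.5, b = 2, c = 1.3, d = 0.1)
  for (i in 1:200) {
    xi <- stats::setNames(exp(stats::runif(4, -3, 3)), names(caps))
    for (rxn in rxns) {
      FF <- force(rxn, xi)
      J <- flux(rxn, xi, caps, c_E = 1)
      expect_gte(J * FF, 0)
      if (FF != 0) expect_gt(abs(J), 0)
    }
  }
})

test_that("equilibrium constants around stoichiometric cycles multiply to one", {
  # capacities derive from formation energies, so any null-space cycle of
  # the reaction network has a net equilibrium constant of exactly 1
  core <- build_fixture("core")
  sys <- assemble(core, k_in_o2 = 0)
  lnK <- vapply(core$reactions, function(r) {
    idx <- match(names(r$stoich), sys$met_ids)
    sum(r$stoich * (sys$lC_mm[idx] - log(1000)))
  }, numeric(1))
  S <- sys$S[, names(core$reactions)]
  N <- MASS::Null(t(S))        # cycles: S %*% n = 0
  expect_gt(ncol(N), 0)        # the fixture does contain cycles
  expect_lt(max(abs(t(N) %*% lnK)), 1e-9)
})
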