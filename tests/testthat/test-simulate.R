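test_that("quasi-equilibrium reduction builds constraints and pool fluxes", {
  txt <- c(
    "[context]", "T = 310.15",
    "[compartments]", "c: phi = 0",
    "[metabolites]",
    "a: dfg0 = 0", "b: dfg0 = 1", "cc: dfg0 = 2",
    "[reactions]", "q1: a = b", "q2: b = cc")
  doc <- parse_model(txt)
  sys <- assemble(doc)
  # two chained QE reactions: three species, two constraints, two QE fluxes
  expect_equal(length(sys$qe_ids), 2L)
  expect_equal(sum(grepl("^qe\\.", sys$row_names)), 2L)
  expect_equal(sys$n_x, 3L + 2L)
  # a model with no QE reactions is a pure ODE system
  toy <- build_fixture("toy")
  expect_equal(length(assemble(toy)$qe_ids), 0L)
})

test_that("chained QE pool equilibrates to capacity-weighted potentials", {
  # closed three-species pool a = b = c: unique steady state has equal
  # potentials; concentrations are then proportional to capacities.
  # Independent oracle: symbolic elimination. With total T0 = ca + cb + cc
  # and xi equal: c_i = C_i * xi, xi = T0 / (1000 * (Ca + Cb + Cc)).
  txt <- c(
    "[context]", "T = 310.15",
    "[compartments]", "c: phi = 0",
    "[metabolites]",
    "a: dfg0 = 0", "b: dfg0 = 1", "cc: dfg0 = 2",
    "[reactions]", "q1: a = b", "q2: b = cc",
    "[moieties]", "pool abc: members = a b cc, base = a, total = 3")
  doc <- parse_model(txt)
  sys <- assemble(doc)
  st <- solve_steady_state(sys)
  expect_true(st$converged)
  expect_equal(unname(st$xi[["a"]]), unname(st$xi[["b"]]), tolerance = 1e-9)
  expect_equal(unname(st$xi[["b"]]), unname(st$xi[["cc"]]), tolerance = 1e-9)
  RT <- doc$context$RT
  caps <- exp(-c(0, 1000, 2000) / RT)
  oracle <- 3 * caps / sum(caps)
  expect_equal(unname(st$c[c("a", "b", "cc")]), oracle, tolerance = 1e-8)
})

test_that("closed single reaction reaches detailed balance", {
  # A <-> B with equal capacities: steady state must have xi_A = xi_B and
  # hence equal concentrations
  txt <- c(
    "[context]", "T = 310.15",
    "[compartments]", "c: phi = 0",
    "[metabolites]", "a: dfg0 = 0", "b: dfg0 = 0",
    "[reactions]", "r: a <-> b | k = 3",
    "[moieties]", "pool ab: members = a b, base = a, total = 2")
  st <- solve_steady_state(assemble(parse_model(txt)))
  expect_true(st$converged)
  expect_equal(unname(st$c[["a"]]), unname(st$c[["b"]]), tolerance = 1e-9)
  expect_equal(unname(st$J[["r"]]), 0, tolerance = 1e-9)
})

test_that("thermokinetic steady state matches mass-action integration", {
  # independent oracle: the toy chain as reversible mass-action ODEs with
  # rate constants derived only from k+ = 10^x and equilibrium constants
  # from the formation energies; integrated to t -> infinity with deSolve
  toy <- build_fixture("toy")
  sys <- assemble(toy)
  st <- solve_steady_state(sys)
  expect_true(st$converged)
  expect_lt(st$residual_norm, 1e-9)

  RT <- toy$context$RT
  dfg <- stats::setNames(toy$metabolites$dfg0, toy$metabolites$id)
  Keq_mm <- function(st_) {
    # equilibrium constant in mmol/l units for signed stoichiometry st_
    exp(-sum(st_ * dfg[names(st_)]) / RT) * 1000^(sum(st_))
  }
  kf <- function(rxn) {
    # mass-action forward constant in mmol units: c_E k+ prod C_r^{|nu|}
    # equals 10^x * 1000^{-n_r} in mmol space with c = 1000 C xi
    r <- rxn$stoich[rxn$stoich < 0]
    10^rxn$log10_k_plus * 1000^(-sum(abs(r)))
  }
  env <- toy$chemostat
  rate <- function(rxn, c) {
    r <- abs(rxn$stoich[rxn$stoich < 0]); p <- rxn$stoich[rxn$stoich > 0]
    kf(rxn) * (prod(c[names(r)]^r) -
                 prod(c[names(p)]^p) / Keq_mm(rxn$stoich))
  }
  rhs <- function(t, y, parms) {
    c <- y
    J <- vapply(toy$reactions, rate, numeric(1), c = c)
    dc <- numeric(length(c)); names(dc) <- names(c)
    for (j in seq_along(toy$reactions)) {
      stj <- toy$reactions[[j]]$stoich
      dc[names(stj)] <- dc[names(stj)] + stj * J[j]
    }
    cX <- 1
    dc_out <- dc
    for (id in names(c)) {
      if (id == "glc_e") dc_out[id] <- dc[id] * cX + env$D * (env$c_in[["glc_e"]] - c[id])
      else if (id == "ac_e") dc_out[id] <- dc[id] * cX + env$D * (0 - c[id])
      else if (id == "co2") dc_out[id] <- dc[id] * cX - env$k_out[["co2"]] * c[id]
      else dc_out[id] <- dc[id] / env$v_cell
    }
    list(dc_out)
  }
  y0 <- c(glc_e = 10, g6p = 1, pyr = 1, ac_e = 0.001, co2 = 0.001,
          atp = 2, adp = 1)
  out <- deSolve::lsoda(y0, times = c(0, 2000, 4000), rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-12, maxsteps = 1e6)
  oracle <- out[nrow(out), -1]
  # integration has settled
  expect_lt(max(abs(out[2, -1] - oracle) / oracle), 1e-8)
  for (id in names(oracle))
    expect_equal(unname(st$c[[id]]), unname(oracle[[id]]), tolerance = 1e-6)
})

test_that("conserved moiety totals stay constant along trajectories", {
  toy <- build_fixture("toy")
  sys <- assemble(toy)
  x0 <- solve_steady_state(sys)$x
  # start well away from steady state
  x0 <- x0 + seq(-0.5, 0.5, length.out = length(x0))
  tr <- tk_integrate(sys, times = seq(0, 2, by = 0.25), x0 = x0,
                     mu_override = 0)
  total <- tr$atp + tr$adp
  expect_lt(max(abs(total - total[1]) / total[1]), 1e-8)
})

test_that("wash-out is reported as a distinct valid outcome", {
  # single-nutrient model with an analytically bounded growth rate:
  # b equilibrates at most to the feed level (K_eq = 1), so
  # mu_max = k_a * (k_b + nu * ln b_max) = ln(10) ~ 2.3 /h; D = 5 washes out
  txt <- c(
    "[context]", "T = 310.15",
    "[compartments]", "c: phi = 0", "e: phi = 0",
    "[metabolites]",
    "glc_e: dfg0 = 0, compartment = e, external",
    "b: dfg0 = 0, compartment = c",
    "[reactions]", "U: glc_e -> b | k = 3",
    "[biomass]", "k_a = 1", "k_b = 0", "k_lo = 1", "k_hi = 2",
    "m_max = 0", "nu.b = 1", "x_carbon = 0",
    "[chemostat]", "D = 5", "v_cell = 0.002", "c_in.glc_e = 10")
  doc <- parse_model(txt)
  st <- solve_steady_state(assemble(doc), maxit = 100)
  expect_true(st$washout)
  expect_equal(unname(st$c_X), 0)
  # extracellular medium at inflow composition
  expect_equal(unname(st$c[["glc_e"]]), 10, tolerance = 1e-6)
  # the same model sustains a dilution rate below mu_max
  doc$chemostat$D <- 0.5
  for (g in names(doc$genes)) doc$genes[[g]]$basal_rate <- 0.5
  st2 <- solve_steady_state(assemble(doc), maxit = 100)
  expect_true(st2$converged)
  expect_false(st2$washout)
  expect_gt(st2$c_X, 0)
})

test_that("zero-length sweep grids give empty tables", {
  toy <- build_fixture("toy")
  out <- sweep_states(toy, "D", numeric(0))
  expect_s3_class(out, "tk_sweep")
  expect_equal(nrow(out), 0)
})

test_that("sweeping dilution rate forward and backward agree (toy)", {
  toy <- build_fixture("toy")
  Ds <- seq(0.1, 0.5, by = 0.1)
  fwd <- sweep_states(toy, "D", Ds)
  bwd <- sweep_states(toy, "D", rev(Ds))
  expect_true(all(fwd$converged), all(bwd$converged))
  for (v in c("c.glc_e", "c.g6p", "c.pyr", "c.atp")) {
    a <- fwd[[v]]
    b <- rev(bwd[[v]])
    expect_lt(max(abs(a - b) / pmax(abs(a), 1e-12)), 1e-6)
  }
})
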