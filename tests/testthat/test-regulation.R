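test_that("Hill activity has the midpoint, bounds and monotonicity", {
  tf <- transcription_factor("t", "x", k_half = 2, hill_n = 2)
  expect_equal(tf_activity(2, tf), 0.5)
  expect_equal(tf_activity(4, tf), 0.8)
  inh <- transcription_factor("t2", "x", k_half = 2, hill_n = -2)
  expect_equal(tf_activity(2, inh), 0.5)
  expect_equal(tf_activity(4, inh), 0.2)

  xs <- exp(seq(log(0.01), log(100), length.out = 50))
  a_up <- tf_activity(xs, tf)
  a_dn <- tf_activity(xs, inh)
  expect_true(all(diff(a_up) > 0))
  expect_true(all(diff(a_dn) < 0))
  expect_true(all(a_up > 0 & a_up < 1))
  expect_error(tf_activity(0, tf), "positive")
})

test_that("activity midpoint is exact for extreme Hill exponents", {
  for (n in c(-8, -1, 0.5, 1, 4, 12)) {
    tf <- transcription_factor("t", "x", k_half = 0.37, hill_n = n)
    expect_equal(tf_activity(0.37, tf), 0.5)
  }
})

test_that("expression modifier spans [2^-k, 1]", {
  expect_equal(expression_modifier(3, 1), 1)
  expect_equal(expression_modifier(3, 0), 1 / 8)
  expect_equal(expression_modifier(2, 0.5), 0.625)
  expect_equal(expression_modifier(0, 0.3), 1) # strength 0: no regulation
  expect_error(expression_modifier(2, 1.2), "\\[0, 1\\]")
})

test_that("synthesis rate multiplies regulator modifiers", {
  g0 <- gene("g0", basal_rate = 2)
  expect_equal(synthesis_rate(g0, c()), 2)

  g1 <- gene("g1", basal_rate = 1, regulators = list(
    list(tf = "a", mode = "activator", strength = 1)))
  expect_equal(synthesis_rate(g1, c(a = 0)), 0.5)

  # two activators and one inhibitor at full activity: the inhibitor
  # contributes s(k, 1 - a) = 2^-3
  g3 <- gene("g3", basal_rate = 1, regulators = list(
    list(tf = "a", mode = "activator", strength = 2),
    list(tf = "b", mode = "activator", strength = 1),
    list(tf = "c", mode = "inhibitor", strength = 3)))
  act <- c(a = 1, b = 1, c = 1)
  expect_equal(synthesis_rate(g3, act), 1 / 8)
  expect_error(synthesis_rate(g3, c(a = 1, b = 1)), "unknown transcription factor")
})

test_that("synthesis rate is invariant to regulator ordering", {
  regs <- list(
    list(tf = "a", mode = "activator", strength = 2),
    list(tf = "b", mode = "inhibitor", strength = 1),
    list(tf = "c", mode = "activator", strength = 3))
  act <- c(a = 0.3, b = 0.71, c = 0.05)
  g_fwd <- gene("g", 1.7, regulators = regs)
  g_rev <- gene("g", 1.7, regulators = rev(regs))
  expect_equal(synthesis_rate(g_fwd, act), synthesis_rate(g_rev, act))
})

test_that("gene construction enforces integer strengths and positive rates", {
  expect_error(gene("g", basal_rate = 0), "positive")
  expect_error(gene("g", basal_rate = 1, regulators = list(
    list(tf = "a", mode = "activator", strength = 1.5))), "integer")
})

test_that("enzyme balance: synthesis minus dilution, steady state J_syn/mu", {
  expect_equal(enzyme_rhs(2, J_syn = 0.2, mu = 0.1), 0)
  expect_equal(enzyme_rhs(1, J_syn = 0, mu = 0.1), -0.1)
  expect_equal(enzyme_rhs(1, J_syn = 0.2, mu = 0.1), 0.1)
  # analytic steady state c_E = J_syn / mu for a regulated gene
  g <- gene("g", basal_rate = 0.4, regulators = list(
    list(tf = "a", mode = "activator", strength = 2)))
  J <- synthesis_rate(g, c(a = 0.6))
  D <- 0.25
  expect_equal(enzyme_rhs(J / D, J, D), 0)
})
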