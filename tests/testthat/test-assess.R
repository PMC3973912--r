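test_that("scaling factor equals the closed form on simple cases", {
  x <- c(1, 2, 3)
  expect_equal(scaling_factor(x, x), 1)
  expect_equal(scaling_factor(x, 2 * x), 0.5)
  expect_equal(scaling_factor(c(1, 2), c(2, 2)), 5 / 6)
  expect_warning(f <- scaling_factor(c(1, 0), c(0, 1)), "orthogonal")
  expect_true(is.na(f))
})

test_that("scaling factor is the argmin of the quadratic objective", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:12, 1)
    x_s <- stats::rlnorm(n)
    x_m <- stats::rlnorm(n)
    f <- scaling_factor(x_s, x_m)
    obj <- function(g) sum((x_s / g - x_m)^2)
    num <- stats::optimize(obj, c(1e-4, 1e4))$minimum
    expect_equal(f, num, tolerance = 1e-4)
    # stationarity of the objective at the analytic factor
    h <- 1e-6 * f
    expect_lt(abs(obj(f + h) - obj(f - h)) / (2 * h), 1e-6 * obj(f) + 1e-8)
  }
})

make_sweep_stub <- function() {
  # a small synthetic sweep table with known values
  tb <- tibble::tibble(
    aerobiosis = c(0, 50, 100),
    converged = TRUE, washout = FALSE,
    c.pyr = c(4, 2, 1), cE.pfl = c(1, 0.6, 0.2), J.ACKr = c(8, 4, 0.1),
    mu = 0.2, c_X = c(0.5, 0.8, 1.2))
  attr(tb, "param") <- "aerobiosis"
  class(tb) <- c("tk_sweep", class(tb))
  tb
}

test_that("overlay scales relative kinds and passes fluxes through", {
  sim <- make_sweep_stub()
  data <- tibble::tibble(
    variable_id = c("pyr", "pyr", "pyr", "pfl", "pfl", "ACKr", "ACKr"),
    aerobiosis = c(0, 50, 100, 0, 100, 0, 50),
    value = c(2, 1, 0.5, 10, 2, 8.5, 3.9),
    kind = c(rep("metabolite", 3), rep("transcript", 2), rep("flux", 2)))
  ov <- overlay(sim, data)
  rep <- ov$report
  # metabolite: x_m = x_s/2 exactly, so f = 2
  expect_equal(rep$f[rep$variable_id == "pyr"], 2)
  # flux: compared directly
  expect_equal(rep$f[rep$variable_id == "ACKr"], 1)
  expect_equal(nrow(ov$unmatched), 0)
  # scaled points carry f * x_m
  expect_equal(ov$points$scaled_value[ov$points$variable_id == "pyr"],
               c(4, 2, 1))
})

test_that("overlay reports unmatched grid points instead of dropping silently", {
  sim <- make_sweep_stub()
  data <- tibble::tibble(
    variable_id = c("pyr", "pyr", "nosuch"),
    aerobiosis = c(0, 77, 0),
    value = c(2, 1, 1),
    kind = c("metabolite", "metabolite", "metabolite"))
  expect_warning(ov <- overlay(sim, data), "excluded")
  expect_equal(nrow(ov$unmatched), 2)
  expect_equal(nrow(ov$points), 1)
})

test_that("empty grid intersection yields an empty report with a warning", {
  sim <- make_sweep_stub()
  data <- tibble::tibble(variable_id = "pyr", aerobiosis = 33, value = 1,
                         kind = "metabolite")
  expect_warning(ov <- overlay(sim, data), "excluded")
  expect_equal(nrow(ov$points), 0)
})

test_that("limiting precursor picks the largest drop and reports ties", {
  fake_curve <- function(rels) {
    tb <- tibble::tibble(J_prod = c(0, 1))
    for (n in names(rels)) tb[[paste0("rel.", n)]] <- c(1, rels[[n]])
    attr(tb, "drained") <- names(rels)
    class(tb) <- c("tk_production", class(tb))
    tb
  }
  lim <- limiting_precursor(fake_curve(list(a = 1, b = 0.1)))
  expect_equal(lim$species, "b")
  expect_false(lim$tie)
  lim2 <- limiting_precursor(fake_curve(list(a = 0.4, b = 0.4)))
  expect_true(lim2$tie)
  expect_setequal(lim2$species, c("a", "b"))
})
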