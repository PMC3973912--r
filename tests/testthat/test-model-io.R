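test_that("stoichiometry grammar parses coefficients and arrows", {
  st <- parse_stoich("a + 2 b -> c")
  expect_equal(st$stoich[c("a", "b", "c")], c(a = -1, b = -2, c = 1))
  expect_equal(st$arrow, "->")
  expect_equal(parse_stoich("g6p = f6p")$arrow, "=")
  expect_equal(parse_stoich("a <-> b")$arrow, "<->")
  # species on both sides are merged
  st2 <- parse_stoich("a + b -> a + c")
  expect_false("a" %in% names(st2$stoich))
  expect_error(parse_stoich("a + -> b"), "malformed")
  expect_error(parse_stoich("a b c"), "arrow")
  # non-integer coefficients only where allowed
  expect_error(parse_stoich("0.5 a -> b"), "non-integer")
  expect_silent(parse_stoich("0.5 a -> b", allow_noninteger = TRUE))
})

test_that("a minimal document parses", {
  doc <- parse_model(c(
    "[context]", "T = 298.15",
    "[compartments]", "c: phi = 0",
    "[metabolites]", "a: dfg0 = -10, z = 0, compartment = c"))
  expect_s3_class(doc, "tkm_model")
  expect_equal(nrow(doc$metabolites), 1L)
  expect_equal(doc$metabolites$dfg0, -10e3)  # file kJ/mol -> J/mol
  expect_equal(doc$context$T, 298.15)
})

test_that("integer-only parameters are enforced at parse time", {
  base <- c(
    "[context]", "T = 310.15",
    "[compartments]", "c: phi = 0",
    "[metabolites]", "a: dfg0 = 0", "b: dfg0 = 0",
    "[transcription_factors]", 'tf1: signal = "a", k_half = 1, n = 2')
  # fractional gene regulation strength
  expect_error(parse_model(c(base, "[genes]", "g: basal = 1, reg = tf1 +1.5")),
               "integer")
  # fractional log10 rate constant
  expect_error(parse_model(c(base, "[reactions]", "r: a -> b | k = 2.5")),
               "integer")
  expect_silent(parse_model(c(base, "[genes]", "g: basal = 1, reg = tf1 +2",
                              "[reactions]", "r: a -> b | k = 3")))
})

test_that("parse errors carry line numbers", {
  expect_error(parse_model(c("[context]", "T = 310", "[reactions]",
                             "r: nonsense")),
               "line 4")
  expect_error(parse_model(c("[bogus_section]")), "unknown section")
})

test_that("cross-reference validation catches unknown ids", {
  base <- c("[context]", "T = 310.15", "[compartments]", "c: phi = 0",
            "[metabolites]", "a: dfg0 = 0")
  expect_error(parse_model(c(base, "[reactions]", "r: a -> zz | k = 0")),
               "unknown metabolite 'zz'")
  expect_error(parse_model(c(base, "[reactions]",
                             "r: a -> a | k = 0")), "zero|duplicate|empty")
  expect_error(parse_model(c(
    base, "[transcription_factors]",
    'tf: signal = "a / qq", k_half = 1, n = 1')), "unknown")
})

test_that("structurally dependent quasi-equilibrium sets are rejected", {
  bad <- c(
    "[context]", "T = 310.15", "[compartments]", "c: phi = 0",
    "[metabolites]", "a: dfg0 = 0", "b: dfg0 = 0",
    "[reactions]", "q1: a = b", "q2: a = b")
  expect_error(parse_model(bad), "structurally dependent")
  # a chain a = b = c is fine
  ok <- c(
    "[context]", "T = 310.15", "[compartments]", "c: phi = 0",
    "[metabolites]", "a: dfg0 = 0", "b: dfg0 = 0", "cc: dfg0 = 0",
    "[reactions]", "q1: a = b", "q2: b = cc")
  expect_silent(parse_model(ok))
})

test_that("serialize/parse round trips the packaged fixtures", {
  for (scale in c("toy", "core")) {
    doc <- build_fixture(scale)
    txt <- serialize_model(doc)
    doc2 <- parse_model(txt)
    expect_equal(doc2$metabolites, doc$metabolites)
    expect_equal(doc2$reactions, doc$reactions)
    expect_equal(doc2$genes, doc$genes)
    expect_equal(doc2$tfs, doc$tfs)
    expect_equal(doc2$moieties, doc$moieties)
    expect_equal(doc2$biomass, doc$biomass)
    expect_equal(doc2$chemostat, doc$chemostat)
    expect_equal(doc2$header, doc$header)
    # serialization is deterministic
    expect_identical(txt, serialize_model(doc2))
  }
})

test_that("write_tkm/read_tkm round trips through a file", {
  doc <- build_fixture("toy")
  path <- withr::local_tempfile(fileext = ".tkm")
  write_tkm(doc, path)
  expect_equal(read_tkm(path)$reactions, doc$reactions)
})

test_that("shipped model files agree with the generator", {
  for (pair in list(c("ecoli_core.tkm", "core"), c("toy_chain.tkm", "toy"))) {
    path <- system.file("extdata", pair[1], package = "thermokin")
    expect_true(nzchar(path))
    expect_identical(serialize_model(read_tkm(path)),
                     serialize_model(build_fixture(pair[2])))
  }
})

test_that("overlay works on the shipped synthetic measurement table", {
  path <- system.file("extdata", "synthetic_measurements.tsv",
                      package = "thermokin")
  expect_true(nzchar(path))
  data <- utils::read.delim(path)
  expect_setequal(unique(data$kind), c("metabolite", "transcript", "flux"))
  expect_true(all(data$value > 0))
})

test_that("fixture generation is reproducible", {
  expect_identical(serialize_model(build_fixture("core")),
                   serialize_model(build_fixture("core")))
  toy <- build_fixture("toy")
  expect_equal(length(toy$reactions), 4L)
  expect_true(all(c("glc_e", "g6p", "pyr", "ac_e") %in% toy$metabolites$id))
})

test_that("core fixture variants honour the flags", {
  core <- build_fixture("core")
  noreg <- build_fixture("core", include_regulation = FALSE)
  expect_length(noreg$tfs, 0)
  expect_true(all(vapply(noreg$genes, function(g) length(g$regulators),
                         integer(1)) == 0))
  noetc <- build_fixture("core", include_etc = FALSE)
  expect_false("q8" %in% noetc$metabolites$id)
  expect_false("CYTBO3" %in% names(noetc$reactions))
  expect_true("PFL" %in% names(noetc$reactions))
  # both variants still validate
  expect_silent(validate_model(noreg))
  expect_silent(validate_model(noetc))
  # the full core keeps the differential quinone use of the two TCA modes
  expect_setequal(names(core$reactions$SUCDH$stoich[core$reactions$SUCDH$stoich < 0]),
                  c("succ", "q8"))
  expect_true("mql8" %in% names(core$reactions$FRD$stoich))
})

test_that("drain reactions are parsed and clamped to their flux", {
  core <- build_fixture("core")
  # zero drain leaves the model unchanged in effect
  d0 <- add_drain_reaction(core, "accoa -> coa", J_prod = 0)
  expect_equal(d0$drains$PROD$J_fixed, 0)
  # butanol-pathway stoichiometry
  d1 <- add_drain_reaction(core, "2 accoa + 4 nadh -> 2 coa + 4 nad",
                           J_prod = 1.5)
  expect_equal(d1$drains$PROD$stoich[c("accoa", "nadh", "coa", "nad")],
               c(accoa = -2, nadh = -4, coa = 2, nad = 4))
  expect_equal(d1$drains$PROD$J_fixed, 1.5)
  # ethanol pathway via pyruvate and ubiquinol
  d2 <- add_drain_reaction(core, "pyr + q8h2 -> q8", J_prod = 0.5)
  expect_equal(sort(names(d2$drains$PROD$stoich)), c("pyr", "q8", "q8h2"))
  expect_error(add_drain_reaction(core, "unobtainium ->", 1), "unknown")
  expect_error(add_drain_reaction(core, "accoa -> coa", -1), "non-negative")
})
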