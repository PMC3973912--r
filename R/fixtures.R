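## Packaged model fixtures.
##
## The core model covers glucose uptake (PTS), glycolysis, the fermentation
## branches (PFL, PTAr/ACKr, ADHEr), the branched/cyclic citric acid cycle
## with the menaquinone-using fumarate reductase (FRD) versus the
## ubiquinone-using succinate dehydrogenase (SUCDH), anaplerosis (PPC), the
## electron transport chain (proton-pumping and non-pumping NADH
## dehydrogenases, the bo and bd oxidases, ATP synthase) and a lumped
## proton-motive species, together with FNR/ArcA/CRP/FruR regulation,
## biomass formation, maintenance and a glucose-limited chemostat.
##
## The transformed formation energies are synthetic stand-ins on the scale
## of Alberty-style tables: they are assigned so that every reaction's
## standard transformed Gibbs energy matches a literature-typical value
## (a spanning-tree construction; one loop closure fixes the CO2 anchor).
## Because they are per-species formation energies, Wegscheider consistency
## of all equilibrium constants holds by construction.

# transformed formation energies, kJ/mol (synthetic, see above)
core_dfg0 <- c(
  glc_e = 0, g6p = 10.5, f6p = 13, fdp = 27.5, dhap = 22, g3p = 27.5,
  pg3 = -74.8, pep = -73.8, pyr = -132.3,
  accoa = -69.6, coa = 0, actp = -49.6,
  cit = -366, icit = -357.5, akg = -265.8, succoa = -197.6,
  succ = -230.1, fum = -224.1, mal = -227.5, oaa = -261.3,
  atp = 30.5, adp = 0, amp = -30.5,
  nad = 0, nadh = 61.8, nadp = 0, nadph = 60.8,
  q8 = 0, q8h2 = -19.3, mqn8 = 0, mql8 = 14.3,
  o2 = 316.6, co2 = -157.5,
  ac_e = -104.1, etoh_e = 29, for_e = -78.7, succ_e = -230.1,
  h_c = 0, pmf = 0)

core_carbon <- c(
  glc_e = 6, g6p = 6, f6p = 6, fdp = 6, dhap = 3, g3p = 3, pg3 = 3, pep = 3,
  pyr = 3, accoa = 2, actp = 2, cit = 6, icit = 6, akg = 5, succoa = 4,
  succ = 4, fum = 4, mal = 4, oaa = 4, co2 = 1, ac_e = 2, etoh_e = 2,
  for_e = 1, succ_e = 4)

# integer log10 forward rate constants (calibrated by hand against the
# anaerobic/aerobic operating regimes; only orders of magnitude matter)
core_log10k <- c(
  GLCpts = 9, GAPD = 12, PFK = 7, PYK = 8, PDH = 10, PFL = 7, ACKr = 8, ADHEr = 10,
  ACS = 9,
  CS = 10, ICDHyr = 10, AKGDH = 10, SUCOAS = 8, SUCDH = 7, FRD = 7, MDH = 5,
  PPC = 8, THD = 8, NADHIq8 = 9, NADHImq = 7, NADHII = 8,
  CYTBO3 = 15, CYTBD = 15, ATPS = -2, LEAK = -2, SUCCt = 4)

core_reactions <- c(
  "PGI: g6p = f6p",
  "FBA: fdp = dhap + g3p",
  "TPI: dhap = g3p",
  "ENO: pg3 = pep",
  "ACONT: cit = icit",
  "FUM: fum = mal",
  "ADK: atp + amp = 2 adp",
  "PTAr: accoa = actp + coa",
  "GLCpts: glc_e + pep -> g6p + pyr | k = %GLCpts%, enzyme = pts",
  "GAPD: g3p + nad + adp -> pg3 + nadh + atp | k = %GAPD%, enzyme = gapa",
  "PFK: f6p + atp -> fdp + adp | k = %PFK%, enzyme = pfk, activator = adp @ 0.0005",
  "PYK: pep + adp -> pyr + atp | k = %PYK%, enzyme = pyk",
  "PDH: pyr + coa + nad -> accoa + co2 + nadh | k = %PDH%, enzyme = pdh",
  "PFL: pyr + coa -> accoa + for_e | k = %PFL%, enzyme = pfl",
  "ACKr: actp + adp -> ac_e + atp | k = %ACKr%, enzyme = ack",
  "ADHEr: accoa + 2 nadh -> etoh_e + coa + 2 nad | k = %ADHEr%, enzyme = adhe",
  "ACS: ac_e + atp + coa -> accoa + amp | k = %ACS%, enzyme = acs",
  "CS: accoa + oaa -> cit + coa | k = %CS%, enzyme = cs",
  "ICDHyr: icit + nadp -> akg + co2 + nadph | k = %ICDHyr%, enzyme = icd",
  "AKGDH: akg + coa + nad -> succoa + co2 + nadh | k = %AKGDH%, enzyme = suca",
  "SUCOAS: succoa + adp -> succ + coa + atp | k = %SUCOAS%, enzyme = sucoas",
  "SUCDH: succ + q8 -> fum + q8h2 | k = %SUCDH%, enzyme = sdh",
  "FRD: fum + mql8 -> succ + mqn8 | k = %FRD%, enzyme = frd",
  "MDH: mal + nad -> oaa + nadh | k = %MDH%, enzyme = mdh",
  "PPC: pep + co2 -> oaa | k = %PPC%, enzyme = ppc",
  "THD: nadh + nadp -> nad + nadph | k = %THD%, enzyme = thd",
  "NADHIq8: nadh + q8 + 4 h_c -> nad + q8h2 + 4 pmf | k = %NADHIq8%, enzyme = nuo",
  "NADHImq: nadh + mqn8 + 2 h_c -> nad + mql8 + 2 pmf | k = %NADHImq%, enzyme = nuo",
  "NADHII: nadh + q8 -> nad + q8h2 | k = %NADHII%, enzyme = ndh",
  "CYTBO3: 2 q8h2 + o2 + 8 h_c -> 2 q8 + 8 pmf | k = %CYTBO3%, enzyme = cyo",
  "CYTBD: 2 q8h2 + o2 + 4 h_c -> 2 q8 + 4 pmf | k = %CYTBD%, enzyme = cyd",
  "ATPS: adp + 4 pmf -> atp + 4 h_c | k = %ATPS%, enzyme = atps",
  "LEAK: pmf -> h_c | k = %LEAK%",
  "SUCCt: succ -> succ_e | k = %SUCCt%")

core_tfs <- c(
  'fnr: signal = "o2", k_half = 0.003, n = -1.5',
  'arca: signal = "(q8h2 / (q8 + q8h2) + mql8 / (mqn8 + mql8)) / 2", k_half = 0.55, n = 3',
  'crp: signal = "pep / pyr", k_half = 0.3, n = 2',
  'frur: signal = "fdp", k_half = 2, n = -2')

core_genes <- c(
  "pts: basal = %D%",
  "gapa: basal = %D%",
  "pfk: basal = %D%",
  "pyk: basal = %D%, reg = frur -1",
  "pdh: basal = %D%, reg = arca -3",
  "pfl: basal = %D%, reg = fnr +1; arca +1",
  "ack: basal = %D%",
  "acs: basal = %D%, reg = crp +2",
  "adhe: basal = %D%, reg = fnr +1; arca +1",
  "cs: basal = %D%, reg = arca -1",
  "icd: basal = %D%, reg = arca -1",
  "suca: basal = %D%, reg = arca -1; fnr -2",
  "sucoas: basal = %D%",
  "sdh: basal = %D%, reg = arca -1; fnr -2; crp +1",
  "frd: basal = %D%, reg = fnr +2",
  "mdh: basal = %D%, reg = arca -1",
  "ppc: basal = %D%",
  "thd: basal = %D%",
  "nuo: basal = %D%, reg = arca -1; fnr -1",
  "ndh: basal = %D%, reg = fnr -1",
  "cyo: basal = %D%, reg = arca -2; fnr -1",
  "cyd: basal = %D%, reg = arca +2; fnr -1",
  "atps: basal = %D%")

# biomass precursor demands, mmol per gDCW (pentose-phosphate demands folded
# into the hexose entry for the core network)
core_nu <- c(g6p = 1.46, g3p = 0.13, pg3 = 1.5, pep = 0.52, pyr = 2.83,
             accoa = 3.75, akg = 1.08, oaa = 1.79,
             atp = 41.3, nadph = 18.2, nad = 3.5)

#' Build a packaged model fixture
#'
#' Deterministically constructs one of the packaged models:
#' \describe{
#'   \item{`toy`}{a four-reaction linear chain (glucose -> glucose
#'     6-phosphate -> pyruvate -> acetate) with explicit ATP stoichiometry,
#'     a conserved adenylate pool and a chemostat environment; used for
#'     solver oracles and conservation tests.}
#'   \item{`core`}{the central carbon and energy metabolism model described
#'     in the file header: glycolysis, fermentation branches, branched/cyclic
#'     citric acid cycle, electron transport chain with two quinone pools,
#'     FNR/ArcA/CRP/FruR regulation, biomass, maintenance and chemostat.}
#' }
#'
#' @param scale `"toy"` or `"core"`.
#' @param include_regulation include transcription factors and gene
#'   regulation (core only); without it all genes are constitutive.
#' @param include_etc include the electron transport chain, quinone pools
#'   and oxygen exchange (core only); without it the model is
#'   fermentation-only.
#' @param D dilution rate (1/h); unregulated basal synthesis rates equal D
#'   so that unregulated enzyme levels are 1.
#' @return A validated `tkm_model`.
#' @examples
#' toy <- build_fixture("toy")
#' toy
#' @export
build_fixture <- function(scale = c("core", "toy"), include_regulation = TRUE,
                          include_etc = TRUE, D = 0.2) {
  scale <- match.arg(scale)
  if (scale == "toy") return(parse_model(toy_text(D)))
  parse_model(core_text(include_regulation, include_etc, D))
}

toy_text <- function(D = 0.2) {
  c("# toy thermokinetic model: linear chain glc -> g6p -> pyr -> ac",
    "# with explicit ATP stoichiometry and a conserved adenylate pool",
    "",
    "[context]", "T = 310.15", "pH = 7", "I = 0.25", "c_ref = 1",
    "",
    "[compartments]", "c: phi = 0", "e: phi = 0",
    "",
    "[metabolites]",
    "glc_e: dfg0 = 0, z = 0, compartment = e, carbon = 6, external",
    "g6p: dfg0 = 13.5, z = 0, compartment = c, carbon = 6",
    "pyr: dfg0 = -79, z = 0, compartment = c, carbon = 3",
    "ac_e: dfg0 = 13, z = 0, compartment = e, carbon = 2, external",
    "co2: dfg0 = -157.5, z = 0, compartment = e, carbon = 1, external, gas",
    "atp: dfg0 = 30.5, z = 0, compartment = c",
    "adp: dfg0 = 0, z = 0, compartment = c",
    "",
    "[reactions]",
    "HEX: glc_e + atp -> g6p + adp | k = 6",
    "GLY: g6p + 3 adp -> 2 pyr + 3 atp | k = 13",
    "ACK: pyr + adp -> ac_e + co2 + atp | k = 6",
    "ATPASE: atp -> adp | k = 4",
    "",
    "[moieties]",
    "pool adenylate: members = atp adp, base = adp, total = 3",
    "",
    "[chemostat]",
    paste0("D = ", D),
    "v_cell = 0.002",
    "c_in.glc_e = 10",
    "k_out.co2 = 60",
    "",
    "[start]",
    "# chemostat operating point (solver starting point)",
    "glc_e = 2.5", "g6p = 0.0109", "pyr = 1.25", "ac_e = 15",
    "co2 = 0.05", "atp = 0.6", "adp = 2.4")
}

core_text <- function(include_regulation = TRUE, include_etc = TRUE,
                      D = 0.2) {
  etc_rxn <- c("SUCDH", "FRD", "NADHIq8", "NADHImq", "NADHII", "CYTBO3",
               "CYTBD", "ATPS", "LEAK")
  etc_met <- c("q8", "q8h2", "mqn8", "mql8", "o2", "pmf", "h_c")
  mets <- names(core_dfg0)
  rxn_lines <- core_reactions
  for (n in names(core_log10k))
    rxn_lines <- sub(paste0("%", n, "%"), core_log10k[[n]], rxn_lines,
                     fixed = TRUE)
  gene_lines <- sub("%D%", format(D), core_genes, fixed = TRUE)
  if (!include_regulation)
    gene_lines <- sub(",\\s*reg = .*$", "", gene_lines)
  if (!include_etc) {
    mets <- setdiff(mets, etc_met)
    keep <- !grepl(paste0("^(", paste(etc_rxn, collapse = "|"), "):"),
                   rxn_lines)
    rxn_lines <- rxn_lines[keep]
    gene_lines <- gene_lines[!grepl("^(sdh|frd|nuo|ndh|cyo|cyd|atps):",
                                    gene_lines)]
  }
  met_lines <- vapply(mets, function(m) {
    comp <- if (m %in% c("glc_e", "ac_e", "etoh_e", "for_e", "succ_e", "o2",
                         "co2", "pmf")) "e" else "c"
    flags <- ""
    if (m %in% c("glc_e", "ac_e", "etoh_e", "for_e", "succ_e")) flags <- ", external"
    if (m %in% c("o2", "co2")) flags <- ", external, gas"
    if (m == "h_c") flags <- ", clamped"
    cb <- if (m %in% names(core_carbon))
      paste0(", carbon = ", core_carbon[[m]]) else ""
    sprintf("%s: dfg0 = %s, z = 0, compartment = %s%s%s",
            m, format(core_dfg0[[m]]), comp, cb, flags)
  }, character(1))
  tfs <- core_tfs
  if (!include_etc) {
    # FNR and ArcA sense oxygen / quinones, which this variant lacks
    tfs <- tfs[!grepl("^(fnr|arca):", tfs)]
    gene_lines <- gsub("(fnr|arca) [+-][0-9]+(; )?", "", gene_lines)
    gene_lines <- gsub(";\\s*$", "", gene_lines)
    gene_lines <- gsub(",\\s*reg =\\s*$", "", gene_lines)
  }
  tf_lines <- if (include_regulation) c("[transcription_factors]", tfs, "")
    else character(0)
  moiety_lines <- c(
    "[moieties]",
    "pool adenylate: members = atp adp amp, base = amp, total = 5",
    "pool nicotinamide: members = nad nadh, base = nad, total = 2",
    "pool nicotinamide_p: members = nadp nadph, base = nadp, total = 0.25",
    "pool coenzyme_a: members = coa accoa succoa, base = coa, total = 1.5",
    if (include_etc) c(
      "quinone ubiquinone: members = q8 q8h2, base = q8, intercept = 0.15, slope = 0.0035",
      "quinone menaquinone: members = mqn8 mql8, base = mqn8, intercept = 0.6, slope = -0.004",
      "dead_pool_ox = 0.2"))
  chem_lines <- c(
    "[chemostat]",
    paste0("D = ", format(D)),
    "v_cell = 0.002",
    "c_in.glc_e = 20",
    "k_out.co2 = 20",
    if (include_etc) c("k_out.o2 = 60", "o2_id = o2"))
  start_lines <- if (include_etc && include_regulation) c(
    "[start]",
    "# anaerobic chemostat operating point (solver starting point)",
    "glc_e = 0.05526", "g6p = 0.3778", "f6p = 0.1433", "fdp = 2.221",
    "dhap = 1.923", "g3p = 0.2278", "pg3 = 0.3663", "pep = 0.2486",
    "pyr = 3.044", "accoa = 0.7254", "coa = 0.766", "actp = 0.4056",
    "cit = 0.03499", "icit = 0.001296", "akg = 0.4892", "succoa = 0.00865",
    "succ = 1.301", "fum = 0.1113", "mal = 0.4159", "oaa = 0.000122",
    "atp = 4.333", "adp = 0.587", "amp = 0.07952", "nad = 0.5556",
    "nadh = 1.444", "nadp = 0.06885", "nadph = 0.1812", "q8 = 2.719e-07",
    "q8h2 = 0.15", "mqn8 = 0.1235", "mql8 = 0.4765", "o2 = 1.415e-16",
    "co2 = 0.05685", "ac_e = 13.77", "etoh_e = 19.92", "for_e = 30.1",
    "succ_e = 1.217", "pmf = 27550", "c_X = 0.2904", "")
  else character(0)
  c("# core thermokinetic model of E. coli central carbon and energy",
    "# metabolism across the aerobiosis scale (packaged fixture)",
    "",
    "[context]", "T = 310.15", "pH = 7", "I = 0.25", "c_ref = 1",
    "",
    "[compartments]", "c: phi = -0.15", "e: phi = 0",
    "",
    "[metabolites]", met_lines, "",
    "[reactions]", rxn_lines, "",
    tf_lines,
    "[genes]", gene_lines, "",
    "[biomass]",
    "x_carbon = 40",
    "k_a = 0.05", "k_b = 22.8", "k_lo = 1", "k_hi = 2.5",
    "m_max = 45", "m_lo = 1", "m_hi = 30",
    vapply(names(core_nu), function(n)
      sprintf("nu.%s = %s", n, format(core_nu[[n]])), character(1)), "",
    moiety_lines, "",
    chem_lines, "",
    start_lines)
}
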