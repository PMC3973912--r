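#' Ramp function with saturation
#'
#' Piecewise-linear ramp used by the growth and maintenance kinetics: 0 below
#' `lo`, rising linearly to 1 at `hi`, constant above. An optional C1
#' smoothing of width `eps` (in ratio units) replaces the two kinks by
#' quadratic blends; smoothing is off by default so that unit values are
#' exactly piecewise linear, and may be switched on for continuation.
#'
#' @param x ratio value(s).
#' @param lo,hi thresholds, 0 < lo < hi.
#' @param eps smoothing half-width (0 = exact piecewise-linear ramp).
#' @return Value(s) in `[0, 1]`.
#' @export
ramp <- function(x, lo, hi, eps = 0) {
  stopifnot(lo < hi)
  y <- (x - lo) / (hi - lo)
  y <- pmin(1, pmax(0, y))
  if (eps > 0) {
    w <- eps / (hi - lo)
    # quadratic blend over [-w, w] around each kink of the unit ramp
    t <- (x - lo) / (hi - lo)
    y <- ifelse(abs(t) < w, (t + w)^2 / (4 * w), y)
    t2 <- t - 1
    y <- ifelse(abs(t2) < w, 1 - (w - t2)^2 / (4 * w), y)
    y <- pmin(1, pmax(0, y))
  }
  y
}

#' Biomass stoichiometry
#'
#' Stoichiometric demand of precursors (mmol per gDCW) for the formation of
#' one gram of dry cell mass, together with the released byproducts. The
#' byproducts tied to cofactor turnover are derived from the demands: CoA
#' release equals the acetyl-CoA plus succinyl-CoA demand, ADP release equals
#' the ATP demand, NADH release equals the NAD demand and NADP release equals
#' the NADPH demand. Any carbon not retained in biomass (parameter
#' `x_carbon`, mmol C per gDCW) is released as CO2.
#'
#' @param nu named numeric vector of precursor demands (mmol/gDCW, >= 0).
#' @param x_carbon biomass carbon content in mmol C per gDCW.
#' @param carbon named integer vector of carbon atoms per precursor molecule
#'   (used to derive the CO2 byproduct; cofactor moieties count as 0).
#' @return Object of class `tk_biomass` with elements `nu` (demands) and
#'   `byproducts` (releases), both named numeric vectors.
#' @export
biomass_stoichiometry <- function(nu, x_carbon = 40, carbon = NULL) {
  stopifnot(all(nu >= 0), !is.null(names(nu)))
  by <- c()
  g <- function(n) if (n %in% names(nu)) nu[[n]] else 0
  coa_rel <- g("accoa") + g("succoa")
  if (coa_rel > 0) by["coa"] <- coa_rel
  if (g("atp") > 0) by["adp"] <- g("atp")
  if (g("nad") > 0) by["nadh"] <- g("nad")
  if (g("nadph") > 0) by["nadp"] <- g("nadph")
  if (!is.null(carbon)) {
    cin <- sum(vapply(names(nu), function(n)
      nu[[n]] * (if (n %in% names(carbon)) carbon[[n]] else 0), numeric(1)))
    co2 <- cin - x_carbon
    if (co2 < -1e-9)
      stop("biomass carbon content exceeds carbon supplied by precursors",
           call. = FALSE)
    if (co2 > 1e-12) by["co2"] <- co2
  }
  structure(list(nu = nu, byproducts = by, x_carbon = x_carbon),
            class = "tk_biomass")
}

#' Growth parameters
#'
#' @param k_a rate scale (1/h).
#' @param k_b linlog offset (dimensionless).
#' @param k_lo,k_hi ATP/ADP ratio thresholds of the growth ramp
#'   (0 < k_lo < k_hi).
#' @return Object of class `tk_growth_params`.
#' @export
growth_params <- function(k_a, k_b, k_lo, k_hi) {
  if (!(k_lo > 0 && k_lo < k_hi))
    stop("growth thresholds must satisfy 0 < k_lo < k_hi", call. = FALSE)
  structure(list(k_a = k_a, k_b = k_b, k_lo = k_lo, k_hi = k_hi),
            class = "tk_growth_params")
}

#' Specific growth rate
#'
#' Linlog kinetics over the biomass reactants gated by an ATP/ADP ramp:
#' mu = ramp(ratio) * max(0, k_a * (k_b + sum nu_i * log(c_i))). The ramp is
#' 0 below `k_lo` (no growth below the adenylate energy-charge threshold),
#' linear on `[k_lo, k_hi]` and saturates at 1 above `k_hi`.
#'
#' @param c named concentrations of the biomass precursors (mmol/l, > 0).
#' @param ratio ATP/ADP concentration ratio.
#' @param bp a [biomass_stoichiometry()] (its `nu` weights the log terms;
#'   the cofactor demands atp/nad/nadph do not enter the linlog sum).
#' @param gp a [growth_params()].
#' @param eps ramp smoothing width (see [ramp()]).
#' @return Specific growth rate in 1/h (non-negative).
#' @export
growth_rate <- function(c, ratio, bp, gp, eps = 0) {
  nu <- bp$nu[setdiff(names(bp$nu), c("atp", "nad", "nadph"))]
  cc <- c[names(nu)]
  if (any(is.na(cc)) || any(cc <= 0))
    stop("all biomass reactant concentrations must be positive", call. = FALSE)
  lin <- gp$k_a * (gp$k_b + sum(nu * log(cc)))
  ramp(ratio, gp$k_lo, gp$k_hi, eps) * max(0, lin)
}

#' Maintenance ATP hydrolysis rate
#'
#' Non-growth-associated ATP -> ADP hydrolysis, following its own ramp with
#' saturation in the ATP/ADP ratio: 0 below `m_lo`, rising linearly to the
#' maximal rate `m_max` at `m_hi`.
#'
#' @param ratio ATP/ADP ratio (>= 0).
#' @param m_max maximal maintenance rate (mmol ATP/gDCW/h).
#' @param m_lo,m_hi ramp thresholds.
#' @param eps ramp smoothing width.
#' @return Maintenance rate (mmol ATP/gDCW/h).
#' @export
maintenance_rate <- function(ratio, m_max, m_lo, m_hi, eps = 0) {
  if (any(ratio < 0)) stop("ATP/ADP ratio must be non-negative", call. = FALSE)
  m_max * ramp(ratio, m_lo, m_hi, eps)
}

#' Chemostat environment
#'
#' @param D dilution rate (1/h, positive).
#' @param c_in named inflow concentrations of dissolved extracellular
#'   metabolites (mmol/l).
#' @param k_in named supply rates of gas species (mmol/l/h).
#' @param k_out named outgassing constants of gas species (1/h, positive).
#' @param v_cell specific cytoplasmic volume (l/gDCW) coupling
#'   biomass-specific fluxes to intracellular concentration changes.
#' @return Object of class `tk_chemostat`.
#' @export
chemostat_env <- function(D, c_in = c(), k_in = c(), k_out = c(),
                          v_cell = 0.002) {
  if (D <= 0) stop("dilution rate must be positive", call. = FALSE)
  if (length(k_out) > 0 && any(k_out <= 0))
    stop("outgassing constants must be positive", call. = FALSE)
  structure(list(D = D, c_in = c_in, k_in = k_in, k_out = k_out,
                 v_cell = v_cell),
            class = "tk_chemostat")
}

#' Chemostat balance right-hand sides
#'
#' Biomass: dc_X/dt = (mu - D) c_X. Dissolved species:
#' dc_i/dt = J_i c_X + D (c_in,i - c_i). Gas species (exchanged via the gas
#' phase, not the liquid feed): dc_i/dt = J_i c_X + k_in,i - k_out,i c_i.
#'
#' @param c_X biomass concentration (g/l).
#' @param c named extracellular concentrations (mmol/l).
#' @param J named biomass-specific net production rates (mmol/gDCW/h;
#'   negative = consumption).
#' @param mu specific growth rate (1/h).
#' @param env a [chemostat_env()].
#' @param gas character vector of species exchanged via the gas phase.
#' @return List with `dc_X` (g/l/h) and `dc` (named, mmol/l/h).
#' @export
chemostat_rhs <- function(c_X, c, J, mu, env, gas = character()) {
  dc <- numeric(length(c)); names(dc) <- names(c)
  for (i in names(c)) {
    Ji <- if (i %in% names(J)) J[[i]] else 0
    if (i %in% gas) {
      kin <- if (i %in% names(env$k_in)) env$k_in[[i]] else 0
      kout <- if (i %in% names(env$k_out)) env$k_out[[i]] else
        stop("gas species '", i, "' has no outgassing constant", call. = FALSE)
      dc[i] <- Ji * c_X + kin - kout * c[[i]]
    } else {
      cin <- if (i %in% names(env$c_in)) env$c_in[[i]] else 0
      dc[i] <- Ji * c_X + env$D * (cin - c[[i]])
    }
  }
  list(dc_X = (mu - env$D) * c_X, dc = dc)
}

#' Moiety policy: conserved pools and aerobiosis-dependent quinone pools
#'
#' Conserved moieties (adenylates, NAD(H), NADP(H), CoA thioesters) keep a
#' constant total concentration despite dilution by growth; de novo synthesis
#' into the pool's base member balances the dilution. Quinone pool totals are
#' affine in aerobiosis on `[0, 100]` and constant above 100% aerobiosis. A
#' constant pool of oxidized quinones that does not participate in any
#' reaction (`dead_pool_ox`) is added when reporting redox states.
#'
#' @param pools list of conserved pools, each
#'   `list(members = chr, base = chr, total = mmol/l)`.
#' @param quinones list of quinone pools, each
#'   `list(members = chr, base = chr, intercept = mmol/l, slope = mmol/l per
#'   percent aerobiosis)`.
#' @param dead_pool_ox constant non-reactive oxidized quinone concentration
#'   (mmol/l).
#' @return Object of class `tk_moieties`.
#' @export
moiety_policy <- function(pools = list(), quinones = list(), dead_pool_ox = 0) {
  for (p in pools) {
    if (p$total <= 0) stop("conserved pool total must be positive", call. = FALSE)
    if (!p$base %in% p$members) stop("pool base must be a member", call. = FALSE)
  }
  for (q in quinones) {
    if (min(q$intercept, q$intercept + 100 * q$slope) < 0)
      stop("quinone pool total would be negative on [0, 100] aerobiosis",
           call. = FALSE)
    if (!q$base %in% q$members) stop("pool base must be a member", call. = FALSE)
  }
  structure(list(pools = pools, quinones = quinones,
                 dead_pool_ox = dead_pool_ox),
            class = "tk_moieties")
}

#' Quinone pool totals at a given aerobiosis level
#'
#' Affine in aerobiosis on `[0, 100]`, clamped at the 100% value above.
#'
#' @param aerobiosis aerobiosis in percent (>= 0).
#' @param mp a [moiety_policy()].
#' @return Named numeric vector of pool totals (mmol/l), named by the pool's
#'   oxidized (base) member.
#' @export
quinone_totals <- function(aerobiosis, mp) {
  if (aerobiosis < 0) stop("aerobiosis must be non-negative", call. = FALSE)
  a <- min(aerobiosis, 100)
  out <- vapply(mp$quinones, function(q) q$intercept + q$slope * a, numeric(1))
  names(out) <- vapply(mp$quinones, function(q) q$base, character(1))
  out
}

#' De novo synthesis flux of a conserved moiety
#'
#' The synthesis flux that keeps a conserved pool's total concentration
#' constant despite dilution by growth: flux = mu * total, injected into the
#' pool's least-phosphorylated / most-oxidized member.
#'
#' @param mu specific growth rate (1/h, >= 0).
#' @param total pool total (mmol/gDCW or mmol/l, units carried through).
#' @return Synthesis flux in the units of `total` per hour.
#' @export
moiety_synthesis_flux <- function(mu, total) {
  if (any(mu < 0)) stop("growth rate must be non-negative", call. = FALSE)
  mu * total
}
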