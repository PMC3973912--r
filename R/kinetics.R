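#' Define a reaction
#'
#' A reaction is a signed stoichiometry over metabolite ids (reactants
#' negative, products positive) plus a resistance specification. The
#' resistance kind is one of:
#' \describe{
#'   \item{`"finite"`}{constant resistance derived from an integer power-of-ten
#'     forward rate constant, `k_plus = 10^log10_k_plus`;}
#'   \item{`"regulated"`}{as `"finite"` but multiplied by saturation-type
#'     modifier terms in named metabolite potentials;}
#'   \item{`"qe"`}{zero resistance: the reaction is treated as a
#'     quasi-equilibrium constraint, F = 0;}
#'   \item{`"drain"`}{enforced-flux exchange reaction (production drain); the
#'     flux is clamped to `J_fixed` regardless of the thermokinetic state.}
#' }
#'
#' @param id reaction identifier.
#' @param stoich named numeric vector of stoichiometric coefficients,
#'   reactants negative, products positive.
#' @param kind resistance kind, see above.
#' @param log10_k_plus integer exponent x with k_plus = 10^x (finite/regulated).
#' @param modifiers list of modifier terms, each
#'   `list(metabolite =, type = "activator"|"inhibitor", theta =)`. An
#'   activator m multiplies the resistance by `1 / (1 + xi_m / theta)`, an
#'   inhibitor by `(1 + xi_m / theta)`.
#' @param enzyme optional gene id supplying the enzyme concentration; `NULL`
#'   means a constant enzyme level of 1.
#' @param J_fixed fixed biomass-specific flux (mmol/gDCW/h) for drains.
#'
#' @return An object of class `tk_reaction`.
#' @examples
#' reaction("PGI", c(g6p = -1, f6p = 1), kind = "qe")
#' reaction("PFK", c(f6p = -1, atp = -1, fdp = 1, adp = 1),
#'          log10_k_plus = 5, enzyme = "pfk")
#' @export
reaction <- function(id, stoich, kind = c("finite", "regulated", "qe", "drain"),
                     log10_k_plus = 0L, modifiers = list(), enzyme = NULL,
                     J_fixed = 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(stoich), !is.null(names(stoich)), all(nzchar(names(stoich))))
  if (anyDuplicated(names(stoich)))
    stop("duplicate metabolite in stoichiometry of '", id, "'", call. = FALSE)
  if (any(stoich == 0))
    stop("zero stoichiometric coefficient in '", id, "'", call. = FALSE)
  if (kind %in% c("finite", "regulated") &&
      abs(log10_k_plus - round(log10_k_plus)) > 1e-12)
    stop("log10_k_plus must be an integer for reaction '", id, "'", call. = FALSE)
  if (length(modifiers) > 0 && kind == "finite") kind <- "regulated"
  structure(
    list(id = id, stoich = stoich, kind = kind,
         log10_k_plus = as.integer(round(log10_k_plus)),
         modifiers = modifiers, enzyme = enzyme, J_fixed = J_fixed),
    class = "tk_reaction"
  )
}

#' @export
print.tk_reaction <- function(x, ...) {
  cat(sprintf("<tk_reaction> %s: %s [%s]\n", x$id,
              format_stoich(x$stoich, arrow = switch(x$kind,
                qe = "=", drain = "->", "<->")), x$kind))
  invisible(x)
}

reactant_ids <- function(rxn) names(rxn$stoich)[rxn$stoich < 0]
product_ids  <- function(rxn) names(rxn$stoich)[rxn$stoich > 0]

check_xi <- function(rxn, xi) {
  missing <- setdiff(names(rxn$stoich), names(xi))
  if (length(missing) > 0)
    stop("reaction '", rxn$id, "': no potential for metabolite(s) ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  if (any(!is.finite(xi[names(rxn$stoich)])) || any(xi[names(rxn$stoich)] < 0))
    stop("reaction '", rxn$id, "': potentials must be finite and non-negative",
         call. = FALSE)
}

#' Thermokinetic force of a reaction
#'
#' F = prod over reactants of xi^|nu| minus prod over products of xi^|nu|.
#' The sign of F gives the direction in which the reaction proceeds; F = 0
#' at equilibrium.
#'
#' @param rxn a [reaction()].
#' @param xi named numeric vector of thermokinetic potentials.
#' @return Dimensionless force.
#' @examples
#' rxn <- reaction("r", c(a = -1, b = -1, c = 1))
#' force(rxn, c(a = 2, b = 3, c = 5)) # 2*3 - 5 = 1
#' @export
force <- function(rxn, xi) {
  check_xi(rxn, xi)
  s <- rxn$stoich
  r <- s[s < 0]; p <- s[s > 0]
  prod(xi[names(r)]^abs(r)) - prod(xi[names(p)]^p)
}

#' Thermokinetic resistance of a reaction
#'
#' The base resistance is `k_plus^-1 * prod over reactants of C^-|nu|`, i.e.
#' it is tied to the thermokinetic capacities of the reactant set. For
#' regulated reactions the base value is multiplied by the declared
#' saturation terms in the metabolite potentials.
#'
#' @inheritParams force
#' @param capacities named numeric vector of capacities (mol/l) covering at
#'   least the reactant set.
#' @param xi potentials, required when the reaction carries modifier terms.
#' @return Resistance value (positive).
#' @examples
#' rxn <- reaction("r", c(a = -1, b = -1, c = 1), log10_k_plus = 1)
#' resistance(rxn, capacities = c(a = 0.5, b = 2, c = 1)) # 0.1
#' @export
resistance <- function(rxn, capacities, xi = NULL) {
  if (rxn$kind == "qe")
    stop("quasi-equilibrium reaction '", rxn$id, "' has no finite resistance",
         call. = FALSE)
  if (rxn$kind == "drain")
    stop("enforced-flux drain '", rxn$id, "' has no resistance", call. = FALSE)
  r <- rxn$stoich[rxn$stoich < 0]
  missing <- setdiff(names(r), names(capacities))
  if (length(missing) > 0)
    stop("reaction '", rxn$id, "': no capacity for ",
         paste0("'", missing, "'", collapse = ", "), call. = FALSE)
  R <- 10^(-rxn$log10_k_plus) * prod(capacities[names(r)]^(-abs(r)))
  if (length(rxn$modifiers) > 0) {
    if (is.null(xi))
      stop("reaction '", rxn$id, "' has modifier terms; potentials required",
           call. = FALSE)
    for (m in rxn$modifiers) {
      x <- xi[[m$metabolite]]
      if (is.null(x) || is.na(x))
        stop("reaction '", rxn$id, "': no potential for modifier '",
             m$metabolite, "'", call. = FALSE)
      term <- 1 + x / m$theta
      R <- if (identical(m$type, "activator")) R / term else R * term
    }
  }
  if (!is.finite(R) || R <= 0)
    stop("reaction '", rxn$id, "': resistance is not positive", call. = FALSE)
  R
}

#' Flux through a reaction
#'
#' Linear thermokinetic flux law: (R(xi) / c_E) * J = F(xi), i.e.
#' J = c_E * F / R. The flux always has the sign of the force.
#'
#' @inheritParams resistance
#' @param c_E enzyme concentration (non-negative, arbitrary units consistent
#'   with the resistance calibration).
#' @return Biomass-specific flux (mmol/gDCW/h by the package's convention).
#' @examples
#' rxn <- reaction("r", c(a = -1, b = 1), log10_k_plus = 0)
#' flux(rxn, xi = c(a = 2, b = 1), capacities = c(a = 1, b = 1), c_E = 1)
#' @export
flux <- function(rxn, xi, capacities, c_E = 1) {
  if (c_E < 0) stop("enzyme concentration must be non-negative", call. = FALSE)
  if (rxn$kind == "drain") return(rxn$J_fixed)
  FF <- force(rxn, xi)
  R <- resistance(rxn, capacities, xi = xi)
  c_E * FF / R
}
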