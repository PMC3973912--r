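#' Solution conditions for thermokinetic calculations
#'
#' A `thermo_context` bundles the physical constants and solution conditions
#' under which thermokinetic capacities are computed: temperature, pressure
#' (informational; all energies are isobaric-isothermal), pH, ionic strength,
#' water activity and the reference concentration. pH and water activity are
#' assumed to be already folded into the transformed formation energies
#' supplied with a model (Legendre transform convention); the context stores
#' them for provenance only.
#'
#' @param T temperature in K.
#' @param p pressure in Pa (informational).
#' @param pH solution pH (dimensionless).
#' @param I ionic strength in mol/kg.
#' @param a_h2o water activity (dimensionless).
#' @param c_ref reference concentration c-degree in mol/l.
#'
#' @return An object of class `thermo_context`.
#' @examples
#' ctx <- thermo_context(T = 310.15)
#' ctx$RT # J/mol
#' @export
thermo_context <- function(T = 310.15, p = 101325, pH = 7, I = 0.25,
                           a_h2o = 1, c_ref = 1) {
  stopifnot(is.numeric(T), length(T) == 1L, is.finite(T))
  if (T <= 0) stop("temperature must be positive", call. = FALSE)
  if (c_ref <= 0) stop("reference concentration must be positive", call. = FALSE)
  if (I < 0) stop("ionic strength must be non-negative", call. = FALSE)
  structure(
    list(
      T = T, p = p, pH = pH, I = I, a_h2o = a_h2o, c_ref = c_ref,
      R_star = 8.31446261815324,  # J/mol/K
      F_const = 96485.33212,      # C/mol
      RT = 8.31446261815324 * T
    ),
    class = "thermo_context"
  )
}

#' @export
print.thermo_context <- function(x, ...) {
  cat(sprintf(
    "<thermo_context> T = %.2f K, pH = %g, I = %g mol/kg, c_ref = %g mol/l\n",
    x$T, x$pH, x$I, x$c_ref
  ))
  invisible(x)
}

#' Thermokinetic capacity of a metabolite
#'
#' The capacity C maps the dimensionless thermokinetic potential xi to a
#' concentration, c = C * xi. It is derived from the transformed standard
#' Gibbs formation energy mu0' of the species (J/mol), its charge number z
#' and the electrical potential phi of its compartment:
#' C = c_ref * exp(-(mu0' + z * F * phi) / (R * T)).
#'
#' @param mu0_prime transformed standard Gibbs formation energy in J/mol
#'   (at the context's T, pH, water activity, corrected for ionic strength).
#' @param z charge number of the dominant species (integer).
#' @param phi electrical potential of the compartment in V.
#' @param ctx a [thermo_context()].
#' @param id optional metabolite id used in error messages.
#'
#' @return Capacity in mol/l (strictly positive). Vectorised over
#'   `mu0_prime`, `z` and `phi`.
#' @examples
#' ctx <- thermo_context(T = 298.15)
#' capacity(0, 0, 0, ctx)          # equals c_ref
#' capacity(-20e3, 0, 0, ctx)      # larger capacity for more stable species
#' @export
capacity <- function(mu0_prime, z = 0, phi = 0, ctx = thermo_context(),
                     id = NULL) {
  expo <- -(mu0_prime + z * ctx$F_const * phi) / ctx$RT
  # exp() overflows near 709.78; underflow to 0 would break c = C * xi too.
  bad <- !is.finite(expo) | abs(expo) > 700
  if (any(bad)) {
    who <- if (!is.null(id)) paste0(" for metabolite '", id[bad][1L], "'") else ""
    stop("capacity out of numeric range", who, call. = FALSE)
  }
  ctx$c_ref * exp(expo)
}

#' Log-capacity (internal, overflow-safe)
#'
#' Returns log(C / (1 mol/l)); used by the solver so that only stoichiometric
#' combinations of capacities are ever exponentiated.
#' @noRd
log_capacity <- function(mu0_prime, z = 0, phi = 0, ctx = thermo_context()) {
  log(ctx$c_ref) - (mu0_prime + z * ctx$F_const * phi) / ctx$RT
}

#' Ionic-strength correction to a transformed formation energy
#'
#' Extended Debye-Hueckel correction in Alberty's convention,
#' RT ln gamma = -alpha * z^2 * sqrt(I) / (1 + 1.6 * sqrt(I)),
#' with alpha = 1.17582 kg^(1/2) mol^(-1/2) (in units of RT) at 298.15 K.
#' The returned value is added to mu0' before capacities are computed.
#'
#' @inheritParams capacity
#' @param I ionic strength in mol/kg.
#' @return Additive correction in J/mol; 0 for uncharged species or I = 0.
#' @examples
#' ctx <- thermo_context(T = 298.15)
#' ionic_strength_correction(1, 0.25, ctx) # about -810 J/mol
#' @export
ionic_strength_correction <- function(z, I, ctx = thermo_context()) {
  if (any(I < 0)) stop("ionic strength must be non-negative", call. = FALSE)
  alpha <- 1.17582 # kg^0.5 mol^-0.5, Debye-Hueckel constant at 298.15 K
  sI <- sqrt(I)
  -ctx$RT * alpha * z^2 * sI / (1 + 1.6 * sI)
}

#' Concentration from thermokinetic potential
#'
#' @param xi thermokinetic potential (dimensionless, non-negative).
#' @param C capacity in mol/l.
#' @return Concentration c = C * xi in mol/l.
#' @examples
#' concentration_of(2.5, 0.004)
#' @export
concentration_of <- function(xi, C) {
  if (any(xi < 0)) stop("thermokinetic potential must be non-negative", call. = FALSE)
  C * xi
}

#' Thermokinetic potential from concentration
#'
#' Inverse of [concentration_of()]: xi = c / C.
#' @param c concentration in mol/l (non-negative).
#' @param C capacity in mol/l.
#' @return Dimensionless potential.
#' @export
potential_of <- function(c, C) {
  if (any(c < 0)) stop("concentration must be non-negative", call. = FALSE)
  c / C
}
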