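#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a solved steady state
#'
#' One row per model variable: concentrations (mmol/l), thermokinetic
#' potentials, fluxes (mmol/gDCW/h), enzyme levels and transcription-factor
#' activities.
#'
#' @param x a `tk_state`.
#' @param ... unused.
#' @return A tibble with columns `variable`, `type`, `value`.
#' @export
tidy.tk_state <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(variable = names(x$c), type = "concentration",
                   value = unname(x$c)),
    tibble::tibble(variable = names(x$xi), type = "potential",
                   value = unname(x$xi)),
    tibble::tibble(variable = names(x$J), type = "flux", value = unname(x$J)),
    if (length(x$c_E) > 0)
      tibble::tibble(variable = names(x$c_E), type = "enzyme",
                     value = unname(x$c_E)),
    if (length(x$a_TF) > 0)
      tibble::tibble(variable = names(x$a_TF), type = "tf_activity",
                     value = unname(x$a_TF)))
}

#' One-row summary of a solved steady state
#'
#' @param x a `tk_state`.
#' @param ... unused.
#' @return A tibble with growth rate, biomass, ATP/ADP ratio, residual norm
#'   and solver diagnostics.
#' @export
glance.tk_state <- function(x, ...) {
  tibble::tibble(
    converged = x$converged, washout = x$washout, mu = x$mu, c_X = x$c_X,
    atp_adp = x$atp_adp_ratio, aerobiosis = x$aerobiosis, D = x$D,
    residual_norm = x$residual_norm, iterations = x$iterations)
}

#' Long format of a sweep table
#'
#' @param x a `tk_sweep`.
#' @param ... unused.
#' @return A tibble with the swept parameter, `variable`, `type`, `value`.
#' @export
tidy.tk_sweep <- function(x, ...) {
  param <- attr(x, "param")
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x),
    cols = dplyr::matches("^(c|J|cE|a)\\."),
    names_to = c("type", "variable"), names_sep = "\\.")
  type_map <- c(c = "concentration", J = "flux", cE = "enzyme",
                a = "tf_activity")
  long$type <- unname(type_map[long$type])
  dplyr::select(long, dplyr::all_of(c(param, "variable", "type", "value")),
                dplyr::everything())
}

#' One-row summary of a production curve
#'
#' @param x a `tk_production`.
#' @param ... unused.
#' @return A tibble with the drain, mode, maximum volumetric productivity
#'   and limiting precursor.
#' @export
glance.tk_production <- function(x, ...) {
  lim <- attr(x, "limiting")
  tibble::tibble(
    drain = attr(x, "drain"), mode = attr(x, "mode"),
    max_q_prod = attr(x, "max_q"),
    J_prod_max = max(x$J_prod),
    limiting = paste(lim$species, collapse = "+"), tie = lim$tie)
}
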