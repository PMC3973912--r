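#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a steady-state sweep
#'
#' Line plot of selected variables against the swept parameter, faceted by
#' variable. By default plots every concentration; pass explicit variable
#' names (in the sweep table's `c.`/`J.`/`cE.`/`a.` naming or bare ids) to
#' select.
#'
#' @param object a `tk_sweep`.
#' @param vars variables to plot (bare metabolite/reaction/gene ids or
#'   prefixed column names).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tk_sweep <- function(object, vars = NULL, ...) {
  param <- attr(object, "param")
  long <- tidy(object)
  if (!is.null(vars))
    long <- dplyr::filter(long, .data$variable %in% vars |
                            paste0(substr(.data$type, 1, 1), ".",
                                   .data$variable) %in% vars)
  ggplot2::ggplot(long, ggplot2::aes(.data[[param]], .data$value,
                                     colour = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ variable, scales = "free_y") +
    ggplot2::labs(x = param, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a production-assessment curve
#'
#' Biomass (relative), relative precursor concentrations and volumetric
#' productivity against the enforced biomass-specific production flux; the
#' layout mirrors the way production-capability analyses are usually read:
#' relative curves start at unity, productivity on its own scale.
#'
#' @param object a `tk_production`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tk_production <- function(object, ...) {
  rel_cols <- grep("^rel\\.", names(object), value = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(c("c_X_rel", rel_cols)),
    names_to = "series", values_to = "rel")
  long$series <- sub("^rel\\.", "", long$series)
  long$series[long$series == "c_X_rel"] <- "biomass"
  scale_q <- max(object$q_prod) / max(1e-12, max(long$rel))
  ggplot2::ggplot(long, ggplot2::aes(.data$J_prod)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rel, colour = .data$series,
                                    linetype = .data$series)) +
    ggplot2::geom_line(
      data = tibble::as_tibble(object),
      ggplot2::aes(y = .data$q_prod / scale_q), colour = "blue") +
    ggplot2::scale_y_continuous(
      name = "relative to undisturbed state",
      sec.axis = ggplot2::sec_axis(~ . * scale_q,
                                   name = "q_prod (mmol/l/h)")) +
    ggplot2::labs(x = "J_prod (mmol/gDCW/h)",
                  title = attr(object, "drain")) +
    ggplot2::theme_minimal()
}

#' Plot a measurement overlay
#'
#' Simulation lines with scaled measurement points (f * x_m) per variable.
#'
#' @param object a `tk_overlay`.
#' @param sim the `tk_sweep` the overlay was computed from.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.tk_overlay <- function(object, sim, ...) {
  param <- names(object$points)[names(object$points) %in%
                                  c("aerobiosis", "D", "J_prod")][1]
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data[[param]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sim), colour = "blue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$scaled_value), colour = "red") +
    ggplot2::facet_wrap(~ variable_id, scales = "free_y") +
    ggplot2::labs(x = param, y = "simulated / scaled measured") +
    ggplot2::theme_minimal()
}
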