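#' Least-squares scaling factor for relative measurements
#'
#' Relative measurements x_m (transcripts, metabolite concentrations) are
#' compared with simulated variables x_s after scaling: f is chosen so that
#' the quadratic difference || (1/f) x_s - x_m ||^2 is minimal, which gives
#' f = (x_s' x_s) / (x_m' x_s). The data are then plotted as f * x_m next to
#' x_s.
#'
#' @param x_s simulated values.
#' @param x_m measured values (same length).
#' @return The scaling factor. If the vectors are orthogonal
#'   (x_m' x_s = 0) no scaling is defined: returns `NA` with a warning.
#' @examples
#' scaling_factor(c(1, 2), c(2, 2)) # 5/6
#' @export
scaling_factor <- function(x_s, x_m) {
  stopifnot(length(x_s) == length(x_m), length(x_s) >= 1)
  den <- sum(x_m * x_s)
  if (abs(den) < .Machine$double.eps * max(1, sum(abs(x_m * x_s)))) {
    warning("simulated and measured vectors are orthogonal; no scaling applied")
    return(NA_real_)
  }
  sum(x_s * x_s) / den
}

#' Overlay relative measurement data on a simulation sweep
#'
#' Matches a measurement table against a [sweep_states()] result and
#' computes, per variable, the scaling factor f, the scaled data points
#' f * x_m and the residual norm. Absolute variables (fluxes; biomass) are
#' compared directly, i.e. f is fixed at 1. Grid points present in the data
#' but absent from the sweep are listed and excluded, not silently dropped.
#'
#' @param sim a `tk_sweep` (swept over aerobiosis).
#' @param data a data frame with columns `variable_id`, `aerobiosis`,
#'   `value`, optional `sd`, and `kind` (one of `"transcript"`,
#'   `"metabolite"`, `"flux"`).
#' @return A list of class `tk_overlay`: `report` (one row per variable:
#'   kind, f, n, residual norm), `points` (matched pairs with scaled data)
#'   and `unmatched` (excluded rows).
#' @export
overlay <- function(sim, data) {
  stopifnot(inherits(sim, "tk_sweep"))
  param <- attr(sim, "param")
  needed <- c("variable_id", "value", "kind", param)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0)
    stop("measurement table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  col_for <- function(id, kind) {
    switch(kind,
      transcript = paste0("cE.", id),
      metabolite = paste0("c.", id),
      flux = if (id == "c_X") "c_X" else paste0("J.", id),
      stop("unknown measurement kind '", kind, "'", call. = FALSE))
  }
  data <- tibble::as_tibble(data)
  grid <- sim[[param]]
  matched <- dplyr::mutate(
    data,
    .col = vapply(seq_len(nrow(data)), function(i)
      col_for(data$variable_id[i], data$kind[i]), character(1)),
    .row = vapply(data[[param]], function(v) {
      hit <- which(abs(grid - v) < 1e-6 & sim$converged)
      if (length(hit) > 0) hit[1] else NA_integer_
    }, integer(1)))
  bad_col <- !matched$.col %in% names(sim)
  unmatched <- matched[is.na(matched$.row) | bad_col, ]
  ok <- matched[!is.na(matched$.row) & !bad_col, ]
  if (nrow(unmatched) > 0)
    warning(nrow(unmatched), " measurement row(s) had no matching grid ",
            "point or variable and were excluded")
  pts <- dplyr::mutate(ok,
    sim = vapply(seq_len(nrow(ok)), function(i)
      sim[[ok$.col[i]]][ok$.row[i]], numeric(1)))
  if (nrow(pts) > 0) {
    report <- dplyr::group_modify(
      dplyr::group_by(pts, .data$variable_id, .data$kind),
      function(d, key) {
        f <- if (key$kind %in% c("flux")) 1 else scaling_factor(d$sim, d$value)
        tibble::tibble(f = f, n = nrow(d),
                       residual_norm = if (is.na(f)) NA_real_
                         else sqrt(sum((d$sim / f - d$value)^2)))
      })
    report <- dplyr::ungroup(report)
  } else {
    report <- tibble::tibble(variable_id = character(0), kind = character(0),
                             f = numeric(0), n = integer(0),
                             residual_norm = numeric(0))
  }
  f_of <- stats::setNames(report$f, report$variable_id)
  pts$scaled_value <- as.numeric(pts$value * f_of[pts$variable_id])
  pts <- dplyr::select(pts, -dplyr::all_of(c(".col", ".row")))
  structure(list(report = report, points = pts,
                 unmatched = dplyr::select(unmatched,
                   -dplyr::any_of(c(".col", ".row")))),
            class = "tk_overlay")
}

#' @export
print.tk_overlay <- function(x, ...) {
  cat("<tk_overlay>", nrow(x$report), "variables,", nrow(x$points),
      "matched points,", nrow(x$unmatched), "excluded\n")
  print(x$report)
  invisible(x)
}

#' Assess production capability through an enforced precursor drain
#'
#' Introduces the stoichiometric shadow of a production pathway (see
#' [add_drain_reaction()]) and follows the chemostat steady state along an
#' increasing enforced biomass-specific production flux J_prod, by natural
#' continuation from the undisturbed state. Aeration is frozen in absolute
#' terms (a fixed `k_in_o2`), so the culture's aerobiosis may shift as the
#' biomass concentration responds. The sweep stops when the steady state
#' ceases to exist (wash-out or loss of the branch); the failure boundary is
#' then refined by successive step halving. Reported concentrations are
#' normalised to the undisturbed (J_prod = 0) state of the same run; the
#' volumetric productivity is q_prod = J_prod * c_X.
#'
#' @param doc the model.
#' @param drain drain stoichiometry string, e.g.
#'   `"2 accoa + 4 nadh -> 2 coa + 4 nad"`.
#' @param mode `"anaerobic"` (no oxygen input) or `"aerobic"`; aerobic mode
#'   fixes the oxygen supply to `aerobic_aerobiosis` percent of the
#'   calibrated scale, evaluated for the undisturbed culture.
#' @param aerobic_aerobiosis aerobiosis (percent of the calibrated scale)
#'   defining the aerobic operating point of the undisturbed case.
#' @param J_step initial step of the J_prod grid (mmol/gDCW/h).
#' @param J_max upper bound of the sweep.
#' @param refine_rounds rounds of step halving at the failure boundary.
#' @param track metabolite ids whose relative concentrations are reported in
#'   addition to the drained species.
#' @param ... solver controls.
#' @return A `tk_production` tibble: `J_prod`, `c_X`, `c_X_rel`, `q_prod`,
#'   `rel.<species>` columns for each drained/tracked species, plus
#'   attributes `max_q` (maximum volumetric productivity over the converged
#'   grid), `limiting` (see [limiting_precursor()]) and `undisturbed` (the
#'   J_prod = 0 state).
#' @export
production_assessment <- function(doc, drain,
                                  mode = c("anaerobic", "aerobic"),
                                  aerobic_aerobiosis = 160,
                                  J_step = 0.25, J_max = 60,
                                  refine_rounds = 3, track = character(0),
                                  ...) {
  mode <- match.arg(mode)
  kin <- if (mode == "anaerobic") 0 else {
    if (is.na(doc$chemostat$k_in_o2_100))
      stop("aerobic assessment requires a calibrated model ",
           "(run calibrate_aerobiosis() first)", call. = FALSE)
    aerobic_aerobiosis / 100 * doc$chemostat$k_in_o2_100
  }
  doc <- add_drain_reaction(doc, drain, J_prod = 0, id = "PROD")
  st <- parse_stoich(drain, allow_noninteger = TRUE, allow_empty_side = TRUE)
  drained <- names(st$stoich)[st$stoich < 0]
  species <- unique(c(drained, track))

  solve_at <- function(J, guess) {
    doc$drains[["PROD"]]$J_fixed <- J
    sys <- assemble(doc, k_in_o2 = kin)
    s <- tryCatch(solve_steady_state(sys, guess = guess, ...),
                  error = function(e) NULL)
    if (!is.null(s) && (!s$converged || s$washout || s$c_X < 1e-6)) s$failed <- TRUE
    s
  }
  st0 <- solve_at(0, NULL)
  if ((is.null(st0) || !st0$converged) && kin > 0) {
    # reach the aerobic operating point by continuation in the oxygen
    # supply from the (anaerobic-flavoured) default starting point
    doc0 <- doc
    guess <- NULL
    for (frac in c(0, 0.25, 0.5, 0.75, 1)) {
      sys <- assemble(doc0, k_in_o2 = frac * kin)
      s <- tryCatch(solve_steady_state(sys, guess = guess, ...),
                    error = function(e) NULL)
      if (is.null(s) || !s$converged) break
      guess <- s
    }
    if (!is.null(guess) && guess$converged) st0 <- solve_at(0, guess)
  }
  if (is.null(st0) || !st0$converged || st0$washout)
    stop("undisturbed steady state did not converge", call. = FALSE)

  pts <- list(list(J = 0, st = st0))
  J <- 0; step <- J_step; guess <- st0; round <- 0L
  repeat {
    Jn <- J + step
    if (Jn > J_max) break
    s <- solve_at(Jn, guess)
    ok <- !is.null(s) && isTRUE(s$converged) && !isTRUE(s$failed)
    if (ok) {
      pts[[length(pts) + 1L]] <- list(J = Jn, st = s)
      J <- Jn; guess <- s
    } else {
      round <- round + 1L
      if (round > refine_rounds) break
      step <- step / 2
    }
  }

  Jv <- vapply(pts, `[[`, numeric(1), "J")
  states <- lapply(pts, `[[`, "st")
  cX <- vapply(states, `[[`, numeric(1), "c_X")
  out <- tibble::tibble(
    J_prod = Jv, c_X = cX, c_X_rel = cX / cX[1], q_prod = Jv * cX,
    mu = vapply(states, `[[`, numeric(1), "mu"),
    atp_adp = vapply(states, `[[`, numeric(1), "atp_adp_ratio"))
  for (sp in species)
    out[[paste0("rel.", sp)]] <- vapply(states, function(s)
      s$c[[sp]], numeric(1)) / st0$c[[sp]]
  attr(out, "states") <- states
  attr(out, "drain") <- drain
  attr(out, "drained") <- drained
  attr(out, "mode") <- mode
  attr(out, "k_in_o2") <- kin
  attr(out, "max_q") <- max(out$q_prod)
  attr(out, "undisturbed") <- st0
  class(out) <- c("tk_production", class(out))
  attr(out, "limiting") <- limiting_precursor(out)
  out
}

#' Diagnose the limiting precursor of a production curve
#'
#' Among the drained species, the one with the largest relative
#' concentration drop at the last converged point of the curve. Ties (drops
#' within `tie_tol` of each other) are reported explicitly rather than
#' broken arbitrarily.
#'
#' @param curve a `tk_production`.
#' @param tie_tol absolute tolerance on the relative drop for declaring a
#'   tie.
#' @return A list: `species` (character vector; length > 1 indicates a tie),
#'   `drops` (named relative drops, 1 - c/c0, at the last point), `tie`.
#' @export
limiting_precursor <- function(curve, tie_tol = 1e-6) {
  drained <- attr(curve, "drained")
  if (length(drained) < 1)
    stop("production curve has no drained species", call. = FALSE)
  last <- nrow(curve)
  drops <- vapply(drained, function(sp)
    1 - curve[[paste0("rel.", sp)]][last], numeric(1))
  mx <- max(drops)
  winners <- names(drops)[drops >= mx - tie_tol]
  list(species = winners, drops = drops, tie = length(winners) > 1)
}
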