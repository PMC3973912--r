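#' Sweep a parameter and collect steady states
#'
#' Natural continuation along a monotone grid: each converged solution seeds
#' the next grid point. Failed points are flagged in the result, never
#' silently dropped.
#'
#' @param doc a `tkm_model`.
#' @param param one of `"aerobiosis"`, `"D"` (dilution rate) or `"J_prod"`
#'   (enforced flux of the drain named by `drain_id`).
#' @param values numeric grid (monotone).
#' @param drain_id drain reaction id used when `param = "J_prod"`.
#' @param guess optional warm start for the first grid point.
#' @param tol,maxit solver controls, see [solve_steady_state()].
#' @param k_in_o2 frozen absolute oxygen supply (mmol/l/h), used instead of
#'   the aerobiosis scaling when sweeping `J_prod` at fixed aeration.
#' @param ramp_eps ramp smoothing passed to [assemble()].
#' @return A `tk_sweep` tibble: one row per grid point with the swept value,
#'   convergence flags, biomass, growth rate and one column per
#'   concentration (`c.<id>`, mmol/l), flux (`J.<id>`, mmol/gDCW/h), enzyme
#'   level (`cE.<gene>`) and TF activity (`a.<tf>`). The solved `tk_state`
#'   objects are attached as the `"states"` attribute.
#' @export
sweep_states <- function(doc, param = c("aerobiosis", "D", "J_prod"),
                         values, drain_id = "PROD", guess = NULL,
                         tol = 1e-9, maxit = 200, k_in_o2 = NULL,
                         ramp_eps = 0) {
  param <- match.arg(param)
  states <- vector("list", length(values))
  prev <- guess
  for (i in seq_along(values)) {
    v <- values[i]
    doc_i <- doc
    aer <- 0
    kin <- k_in_o2
    if (param == "aerobiosis") aer <- v
    if (param == "D") doc_i$chemostat$D <- v
    if (param == "J_prod") {
      if (!drain_id %in% names(doc_i$drains))
        stop("no drain '", drain_id, "' in the model; add one with ",
             "add_drain_reaction()", call. = FALSE)
      doc_i$drains[[drain_id]]$J_fixed <- v
    }
    sys <- assemble(doc_i, aerobiosis = aer, k_in_o2 = kin,
                    ramp_eps = ramp_eps)
    st <- tryCatch(
      solve_steady_state(sys, guess = prev, tol = tol, maxit = maxit),
      error = function(e) NULL)
    if (!is.null(st)) {
      st$param <- param
      st$value <- v
      st$sys <- sys
      states[[i]] <- st
      if (st$converged && !st$washout) prev <- st
    }
    if (is.null(st) || !st$converged) {
      if (i == 1L)
        stop("sweep failed at the first grid point (", param, " = ", v, ")",
             call. = FALSE)
    }
  }
  # backward fill: re-attempt failed points seeded from the next converged
  # neighbour (continuation from the other side)
  solve_one <- function(i, guess) {
    v <- values[i]
    doc_i <- doc
    aer <- 0
    if (param == "aerobiosis") aer <- v
    if (param == "D") doc_i$chemostat$D <- v
    if (param == "J_prod") doc_i$drains[[drain_id]]$J_fixed <- v
    sys <- assemble(doc_i, aerobiosis = aer, k_in_o2 = k_in_o2,
                    ramp_eps = ramp_eps)
    st <- tryCatch(
      solve_steady_state(sys, guess = guess, tol = tol, maxit = maxit),
      error = function(e) NULL)
    if (!is.null(st)) { st$param <- param; st$value <- v; st$sys <- sys }
    st
  }
  ok <- vapply(states, function(s) !is.null(s) && s$converged, logical(1))
  for (i in rev(which(!ok))) {
    nxt <- which(ok & seq_along(ok) > i)
    if (length(nxt) == 0) next
    st <- solve_one(i, states[[min(nxt)]])
    if (!is.null(st) && st$converged) { states[[i]] <- st; ok[i] <- TRUE }
  }
  sweep_table(states, param, values)
}

sweep_table <- function(states, param, values) {
  if (length(values) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      list(numeric(0), logical(0), logical(0)),
      c(param, "converged", "washout")))
    attr(out, "states") <- list()
    attr(out, "param") <- param
    class(out) <- c("tk_sweep", class(out))
    return(out)
  }
  rows <- lapply(seq_along(values), function(i) {
    st <- states[[i]]
    base <- tibble::tibble(
      value = values[i],
      converged = !is.null(st) && st$converged,
      washout = !is.null(st) && st$washout)
    if (is.null(st)) return(base)
    wide <- c(
      stats::setNames(as.list(st$c), paste0("c.", names(st$c))),
      stats::setNames(as.list(st$J), paste0("J.", names(st$J))),
      if (length(st$c_E) > 0)
        stats::setNames(as.list(st$c_E), paste0("cE.", names(st$c_E))),
      if (length(st$a_TF) > 0)
        stats::setNames(as.list(st$a_TF), paste0("a.", names(st$a_TF))),
      list(mu = st$mu, c_X = st$c_X, atp_adp = st$atp_adp_ratio,
           residual_norm = st$residual_norm, k_in_o2 = st$k_in_o2))
    dplyr::bind_cols(base, tibble::as_tibble(wide))
  })
  out <- dplyr::bind_rows(rows)
  names(out)[1] <- param
  attr(out, "states") <- states
  attr(out, "param") <- param
  class(out) <- c("tk_sweep", class(out))
  out
}

#' Calibrate the aerobiosis scale
#'
#' The aerobiosis scale is defined operationally: 100% aerobiosis is the
#' steady state with the minimal oxygen input into the reactor at which no
#' fermentation products are excreted; the scale is linear in the oxygen
#' input, with 0% the anaerobic state. This function reproduces that
#' definition: it bisects on the volumetric oxygen supply rate `k_in_o2`
#' until the biomass-specific acetate excretion flux has dropped to
#' `ferm_frac` of its anaerobic value (default 1%, i.e. operationally
#' zero), and stores the result as `k_in_o2_100` in the returned model, so
#' that subsequent [assemble()] calls can map aerobiosis percent to oxygen
#' supply.
#'
#' @param doc the model (must excrete acetate anaerobically).
#' @param acetate_id extracellular acetate id.
#' @param ferm_frac fraction of the anaerobic acetate excretion defining
#'   "no fermentation products" (operational zero).
#' @param k_max upper bracket for the oxygen supply (mmol/l/h); raised
#'   automatically if needed.
#' @param tol_k relative bisection tolerance on `k_in_o2`.
#' @param ... passed to [solve_steady_state()].
#' @return The model with `chemostat$k_in_o2_100` set; the anaerobic state
#'   and the calibration trace are attached as attributes
#'   (`"anaerobic_state"`, `"trace"`).
#' @export
calibrate_aerobiosis <- function(doc, acetate_id = "ac_e", ferm_frac = 0.01,
                                 k_max = 30, tol_k = 1e-3, ...) {
  excr <- function(st) {
    # biomass-specific acetate excretion, mmol/gDCW/h
    D <- st$D
    if (st$c_X <= 0) return(0)
    D * st$c[[acetate_id]] / st$c_X
  }
  sys0 <- assemble(doc, k_in_o2 = 0)
  st0 <- solve_steady_state(sys0, ...)
  if (!st0$converged || st0$washout)
    stop("anaerobic reference state did not converge", call. = FALSE)
  J0 <- excr(st0)
  if (J0 <= 0)
    stop("model excretes no acetate anaerobically; cannot calibrate",
         call. = FALSE)
  target <- ferm_frac * J0
  trace <- list()
  solve_at <- function(k, guess) {
    st <- tryCatch(
      solve_steady_state(assemble(doc, k_in_o2 = k), guess = guess, ...),
      error = function(e) NULL)
    trace[[length(trace) + 1L]] <<- list(k = k, state = st)
    st
  }
  # march upward to bracket the zero-acetate point (adaptive continuation)
  lo <- 0; st_lo <- st0; hi <- NA_real_
  step <- k_max / 64
  guess <- st0
  st_hi <- NULL
  while (is.na(hi)) {
    k <- lo + step
    st <- solve_at(k, guess)
    if (is.null(st) || !st$converged) {
      step <- step / 2
      if (step < k_max / 4096)
        stop("calibration solve failed near k_in_o2 = ", signif(k, 4),
             call. = FALSE)
      next
    }
    if (excr(st) <= target) { hi <- k; st_hi <- st; break }
    lo <- k; st_lo <- st; guess <- st
    step <- min(step * 2, k_max / 8)
    if (lo > 4 * k_max)
      stop("acetate excretion does not vanish below k_in_o2 = ", 4 * k_max,
           call. = FALSE)
  }
  while ((hi - lo) / hi > tol_k) {
    mid <- (lo + hi) / 2
    st <- solve_at(mid, st_lo)
    if (is.null(st) || !st$converged) { hi <- mid; next }
    if (excr(st) <= target) { hi <- mid; st_hi <- st } else { lo <- mid; st_lo <- st }
  }
  doc$chemostat$k_in_o2_100 <- hi
  attr(doc, "anaerobic_state") <- st0
  attr(doc, "trace") <- trace
  doc
}
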