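## Damped Newton solver with pseudo-transient (Levenberg-regularised)
## fallback. Variables: log-concentrations (positivity built in),
## quasi-equilibrium fluxes and biomass in linear space.

tk_jacobian <- function(sys, x, r0, central = FALSE) {
  n <- length(x)
  Jm <- matrix(0, length(r0), n)
  for (j in seq_len(n)) {
    h <- (if (central) 1e-6 else 1e-7) * max(1, abs(x[j]))
    xp <- x; xp[j] <- xp[j] + h
    if (central) {
      xm <- x; xm[j] <- xm[j] - h
      Jm[, j] <- (tk_eval(sys, xp)$residual - tk_eval(sys, xm)$residual) / (2 * h)
    } else {
      Jm[, j] <- (tk_eval(sys, xp)$residual - r0) / h
    }
  }
  Jm
}

tk_scales <- function(sys) {
  # residual row scales so that "converged" is comparable across row types
  s <- rep(1, length(sys$row_names))
  names(s) <- sys$row_names
  D <- sys$env$D
  s[grepl("^ext\\.", sys$row_names)] <- 1 / max(D, 1e-6)
  s[grepl("^gas\\.", sys$row_names)] <- 1
  s
}

# Diagonal mass entries for pseudo-transient continuation: each differential
# row is paired with the log-concentration variable of its species, with
# mass d r / d (dx/dt): species balances (mmol/gDCW/h) carry v_cell * c_i,
# chemostat rows carry c_i, the growth row pairs with biomass.
tk_mass <- function(sys, ev) {
  rn <- sys$row_names
  m_row <- numeric(length(rn))
  m_var <- rep(NA_integer_, length(rn))
  Lpos <- match(paste0("L.", sys$met_ids), sys$var_names)
  for (k in seq_along(rn)) {
    if (grepl("^bal\\.", rn[k])) {
      id <- sub("^bal\\.", "", rn[k])
      m_var[k] <- Lpos[match(id, sys$met_ids)]
      m_row[k] <- sys$env$v_cell * ev$c[[id]]
    } else if (grepl("^(ext|gas)\\.", rn[k])) {
      id <- sub("^(ext|gas)\\.", "", rn[k])
      m_var[k] <- Lpos[match(id, sys$met_ids)]
      m_row[k] <- ev$c[[id]]
    } else if (rn[k] == "growth") {
      m_var[k] <- sys$idxX
      m_row[k] <- 1
    }
  }
  list(var = m_var, mass = m_row)
}

newton_step <- function(sys, x, r, sc, nrm, dtau = Inf, ev = NULL) {
  # central differences near the solution for clean terminal convergence
  Jm <- tk_jacobian(sys, x, r, central = nrm(r) < 1e-5)
  A <- Jm * sc
  if (is.finite(dtau)) {
    mm <- tk_mass(sys, ev)
    for (k in which(!is.na(mm$var)))
      A[k, mm$var[k]] <- A[k, mm$var[k]] + sc[k] * mm$mass[k] / dtau
  }
  dx <- tryCatch(-solve(A, r * sc), error = function(e) NULL)
  if (is.null(dx) || any(!is.finite(dx))) {
    # (near-)singular system, e.g. dissolved oxygen in a strictly anaerobic
    # chemostat: rank-revealing QR, inert null directions get a zero step
    dx <- tryCatch({
      co <- qr.coef(qr(A), -(r * sc))
      co[!is.finite(co)] <- 0
      co
    }, error = function(e) NULL)
  }
  if (is.null(dx) || any(!is.finite(dx))) return(NULL)
  dx <- drop(dx)
  cap <- if (length(sys$idxL) > 0) max(abs(dx[sys$idxL])) else 0
  if (is.finite(cap) && cap > 4) dx <- dx * (4 / cap)
  dx
}

try_linesearch <- function(sys, x, dx, r, nrm, armijo = TRUE) {
  alpha <- 1
  for (ls in 1:25) {
    xn <- x + alpha * dx
    if (sys$solve_cX) xn[sys$idxX] <- max(xn[sys$idxX], 1e-12)
    evn <- tryCatch(tk_eval(sys, xn), error = function(e) NULL)
    if (!is.null(evn) && all(is.finite(evn$residual))) {
      ok <- if (armijo) nrm(evn$residual) < (1 - 1e-4 * alpha) * nrm(r)
        else nrm(evn$residual) < 1e3 * nrm(r)
      if (ok) return(list(x = xn, ev = evn, alpha = alpha))
    }
    alpha <- alpha / 2
  }
  NULL
}

newton_solve <- function(sys, x0, tol = 1e-9, maxit = 200, quiet = TRUE) {
  sc <- tk_scales(sys)
  nrm <- function(r) max(abs(r * sc))
  x <- x0
  ev <- tk_eval(sys, x)
  r <- ev$residual
  it <- 0L
  best <- list(x = x, ev = ev, norm = nrm(r))
  mode <- "newton"
  dtau <- 1e-3
  stall <- 0L
  repeat {
    it <- it + 1L
    if (nrm(r) < tol || it > maxit) break
    if (mode == "newton") {
      dx <- newton_step(sys, x, r, sc, nrm)
      step <- if (is.null(dx)) NULL else try_linesearch(sys, x, dx, r, nrm)
      if (!is.null(step) && step$alpha > 1 / 64) {
        x <- step$x; ev <- step$ev; r <- ev$residual
        stall <- 0L
      } else if (!is.null(step)) {
        x <- step$x; ev <- step$ev; r <- ev$residual
        stall <- stall + 1L
        if (stall >= 3L) { mode <- "ptc"; dtau <- 1e-3; stall <- 0L }
      } else {
        mode <- "ptc"; dtau <- 1e-3
      }
    } else {
      # pseudo-transient: implicit Euler on the physical dynamics with
      # growing steps; falls back to Newton once steps are large
      dx <- newton_step(sys, x, r, sc, nrm, dtau = dtau, ev = ev)
      step <- if (is.null(dx)) NULL
        else try_linesearch(sys, x, dx, r, nrm, armijo = FALSE)
      if (!is.null(step)) {
        x <- step$x; ev <- step$ev; r <- ev$residual
        dtau <- dtau * 2
        if (dtau > 1e5) mode <- "newton"
      } else {
        dtau <- dtau / 8
        if (dtau < 1e-9) break
      }
    }
    if (nrm(r) < best$norm) best <- list(x = x, ev = ev, norm = nrm(r))
  }
  if (nrm(r) < best$norm) best <- list(x = x, ev = ev, norm = nrm(r))
  list(x = best$x, ev = best$ev, norm = best$norm, iterations = it,
       converged = best$norm < tol)
}

integrate_polish <- function(sys, x0, tol, maxit) {
  x <- x0
  best <- newton_solve(sys, x0, tol = tol, maxit = 0)
  for (t_end in c(1, 10, 100, 1000)) {
    tr <- tryCatch(suppressWarnings(deSolve::lsoda(
      y = x, times = c(0, t_end), maxsteps = 50000,
      func = function(t, y, p) list(tk_eval_dynamic(sys, y)$dydt),
      rtol = 1e-6, atol = 1e-8)), error = function(e) NULL)
    if (is.null(tr) || nrow(tr) < 2) break
    xn <- tr[nrow(tr), -1]
    if (any(!is.finite(xn))) break
    x <- xn
    if (sys$solve_cX) x[sys$idxX] <- max(x[sys$idxX], 1e-12)
    cand <- newton_solve(sys, x, tol = tol, maxit = maxit)
    if (cand$norm < best$norm) best <- cand
    if (best$converged) break
  }
  best
}

# replace quasi-equilibrium reactions by fast finite reactions (relaxation);
# rate constants scale with the reactant count so every fast reaction
# relaxes roughly two orders of magnitude faster than the chemostat
tk_relax_system <- function(sys, extra_args = list()) {
  doc <- sys$doc
  for (id in sys$qe_ids) {
    r <- doc$reactions[[id]]
    n_r <- sum(abs(r$stoich[r$stoich < 0]))
    doc$reactions[[id]] <- reaction(id, r$stoich, kind = "finite",
                                    log10_k_plus = as.integer(3 * (n_r - 1) + 2))
  }
  do.call(assemble, c(list(doc = doc),
                      utils::modifyList(sys$call_args, extra_args)))
}

# staged global solve for chemostat models that resist a direct Newton run:
# (A) fix the biomass concentration (dropping the growth closure), settle
#     the remaining system, integrating a relaxed-QE variant in time if
#     Newton alone does not get there;
# (B) adjust the fixed biomass by a guarded secant iteration on
#     mu(c_X) - D (growth is monotone in biomass through substrate supply);
# (C) release the biomass and polish the full system with Newton.
tk_global_solve <- function(sys, x0, tol, maxit) {
  cX <- if (sys$solve_cX) max(x0[sys$idxX], 1e-3) else sys$cX_val
  mk_fixed <- function(cX) {
    do.call(assemble, c(list(doc = sys$doc),
                        utils::modifyList(sys$call_args,
                                          list(c_X_fixed = cX))))
  }
  sysF <- mk_fixed(cX)
  xF <- if (sys$solve_cX) x0[-sys$idxX] else x0
  solF <- newton_solve(sysF, xF, tol = max(tol, 1e-8), maxit = maxit)
  if (!solF$converged) {
    if (length(sysF$qe_ids) > 0) {
      relax <- tk_relax_system(sys, list(c_X_fixed = cX))
      x0r <- xF[-sysF$idxQ]
      solr <- newton_solve(relax, x0r, tol = 1e-6, maxit = maxit)
      if (!solr$converged) {
        cand <- integrate_polish(relax, x0r, 1e-6, maxit)
        if (cand$norm < solr$norm) solr <- cand
      }
      xq <- numeric(sysF$n_x)
      xq[sysF$idxL] <- solr$x[relax$idxL]
      xq[sysF$idxQ] <- solr$ev$J[sysF$qe_ids]
      cand <- newton_solve(sysF, xq, tol = max(tol, 1e-8), maxit = maxit)
      if (cand$norm < solF$norm) solF <- cand
    } else {
      cand <- integrate_polish(sysF, xF, max(tol, 1e-8), maxit)
      if (cand$norm < solF$norm) solF <- cand
    }
  }
  if (!sys$solve_cX) return(solF)   # sysF coincides with sys in this case
  if (!solF$converged)
    return(list(x = c(solF$x, cX), norm = Inf, ev = solF$ev,
                iterations = solF$iterations, converged = FALSE))
  # stage B: scalar iteration on the growth closure
  D <- sys$env$D
  g <- solF$ev$mu - D
  pts <- list(list(cX = cX, g = g, x = solF$x))
  for (it in 1:15) {
    if (abs(g) < 1e-4) break
    # guarded secant / geometric step: mu falls as biomass rises
    if (length(pts) >= 2) {
      p1 <- pts[[length(pts) - 1]]; p2 <- pts[[length(pts)]]
      if (abs(p2$g - p1$g) > 1e-12) {
        cX_new <- p2$cX - p2$g * (p2$cX - p1$cX) / (p2$g - p1$g)
      } else cX_new <- p2$cX * if (g > 0) 1.5 else 0.67
    } else cX_new <- cX * if (g > 0) 1.5 else 0.67
    if (!is.finite(cX_new) || cX_new <= 0) cX_new <- cX * if (g > 0) 1.5 else 0.67
    cX_new <- min(max(cX_new, cX / 3), cX * 3)
    sysF <- mk_fixed(cX_new)
    solF2 <- newton_solve(sysF, pts[[length(pts)]]$x, tol = max(tol, 1e-8),
                          maxit = maxit)
    if (!solF2$converged) break
    cX <- cX_new
    g <- solF2$ev$mu - D
    solF <- solF2
    pts[[length(pts) + 1]] <- list(cX = cX, g = g, x = solF$x)
  }
  # stage C: full polish with biomass free
  xq <- numeric(sys$n_x)
  xq[-sys$idxX] <- solF$x
  xq[sys$idxX] <- cX
  newton_solve(sys, xq, tol = tol, maxit = maxit)
}

#' Solve for a chemostat steady state
#'
#' Damped Newton iteration (with line search and a pseudo-transient
#' Levenberg-regularised fallback when a full step stalls) on the reduced
#' steady-state residual assembled by [assemble()]. At a nontrivial solution
#' all species balances close to `tol` and the specific growth rate equals
#' the dilution rate. Wash-out (the culture cannot sustain the dilution
#' rate) is detected and reported as a distinct, valid outcome with the
#' biomass at zero and the extracellular medium at its inflow composition.
#'
#' @param sys a `tk_system` from [assemble()], or a `tkm_model` (assembled
#'   with defaults).
#' @param guess optional initial state: a previous `tk_state` (warm start)
#'   or a raw state vector.
#' @param tol absolute residual tolerance (default 1e-9).
#' @param maxit maximum Newton iterations.
#' @return An object of class `tk_state`: solved concentrations (mmol/l),
#'   potentials, fluxes (mmol/gDCW/h), enzyme levels, TF activities, growth
#'   rate, biomass, residual norm and diagnostics.
#' @export
solve_steady_state <- function(sys, guess = NULL, tol = 1e-9, maxit = 200) {
  if (inherits(sys, "tkm_model")) sys <- assemble(sys)
  x0 <- if (is.null(guess)) tk_default_guess(sys)
    else if (inherits(guess, "tk_state")) guess$x
    else guess
  if (length(x0) != sys$n_x)
    stop("initial guess has wrong length (", length(x0), " != ", sys$n_x, ")",
         call. = FALSE)
  # gas species whose supply changed since the guess was made can sit many
  # orders of magnitude below their new scale, where the balance is
  # insensitive to them; lift them to the no-consumption level k_in/k_out
  for (i in sys$gas_rows) {
    id <- sys$met_ids[i]
    kin_i <- if (id %in% names(sys$env$k_in)) sys$env$k_in[[id]] else 0
    if (kin_i > 0) {
      Lcap <- log(kin_i / sys$env$k_out[[id]])
      j <- match(paste0("L.", id), sys$var_names)
      if (!is.na(j) && x0[j] < Lcap + log(1e-3)) x0[j] <- Lcap
    }
  }
  sol <- newton_solve(sys, x0, tol = tol, maxit = maxit)

  if (!sol$converged) {
    if (sys$solve_cX || length(sys$qe_ids) > 0) {
      cand <- tk_global_solve(sys, x0, tol, maxit)
      if (cand$norm < sol$norm) sol <- cand
    } else {
      cand <- integrate_polish(sys, x0, tol, maxit)
      if (cand$norm < sol$norm) sol <- cand
    }
  }

  washout <- FALSE
  if (sys$solve_cX && (!sol$converged || sol$ev$c_X < 1e-8)) {
    # try the wash-out branch: c_X = 0, biomass row dropped
    sys0 <- sys
    sys0$solve_cX <- FALSE
    sys0$cX_val <- 0
    sys0$n_x <- sys$n_x - 1L
    sys0$idxX <- NA_integer_
    sys0$row_names <- setdiff(sys$row_names, "growth")
    sys0$var_names <- setdiff(sys$var_names, "c_X")
    x00 <- x0[-sys$idxX]
    sol0 <- newton_solve(sys0, x00, tol = tol, maxit = maxit)
    if (sol0$converged && !sol$converged) {
      sol <- sol0
      washout <- TRUE
    } else if (sol$converged && sol$ev$c_X < 1e-8) {
      washout <- TRUE
    }
  }
  ev <- sol$ev
  xi <- exp(ev$L - sys$lC_mm)
  names(xi) <- sys$met_ids
  structure(list(
    converged = sol$converged, washout = washout,
    c = ev$c, xi = xi, J = ev$J, c_E = ev$c_E, a_TF = ev$a_TF,
    mu = ev$mu, maintenance = ev$maint, c_X = ev$c_X,
    atp_adp_ratio = ev$ratio,
    residual_norm = sol$norm, iterations = sol$iterations,
    aerobiosis = sys$aerobiosis, D = sys$env$D,
    k_in_o2 = if (!is.null(sys$env$o2_id) && !is.na(sys$env$o2_id) &&
                  sys$env$o2_id %in% names(sys$env$k_in))
      sys$env$k_in[[sys$env$o2_id]] else NA_real_,
    x = sol$x, residual = ev$residual), class = "tk_state")
}

#' @export
print.tk_state <- function(x, ...) {
  cat(sprintf(
    "<tk_state> %s%s  mu = %.4g /h, c_X = %.4g g/l, residual = %.2e (%d iterations)\n",
    if (x$converged) "converged" else "NOT converged",
    if (x$washout) " (wash-out)" else "",
    x$mu, x$c_X, x$residual_norm, x$iterations))
  invisible(x)
}

#' Elemental carbon balance of a solved steady state
#'
#' Checks that carbon inflow equals carbon outflow at steady state: glucose
#' (and any other carbon) in the feed versus biomass carbon, CO2 outgassing,
#' excreted products, unconsumed substrate in the outflow, and the carbon
#' held in intracellular metabolites that leaves with the biomass.
#'
#' @param state a converged `tk_state`.
#' @param sys the `tk_system` it was solved on.
#' @return A list with `inflow`, `outflow` (mmol C/l/h) and `relative_gap`.
#' @export
carbon_balance <- function(state, sys) {
  met <- sys$doc$metabolites
  carbon <- stats::setNames(met$carbon, met$id)
  env <- sys$env
  D <- env$D
  inflow <- 0; outflow <- 0
  for (id in names(env$c_in)) inflow <- inflow + D * env$c_in[[id]] * carbon[[id]]
  for (i in which(met$external & !met$gas & !met$clamped))
    outflow <- outflow + D * state$c[[met$id[i]]] * carbon[[met$id[i]]]
  for (i in which(met$gas & !met$clamped)) {
    id <- met$id[i]
    kout <- env$k_out[[id]]
    kin <- if (id %in% names(env$k_in)) env$k_in[[id]] else 0
    inflow <- inflow + kin * carbon[[id]]
    outflow <- outflow + kout * state$c[[id]] * carbon[[id]]
  }
  # biomass carbon and intracellular metabolite carbon leaving with cells
  if (!is.null(sys$bio)) {
    outflow <- outflow + D * state$c_X * sys$bio$stoich$x_carbon
  }
  if (!is.null(sys$bio)) {
    # cells leaving the reactor carry their intracellular metabolite carbon
    intern <- which(sys$internal)
    c_int <- sum(state$c[met$id[intern]] * carbon[met$id[intern]])
    outflow <- outflow + D * state$c_X * env$v_cell * c_int
  }
  # enforced drains remove the drained carbon as (unmodelled) product
  for (d in sys$drains) {
    st <- sys$doc$drains[[d]]$stoich
    drained_c <- -sum(st * carbon[names(st)])
    outflow <- outflow + sys$doc$drains[[d]]$J_fixed * state$c_X * drained_c
  }
  # moiety de novo synthesis creates pool carbon from outside the balance
  for (p in seq_along(sys$pools)) {
    cc <- carbon[sys$pools[[p]]$members[1]]
    if (cc != 0)
      inflow <- inflow + state$mu * sys$totals[p] * cc * state$c_X * env$v_cell
  }
  list(inflow = inflow, outflow = outflow,
       relative_gap = abs(inflow - outflow) / max(abs(inflow), 1e-12))
}

#' Integrate an unreduced model in time
#'
#' Time integration of the full ODE system (chemostat, metabolites, biomass)
#' for models without quasi-equilibrium reactions. This is a test and
#' fallback surface, not a product surface: it exists to cross-check the
#' steady-state solver against brute-force integration and to verify
#' conserved-moiety behaviour along trajectories. De novo synthesis of
#' conserved moieties (mu times the pool total, into the base member) is
#' included so pool totals stay constant despite dilution by growth.
#'
#' @param sys a `tk_system` without QE reactions.
#' @param times numeric vector of output times (h).
#' @param x0 optional initial state vector (defaults to [tk_default_guess()]
#'   semantics).
#' @param mu_override fix the dilution/growth rate used for intracellular
#'   dilution (useful for models without a biomass section).
#' @return A tibble: time plus one column per concentration and biomass.
#' @export
tk_integrate <- function(sys, times, x0 = NULL, mu_override = NULL) {
  if (length(sys$qe_ids) > 0)
    stop("time integration supports ODE-only models (no QE reactions)",
         call. = FALSE)
  if (!requireNamespace("deSolve", quietly = TRUE))
    stop("deSolve is required for tk_integrate()", call. = FALSE)
  if (is.null(x0)) x0 <- tk_default_guess(sys)
  env <- sys$env
  rhs <- function(t, y, parms) {
    ev <- tk_eval_dynamic(sys, y, mu_override)
    list(ev$dydt)
  }
  out <- deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  res <- tibble::as_tibble(as.data.frame(out))
  # convert log-concentrations back
  for (j in seq_along(sys$vL))
    res[[1 + j]] <- exp(res[[1 + j]])
  names(res) <- c("time", sys$met_ids[sys$vL],
                  if (sys$solve_cX) "c_X")
  res
}

# dynamic right-hand side in the same variable layout as the steady solver
# (log-concentrations; d log c/dt = (dc/dt)/c), base members integrated like
# any other species with the de novo synthesis flux included.
tk_eval_dynamic <- function(sys, x, mu_override = NULL) {
  ev <- tk_eval(sys, x)
  env <- sys$env
  mu <- if (!is.null(mu_override)) mu_override else ev$mu
  Tn <- drop(sys$S %*% ev$J) + mu * sys$B + ev$maint * sys$Mvec
  dydt <- numeric(length(x))
  met <- sys$met_ids
  for (j in seq_along(sys$vL)) {
    i <- sys$vL[j]
    id <- met[i]
    ci <- ev$c[[id]]
    if (sys$internal[i]) {
      dc <- Tn[i] / env$v_cell - mu * ci
      # de novo synthesis into conserved-pool base members
      p <- which(sys$base_idx == i)
      if (length(p) == 1) dc <- dc + mu * sys$totals[p]
    } else if (i %in% sys$ext_rows) {
      cin <- if (id %in% names(env$c_in)) env$c_in[[id]] else 0
      dc <- Tn[i] * ev$c_X + env$D * (cin - ci)
    } else {
      kin_i <- if (id %in% names(env$k_in)) env$k_in[[id]] else 0
      dc <- Tn[i] * ev$c_X + kin_i - env$k_out[[id]] * ci
    }
    dydt[j] <- dc / ci            # log-space integration
  }
  if (sys$solve_cX)
    dydt[sys$idxX] <- (mu - env$D) * x[sys$idxX]
  list(dydt = dydt, ev = ev)
}
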