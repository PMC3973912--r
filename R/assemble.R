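#' Assemble the reduced steady-state system from a model document
#'
#' Builds the residual evaluator for the chemostat steady-state problem.
#' Quasi-equilibrium reduction: every zero-resistance reaction contributes an
#' algebraic constraint F_j = 0 (linear in log-potentials) and its unknown
#' flux becomes an algebraic variable, so the coupled species behave as a
#' lumped pool; the resulting system has differential index one. Conserved
#' moieties replace the balance of each pool's base member (the least
#' phosphorylated / most oxidized species, into which de novo synthesis is
#' routed) by the pool-total constraint; quinone pool totals are evaluated at
#' the requested aerobiosis level.
#'
#' Unknowns: log-concentrations of all non-clamped metabolites (positivity by
#' construction), the fluxes of quasi-equilibrium reactions, and the biomass
#' concentration. Flux laws are evaluated in log space so that only
#' stoichiometric combinations of capacities are exponentiated.
#'
#' @param doc a validated `tkm_model`.
#' @param aerobiosis aerobiosis level in percent (sets the oxygen supply rate
#'   `k_in_o2 = aerobiosis/100 * k_in_o2_100` and the quinone pool totals).
#'   Ignored for models without a calibrated/declared oxygen supply.
#' @param k_in_o2 direct oxygen supply rate (mmol/l/h), overriding the
#'   aerobiosis scaling (used by the calibration and by assessments at frozen
#'   absolute aeration).
#' @param c_X_fixed fix the biomass concentration (g/l) instead of solving
#'   for it; models without a biomass section always behave as if
#'   `c_X_fixed = 1`.
#' @param ramp_eps C1 smoothing width for the growth/maintenance ramps
#'   (0 = exact piecewise-linear).
#' @return An object of class `tk_system`.
#' @export
assemble <- function(doc, aerobiosis = 0, k_in_o2 = NULL, c_X_fixed = NULL,
                     ramp_eps = 0) {
  call_args <- list(aerobiosis = aerobiosis, k_in_o2 = k_in_o2,
                    c_X_fixed = c_X_fixed, ramp_eps = ramp_eps)
  validate_model(doc)
  met <- doc$metabolites
  n_m <- nrow(met)
  met_ids <- met$id
  ctx <- doc$context
  phi <- stats::setNames(doc$compartments$phi, doc$compartments$name)
  if (nrow(doc$compartments) == 0) phi <- c(c = 0)
  phi_of <- unname(phi[met$compartment])
  phi_of[is.na(phi_of)] <- 0

  lC <- log_capacity(met$dfg0, met$z, phi_of, ctx)     # ln C, C in mol/l
  lC_mm <- lC + log(1000)                              # concentrations in mmol/l
  names(lC_mm) <- met_ids

  rxns <- c(doc$reactions, doc$drains)
  n_r <- length(rxns)
  S <- matrix(0, n_m, n_r, dimnames = list(met_ids, names(rxns)))
  for (j in seq_along(rxns)) S[names(rxns[[j]]$stoich), j] <- rxns[[j]]$stoich

  kin <- list()
  qe_ids <- character(0)
  for (r in rxns) {
    if (r$kind == "qe") { qe_ids <- c(qe_ids, r$id); next }
    if (r$kind == "drain") next
    ri <- match(reactant_ids(r), met_ids); wi <- abs(r$stoich[r$stoich < 0])
    pi <- match(product_ids(r), met_ids);  wp <- r$stoich[r$stoich > 0]
    lnKeq <- sum(wp * lC[pi]) - sum(wi * lC[ri])       # capacities, mol/l
    kin[[r$id]] <- list(
      id = r$id, ri = ri, wi = unname(wi), pi = pi, wp = unname(wp),
      a_r = r$log10_k_plus * log(10) - sum(wi) * log(1000),
      a_p = r$log10_k_plus * log(10) - sum(wp) * log(1000) - lnKeq,
      mods = lapply(r$modifiers, function(m)
        list(i = match(m$metabolite, met_ids), type = m$type,
             l_theta = log(m$theta) + lC_mm[match(m$metabolite, met_ids)],
             theta = m$theta)),
      enzyme = r$enzyme)
  }
  qe_info <- lapply(doc$reactions[qe_ids], function(r) {
    ri <- match(reactant_ids(r), met_ids); wi <- abs(r$stoich[r$stoich < 0])
    pi <- match(product_ids(r), met_ids);  wp <- r$stoich[r$stoich > 0]
    list(ri = ri, wi = unname(wi), pi = pi, wp = unname(wp),
         const = sum(wp * lC_mm[pi]) - sum(wi * lC_mm[ri]))
  })

  # roles
  clamped <- met$clamped
  external <- met$external & !met$gas & !clamped
  gas <- met$gas & !clamped
  internal <- !clamped & !external & !gas

  pools <- c(doc$moieties$pools, doc$moieties$quinones)
  is_quinone <- c(rep(FALSE, length(doc$moieties$pools)),
                  rep(TRUE, length(doc$moieties$quinones)))
  base_idx <- vapply(pools, function(p) match(p$base, met_ids), integer(1))
  pool_members <- lapply(pools, function(p) match(p$members, met_ids))

  env <- doc$chemostat
  if (is.null(env)) env <- chemostat_env(D = 1e-9)
  # oxygen supply from the aerobiosis scale
  o2_id <- env$o2_id
  if (!is.null(o2_id) && !is.na(o2_id)) {
    if (!is.null(k_in_o2)) {
      env$k_in[o2_id] <- k_in_o2
      if (!is.na(env$k_in_o2_100) && env$k_in_o2_100 > 0)
        aerobiosis <- 100 * k_in_o2 / env$k_in_o2_100
    } else if (aerobiosis > 0) {
      if (is.na(env$k_in_o2_100))
        stop("aerobiosis > 0 requires a calibrated k_in_o2_100 (see ",
             "calibrate_aerobiosis()) or an explicit k_in_o2", call. = FALSE)
      env$k_in[o2_id] <- aerobiosis / 100 * env$k_in_o2_100
    } else env$k_in[o2_id] <- 0
  }

  # biomass / maintenance
  bio <- doc$biomass
  B <- numeric(n_m)                     # per unit mu, mmol/gDCW
  if (!is.null(bio)) {
    for (n in names(bio$stoich$nu)) B[match(n, met_ids)] <-
        B[match(n, met_ids)] - bio$stoich$nu[[n]]
    for (n in names(bio$stoich$byproducts)) B[match(n, met_ids)] <-
        B[match(n, met_ids)] + bio$stoich$byproducts[[n]]
  }
  Mvec <- numeric(n_m)                  # per unit maintenance rate
  if (!is.null(bio) && bio$maintenance$m_max > 0) {
    Mvec[match("atp", met_ids)] <- -1
    Mvec[match("adp", met_ids)] <- 1
  }

  # variable layout
  vL <- which(!clamped)
  L_fix <- numeric(n_m)
  L_fix[clamped] <- lC_mm[clamped] + log(met$xi_clamped[clamped])
  solve_cX <- !is.null(bio) && is.null(c_X_fixed)
  cX_val <- if (is.null(c_X_fixed)) 1 else c_X_fixed

  # row layout: internal balances (non-base), pool totals, QE constraints,
  # external, gas, biomass
  bal_rows <- setdiff(which(internal), base_idx)
  ext_rows <- which(external)
  gas_rows <- which(gas)

  n_x <- length(vL) + length(qe_ids) + as.integer(solve_cX)
  idxL <- seq_along(vL)
  idxQ <- length(vL) + seq_along(qe_ids)
  idxX <- if (solve_cX) n_x else NA_integer_

  sig_exprs <- lapply(doc$tfs, function(tf) str2lang(tf$signal))
  qtot_at <- function(aer) {
    tq <- if (length(doc$moieties$quinones) > 0)
      quinone_totals(aer, moiety_policy(quinones = doc$moieties$quinones))
    else numeric(0)
    totals <- vapply(pools, function(p) if (is.null(p$total)) NA_real_ else p$total,
                     numeric(1))
    totals[is_quinone] <- tq
    totals
  }
  totals <- qtot_at(aerobiosis)

  pfx <- function(p, v) if (length(v) == 0) character(0) else paste0(p, v)
  row_names <- c(pfx("bal.", met_ids[bal_rows]),
                 pfx("pool.", vapply(pools, `[[`, "", "name")),
                 pfx("qe.", qe_ids),
                 pfx("ext.", met_ids[ext_rows]),
                 pfx("gas.", met_ids[gas_rows]),
                 if (solve_cX) "growth")
  var_names <- c(pfx("L.", met_ids[vL]), pfx("J.", qe_ids),
                 if (solve_cX) "c_X")

  sys <- list(
    doc = doc, env = env, aerobiosis = aerobiosis, ramp_eps = ramp_eps,
    met_ids = met_ids, lC_mm = lC_mm, S = S, kin = kin, qe_ids = qe_ids,
    qe_info = qe_info, pools = pools, totals = totals, base_idx = base_idx,
    pool_members = pool_members, B = B, Mvec = Mvec, bio = bio,
    clamped = clamped, internal = internal, vL = vL, L_fix = L_fix,
    bal_rows = bal_rows, ext_rows = ext_rows, gas_rows = gas_rows,
    solve_cX = solve_cX, cX_val = cX_val, idxL = idxL, idxQ = idxQ,
    idxX = idxX, n_x = n_x, sig_exprs = sig_exprs,
    row_names = row_names, var_names = var_names,
    drains = names(doc$drains), call_args = call_args)
  class(sys) <- "tk_system"
  sys
}

#' @export
print.tk_system <- function(x, ...) {
  cat(sprintf(
    "<tk_system> %d unknowns (%d log-concentrations, %d QE fluxes%s), aerobiosis = %.4g%%\n",
    x$n_x, length(x$vL), length(x$qe_ids),
    if (x$solve_cX) ", biomass" else "", x$aerobiosis))
  invisible(x)
}

# Evaluate model quantities at a state vector. Returns fluxes, growth rate,
# enzyme levels, TF activities and the residual (in natural units).
tk_eval <- function(sys, x) {
  n_m <- length(sys$met_ids)
  L <- sys$L_fix
  L[sys$vL] <- x[sys$idxL]
  cmm <- exp(L)
  names(cmm) <- sys$met_ids
  env <- sys$env
  D <- env$D

  # TF activities and enzyme levels
  a_TF <- numeric(0)
  if (length(sys$sig_exprs) > 0) {
    cenv <- as.list(cmm)
    a_TF <- vapply(seq_along(sys$sig_exprs), function(k) {
      sig <- eval(sys$sig_exprs[[k]], envir = cenv)
      if (!is.finite(sig) || sig <= 0) sig <- 1e-300
      tf_activity(min(sig, 1e300), sys$doc$tfs[[k]])
    }, numeric(1))
    names(a_TF) <- names(sys$doc$tfs)
  }
  c_E <- numeric(0)
  if (length(sys$doc$genes) > 0) {
    c_E <- vapply(sys$doc$genes, function(g)
      synthesis_rate(g, a_TF) / D, numeric(1))
    names(c_E) <- names(sys$doc$genes)
  }

  # fluxes
  J <- numeric(ncol(sys$S)); names(J) <- colnames(sys$S)
  for (k in sys$kin) {
    tr <- exp(k$a_r + sum(k$wi * L[k$ri]))
    tp <- exp(k$a_p + sum(k$wp * L[k$pi]))
    cE <- if (is.null(k$enzyme)) 1 else c_E[[k$enzyme]]
    Jj <- cE * (tr - tp)
    for (m in k$mods) {
      term <- 1 + exp(L[m$i] - m$l_theta)   # 1 + xi/theta
      Jj <- if (m$type == "activator") Jj * term else Jj / term
    }
    J[k$id] <- Jj
  }
  if (length(sys$qe_ids) > 0) J[sys$qe_ids] <- x[sys$idxQ]
  for (d in sys$drains) J[d] <- sys$doc$drains[[d]]$J_fixed

  # growth and maintenance
  mu <- 0; maint <- 0; ratio <- NA_real_
  if (!is.null(sys$bio)) {
    ratio <- if (all(c("atp", "adp") %in% names(cmm)))
      cmm[["atp"]] / cmm[["adp"]] else sys$bio$growth$k_hi
    if (!is.finite(ratio)) ratio <- sys$bio$growth$k_hi
    # floor against exp() underflow during wild solver excursions; the
    # linlog then returns 0 growth, the continuous extension
    mu <- growth_rate(pmax(cmm, 1e-300), ratio, sys$bio$stoich,
                      sys$bio$growth, eps = sys$ramp_eps)
    mn <- sys$bio$maintenance
    if (mn$m_max > 0)
      maint <- maintenance_rate(ratio, mn$m_max, mn$m_lo, mn$m_hi,
                                eps = sys$ramp_eps)
  }
  cX <- if (sys$solve_cX) x[sys$idxX] else sys$cX_val

  Tn <- drop(sys$S %*% J) + mu * sys$B + maint * sys$Mvec  # mmol/gDCW/h

  r <- numeric(length(sys$row_names))
  k <- 0L
  for (i in sys$bal_rows) {
    k <- k + 1L
    r[k] <- Tn[i] - env$v_cell * mu * cmm[i]
  }
  for (p in seq_along(sys$pools)) {
    k <- k + 1L
    r[k] <- sum(cmm[sys$pool_members[[p]]]) / sys$totals[p] - 1
  }
  for (q in seq_along(sys$qe_info)) {
    k <- k + 1L
    qi <- sys$qe_info[[q]]
    r[k] <- sum(qi$wi * L[qi$ri]) - sum(qi$wp * L[qi$pi]) + qi$const
  }
  for (i in sys$ext_rows) {
    k <- k + 1L
    id <- sys$met_ids[i]
    cin <- if (id %in% names(env$c_in)) env$c_in[[id]] else 0
    r[k] <- Tn[i] * cX + D * (cin - cmm[i])
  }
  for (i in sys$gas_rows) {
    k <- k + 1L
    id <- sys$met_ids[i]
    kin_i <- if (id %in% names(env$k_in)) env$k_in[[id]] else 0
    kout_i <- env$k_out[[id]]
    r[k] <- Tn[i] * cX + kin_i - kout_i * cmm[i]
  }
  if (sys$solve_cX) {
    k <- k + 1L
    r[k] <- mu - D
  }
  names(r) <- sys$row_names

  list(residual = r, J = J, mu = mu, maint = maint, c = cmm, L = L,
       c_E = c_E, a_TF = a_TF, c_X = cX, ratio = ratio)
}

#' Default initial state for a steady-state solve
#'
#' Heuristic starting point: 1 mmol/l for internal metabolites, conserved
#' pools distributed with an energized bias (high ATP/NADPH/CoA), inflow
#' levels for extracellular species and supply/outgassing balance for gas
#' species; a `[start]` section in the model overrides all of it. Used by
#' [solve_steady_state()] when no guess is given.
#'
#' @param sys a `tk_system` from [assemble()].
#' @return Numeric state vector in the system's variable layout.
#' @export
tk_default_guess <- function(sys) {
  cmm <- rep(1, length(sys$met_ids))            # 1 mmol/l
  names(cmm) <- sys$met_ids
  # distribute conserved pools over members; start the culture energized
  # (high ATP, moderately reduced NAD pool) so Newton homes in on the live
  # branch rather than the ATP-depleted one
  for (p in seq_along(sys$pools)) {
    mem <- sys$pool_members[[p]]
    w <- rep(1, length(mem))
    ids <- sys$met_ids[mem]
    w[ids %in% c("atp", "nadph", "coa")] <- 3
    w[ids %in% c("amp", "succoa")] <- 0.3
    cmm[mem] <- sys$totals[p] * w / sum(w)
  }
  env <- sys$env
  for (i in sys$ext_rows) {
    id <- sys$met_ids[i]
    cin <- if (id %in% names(env$c_in)) env$c_in[[id]] else 0
    cmm[i] <- max(cin, 1e-3)
  }
  for (i in sys$gas_rows) {
    id <- sys$met_ids[i]
    kin_i <- if (id %in% names(env$k_in)) env$k_in[[id]] else 0
    cmm[i] <- max(kin_i / env$k_out[[id]], 1e-6)
  }
  # a [start] section in the model overrides the heuristics
  cX0 <- 0.5
  if (length(sys$doc$start) > 0) {
    for (n in names(sys$doc$start)) {
      if (n == "c_X") cX0 <- sys$doc$start[[n]]
      else {
        i <- match(n, sys$met_ids)
        if (!is.na(i)) cmm[i] <- sys$doc$start[[n]]
      }
    }
  }
  x <- numeric(sys$n_x)
  x[sys$idxL] <- log(cmm[sys$vL])
  if (length(sys$qe_ids) > 0) x[sys$idxQ] <- 0
  if (sys$solve_cX) x[sys$idxX] <- cX0
  names(x) <- sys$var_names
  x
}
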