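## The .tkm model-definition format
##
## Sectioned, line-oriented plain text:
##   [section]                      section header
##   key = value                    scalar entry
##   id: body                       record entry (metabolite, reaction, ...)
## Reaction bodies are stoichiometry strings ("a + 2 b -> c") optionally
## followed by "| key = value, ..." attributes. "<->"/"->" mark a
## finite-resistance reaction, "=" a quasi-equilibrium (zero-resistance)
## reaction. Comments start with "#"; a leading comment block is preserved
## as the document's provenance header.

tkm_err <- function(line_no, msg) {
  stop(sprintf("tkm parse error (line %d): %s", line_no, msg), call. = FALSE)
}

#' Parse a stoichiometry string
#'
#' Grammar: `term (+ term)* ARROW term (+ term)*` with `term = [coef] id`
#' and `ARROW` one of `->`, `<->`, `=`. Reactants get negative signs.
#'
#' @param s stoichiometry string.
#' @param allow_noninteger allow non-integer coefficients (biomass / drain
#'   context only).
#' @param allow_empty_side allow an empty product (pure drain, "a ->").
#' @return List with `stoich` (named numeric) and `arrow` (character).
#' @examples
#' parse_stoich("a + 2 b -> c")$stoich
#' @export
parse_stoich <- function(s, allow_noninteger = FALSE, allow_empty_side = FALSE) {
  arrow <- if (grepl("<->", s, fixed = TRUE)) "<->"
    else if (grepl("->", s, fixed = TRUE)) "->"
    else if (grepl("=", s, fixed = TRUE)) "="
    else stop("no reaction arrow ('->', '<->' or '=') in: ", s, call. = FALSE)
  sides <- strsplit(s, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1) sides <- c(sides, "")
  if (length(sides) != 2) stop("malformed stoichiometry: ", s, call. = FALSE)
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (grepl("^\\+|\\+\\s*$|\\+\\s*\\+", txt))
      stop("malformed stoichiometry (dangling '+') in: ", s, call. = FALSE)
    if (txt == "") {
      if (!allow_empty_side)
        stop("empty reaction side in: ", s, call. = FALSE)
      return(numeric(0))
    }
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (t in terms) {
      m <- regmatches(t, regexec(
        "^([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?\\s+)?([A-Za-z_][A-Za-z0-9_]*)$", t))[[1]]
      if (length(m) == 0)
        stop("malformed stoichiometry term '", t, "' in: ", s, call. = FALSE)
      coef <- if (nzchar(trimws(m[2]))) as.numeric(m[2]) else 1
      if (!allow_noninteger && abs(coef - round(coef)) > 1e-9)
        stop("non-integer stoichiometric coefficient '", t,
             "' (allowed in biomass/drain reactions only)", call. = FALSE)
      id <- m[3]
      out[id] <- (if (is.na(out[id])) 0 else out[id]) + sign * coef
      if (is.na(out[id])) out[id] <- sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- c(lhs, rhs)
  # merge ids appearing on both sides
  st <- tapply(st, names(st), sum)
  st <- st[st != 0]
  out <- as.numeric(st); names(out) <- names(st)
  if (length(out) == 0 && !allow_empty_side)
    stop("stoichiometry is empty after cancellation: ", s, call. = FALSE)
  list(stoich = out, arrow = arrow)
}

format_stoich <- function(stoich, arrow = "<->") {
  fmt_side <- function(v) {
    if (length(v) == 0) return("")
    paste(vapply(names(v), function(n) {
      cf <- abs(v[[n]])
      if (abs(cf - 1) < 1e-12) n
      else paste(format(cf, digits = 12, scientific = FALSE), n)
    }, character(1)), collapse = " + ")
  }
  r <- stoich[stoich < 0]; p <- stoich[stoich > 0]
  paste(fmt_side(r), arrow, fmt_side(p))
}

# split "k = v, k = v, flag" attribute lists (no nested commas in values)
parse_attrs <- function(txt, line_no) {
  out <- list(flags = character(0))
  if (is.na(txt) || !nzchar(trimws(txt))) return(out)
  parts <- trimws(strsplit(txt, ",", fixed = TRUE)[[1]])
  for (p in parts) {
    if (!nzchar(p)) next
    if (grepl("=", p, fixed = TRUE)) {
      kv <- trimws(strsplit(p, "=", fixed = TRUE)[[1]])
      if (length(kv) != 2 || !nzchar(kv[1]))
        tkm_err(line_no, paste0("malformed attribute '", p, "'"))
      out[[kv[1]]] <- kv[2]
    } else {
      out$flags <- c(out$flags, p)
    }
  }
  out
}

num_attr <- function(attrs, key, line_no, default = NULL, integer = FALSE) {
  if (is.null(attrs[[key]])) {
    if (is.null(default))
      tkm_err(line_no, paste0("missing required attribute '", key, "'"))
    return(default)
  }
  v <- suppressWarnings(as.numeric(attrs[[key]]))
  if (is.na(v)) tkm_err(line_no, paste0("attribute '", key, "' is not numeric"))
  if (integer && abs(v - round(v)) > 1e-9)
    tkm_err(line_no, paste0("attribute '", key, "' must be an integer"))
  v
}

#' Read a model-definition file
#'
#' @param path path to a `.tkm` file.
#' @return A validated `tkm_model`, see [parse_model()].
#' @export
read_tkm <- function(path) {
  parse_model(readLines(path, warn = FALSE))
}

#' Parse model-definition text
#'
#' Parses the sectioned plain-text model format into a `tkm_model`: thermo
#' context, compartments, metabolites, reactions, transcription factors,
#' genes, biomass stoichiometry and growth/maintenance kinetics, conserved
#' moieties and quinone pools, chemostat settings and enforced drains. The
#' document is cross-validated (see [validate_model()]) before it is
#' returned; parse errors name the offending line.
#'
#' @param text character vector of lines (or a single string with newlines).
#' @return An object of class `tkm_model`.
#' @export
parse_model <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text <- unname(text)
  doc <- list(
    header = character(0),
    context = NULL,
    compartments = tibble::tibble(name = character(0), phi = numeric(0)),
    metabolites = tibble::tibble(
      id = character(0), dfg0 = numeric(0), z = integer(0),
      compartment = character(0), carbon = numeric(0),
      external = logical(0), gas = logical(0), clamped = logical(0),
      xi_clamped = numeric(0)),
    reactions = list(), tfs = list(), genes = list(),
    biomass = NULL, moieties = moiety_policy(), chemostat = NULL,
    drains = list(), start = list()
  )
  ctx_kv <- list(); chem_kv <- list(); bio_kv <- list(); start_kv <- list()
  pools <- list(); quinones <- list(); dead_pool <- 0
  section <- NULL
  in_preamble <- TRUE

  for (i in seq_along(text)) {
    raw <- text[i]
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (!nzchar(line)) {
      if (in_preamble && grepl("^\\s*#", raw))
        doc$header <- c(doc$header, sub("^\\s*#\\s?", "", raw))
      next
    }
    in_preamble <- FALSE
    if (grepl("^\\[.*\\]$", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      known <- c("context", "compartments", "metabolites", "reactions",
                 "transcription_factors", "genes", "biomass", "moieties",
                 "chemostat", "drains", "start")
      if (!section %in% known) tkm_err(i, paste0("unknown section '", section, "'"))
      next
    }
    if (is.null(section)) tkm_err(i, "entry before any [section] header")

    if (section == "context") {
      kv <- parse_attrs(line, i)
      ctx_kv <- utils::modifyList(ctx_kv, kv[setdiff(names(kv), "flags")])
    } else if (section == "compartments") {
      m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) == 0) tkm_err(i, "expected 'name: phi = <value>'")
      attrs <- parse_attrs(m[3], i)
      doc$compartments <- dplyr::bind_rows(
        doc$compartments,
        tibble::tibble(name = m[2], phi = num_attr(attrs, "phi", i)))
    } else if (section == "metabolites") {
      m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) == 0) tkm_err(i, "expected 'id: attributes'")
      attrs <- parse_attrs(m[3], i)
      doc$metabolites <- dplyr::bind_rows(doc$metabolites, tibble::tibble(
        id = m[2],
        dfg0 = num_attr(attrs, "dfg0", i) * 1000, # file: kJ/mol -> J/mol
        z = as.integer(num_attr(attrs, "z", i, default = 0, integer = TRUE)),
        compartment = if (!is.null(attrs$compartment)) attrs$compartment else "c",
        carbon = num_attr(attrs, "carbon", i, default = 0),
        external = "external" %in% attrs$flags,
        gas = "gas" %in% attrs$flags,
        clamped = "clamped" %in% attrs$flags,
        xi_clamped = num_attr(attrs, "xi", i, default = 1)))
    } else if (section %in% c("reactions", "drains")) {
      m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*([^|]*)(\\|(.*))?$", line))[[1]]
      if (length(m) == 0) tkm_err(i, "expected 'ID: stoichiometry [| attributes]'")
      id <- m[2]
      attrs <- parse_attrs(if (length(m) >= 5) m[5] else NA, i)
      st <- tryCatch(
        parse_stoich(m[3], allow_noninteger = section == "drains",
                     allow_empty_side = section == "drains"),
        error = function(e) tkm_err(i, conditionMessage(e)))
      if (section == "drains") {
        doc$drains[[id]] <- reaction(id, st$stoich, kind = "drain",
                                     J_fixed = num_attr(attrs, "J", i, default = 0))
      } else if (st$arrow == "=") {
        doc$reactions[[id]] <- reaction(id, st$stoich, kind = "qe")
      } else {
        mods <- list()
        for (key in c("activator", "inhibitor")) {
          if (!is.null(attrs[[key]])) {
            # "adp @ 0.5": modifier metabolite and threshold theta
            am <- regmatches(attrs[[key]],
                             regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*@\\s*([0-9.eE+-]+)$",
                                     attrs[[key]]))[[1]]
            if (length(am) == 0)
              tkm_err(i, paste0("malformed ", key, " spec '", attrs[[key]], "'"))
            mods <- c(mods, list(list(metabolite = am[2], type = key,
                                      theta = as.numeric(am[3]))))
          }
        }
        doc$reactions[[id]] <- reaction(
          id, st$stoich, kind = if (length(mods) > 0) "regulated" else "finite",
          log10_k_plus = num_attr(attrs, "k", i, integer = TRUE),
          modifiers = mods,
          enzyme = if (!is.null(attrs$enzyme)) attrs$enzyme else NULL)
      }
    } else if (section == "transcription_factors") {
      m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) == 0) tkm_err(i, "expected 'id: attributes'")
      attrs <- parse_attrs(m[3], i)
      sig <- attrs$signal
      if (is.null(sig)) tkm_err(i, "transcription factor needs a signal expression")
      sig <- gsub('^"|"$', "", sig)
      doc$tfs[[m[2]]] <- transcription_factor(
        m[2], sig, k_half = num_attr(attrs, "k_half", i),
        hill_n = num_attr(attrs, "n", i))
    } else if (section == "genes") {
      m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
      if (length(m) == 0) tkm_err(i, "expected 'id: attributes'")
      attrs <- parse_attrs(m[3], i)
      regs <- list()
      if (!is.null(attrs$reg)) {
        for (r in trimws(strsplit(attrs$reg, ";", fixed = TRUE)[[1]])) {
          rm <- regmatches(r, regexec(
            "^([A-Za-z_][A-Za-z0-9_]*)\\s*([+-])\\s*([0-9.]+)$", r))[[1]]
          if (length(rm) == 0)
            tkm_err(i, paste0("malformed regulator spec '", r,
                              "' (want 'tf +k' or 'tf -k')"))
          k <- as.numeric(rm[4])
          if (abs(k - round(k)) > 1e-9)
            tkm_err(i, "regulation strength must take integer values")
          regs <- c(regs, list(list(
            tf = rm[2],
            mode = if (rm[3] == "+") "activator" else "inhibitor",
            strength = as.integer(round(k)))))
        }
      }
      doc$genes[[m[2]]] <- gene(m[2], basal_rate = num_attr(attrs, "basal", i),
                                regulators = regs)
    } else if (section == "biomass") {
      kv <- parse_attrs(line, i)
      bio_kv <- utils::modifyList(bio_kv, kv[setdiff(names(kv), "flags")])
    } else if (section == "moieties") {
      if (grepl("^dead_pool_ox", line)) {
        kv <- parse_attrs(line, i)
        dead_pool <- num_attr(kv, "dead_pool_ox", i)
      } else {
        m <- regmatches(line, regexec(
          "^(pool|quinone)\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", line))[[1]]
        if (length(m) == 0)
          tkm_err(i, "expected 'pool NAME: ...', 'quinone NAME: ...' or 'dead_pool_ox = ...'")
        attrs <- parse_attrs(m[4], i)
        if (is.null(attrs$members)) tkm_err(i, "pool needs members")
        members <- strsplit(trimws(attrs$members), "\\s+")[[1]]
        base <- if (!is.null(attrs$base)) attrs$base else members[1]
        if (m[2] == "pool") {
          pools[[m[3]]] <- list(name = m[3], members = members, base = base,
                                total = num_attr(attrs, "total", i))
        } else {
          quinones[[m[3]]] <- list(name = m[3], members = members, base = base,
                                   intercept = num_attr(attrs, "intercept", i),
                                   slope = num_attr(attrs, "slope", i))
        }
      }
    } else if (section == "chemostat") {
      kv <- parse_attrs(line, i)
      chem_kv <- utils::modifyList(chem_kv, kv[setdiff(names(kv), "flags")])
    } else if (section == "start") {
      # optional solver starting point: reference concentrations (mmol/l)
      # and biomass for the packaged operating point
      kv <- parse_attrs(line, i)
      start_kv <- utils::modifyList(start_kv, kv[setdiff(names(kv), "flags")])
    }
  }
  if (length(start_kv) > 0)
    doc$start <- lapply(start_kv, as.numeric)

  num_or <- function(lst, key, default) {
    if (is.null(lst[[key]])) default else as.numeric(lst[[key]])
  }
  doc$context <- thermo_context(
    T = num_or(ctx_kv, "T", 310.15), p = num_or(ctx_kv, "p", 101325),
    pH = num_or(ctx_kv, "pH", 7), I = num_or(ctx_kv, "I", 0.25),
    a_h2o = num_or(ctx_kv, "a_h2o", 1), c_ref = num_or(ctx_kv, "c_ref", 1))

  if (length(bio_kv) > 0) {
    nu_keys <- grep("^nu\\.", names(bio_kv), value = TRUE)
    nu <- vapply(bio_kv[nu_keys], as.numeric, numeric(1))
    names(nu) <- sub("^nu\\.", "", nu_keys)
    carbon <- NULL
    if (nrow(doc$metabolites) > 0) {
      carbon <- doc$metabolites$carbon
      names(carbon) <- doc$metabolites$id
    }
    doc$biomass <- list(
      stoich = biomass_stoichiometry(
        nu, x_carbon = num_or(bio_kv, "x_carbon", 40), carbon = carbon),
      growth = growth_params(
        k_a = num_or(bio_kv, "k_a", 1), k_b = num_or(bio_kv, "k_b", 0),
        k_lo = num_or(bio_kv, "k_lo", 1), k_hi = num_or(bio_kv, "k_hi", 3)),
      maintenance = list(
        m_max = num_or(bio_kv, "m_max", 0),
        m_lo = num_or(bio_kv, "m_lo", 0.5),
        m_hi = num_or(bio_kv, "m_hi", 2)))
  }
  doc$moieties <- moiety_policy(pools, quinones, dead_pool)

  if (length(chem_kv) > 0) {
    pick_map <- function(prefix) {
      keys <- grep(paste0("^", prefix, "\\."), names(chem_kv), value = TRUE)
      v <- vapply(chem_kv[keys], as.numeric, numeric(1))
      names(v) <- sub(paste0("^", prefix, "\\."), "", keys)
      v
    }
    doc$chemostat <- chemostat_env(
      D = num_or(chem_kv, "D", 0.2),
      c_in = pick_map("c_in"), k_in = pick_map("k_in"),
      k_out = pick_map("k_out"),
      v_cell = num_or(chem_kv, "v_cell", 0.002))
    doc$chemostat$k_in_o2_100 <- if (is.null(chem_kv$k_in_o2_100)) NA_real_
      else as.numeric(chem_kv$k_in_o2_100)
    doc$chemostat$o2_id <- if (is.null(chem_kv$o2_id)) NA_character_
      else chem_kv$o2_id
  }

  doc <- structure(doc, class = "tkm_model")
  validate_model(doc)
  doc
}

#' @export
print.tkm_model <- function(x, ...) {
  cat(sprintf(
    "<tkm_model> %d metabolites, %d reactions (%d quasi-equilibrium), %d TFs, %d genes, %d drains\n",
    nrow(x$metabolites), length(x$reactions),
    sum(vapply(x$reactions, function(r) r$kind == "qe", logical(1))),
    length(x$tfs), length(x$genes), length(x$drains)))
  invisible(x)
}

#' Validate a model document
#'
#' Checks cross-references (every id used anywhere is defined, no duplicate
#' ids), structural constraints (every metabolite belongs to a declared
#' compartment, conserved-pool members exist) and that the quasi-equilibrium
#' constraints are structurally independent (no over-determining cycle).
#'
#' @param doc a `tkm_model`.
#' @return `doc`, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(doc) {
  met <- doc$metabolites
  if (anyDuplicated(met$id))
    stop("duplicate metabolite id: ", met$id[duplicated(met$id)][1], call. = FALSE)
  if (anyDuplicated(doc$compartments$name))
    stop("duplicate compartment", call. = FALSE)
  bad <- setdiff(met$compartment, doc$compartments$name)
  if (length(bad) > 0 && nrow(doc$compartments) > 0)
    stop("undefined compartment '", bad[1], "'", call. = FALSE)
  ids <- met$id
  all_rxns <- c(doc$reactions, doc$drains)
  if (anyDuplicated(names(all_rxns)))
    stop("duplicate reaction id: ",
         names(all_rxns)[duplicated(names(all_rxns))][1], call. = FALSE)
  for (r in all_rxns) {
    bad <- setdiff(names(r$stoich), ids)
    if (length(bad) > 0)
      stop("reaction '", r$id, "' references unknown metabolite '", bad[1], "'",
           call. = FALSE)
    if (!is.null(r$enzyme) && !r$enzyme %in% names(doc$genes))
      stop("reaction '", r$id, "' references unknown gene '", r$enzyme, "'",
           call. = FALSE)
    for (m in r$modifiers)
      if (!m$metabolite %in% ids)
        stop("reaction '", r$id, "' modifier references unknown metabolite '",
             m$metabolite, "'", call. = FALSE)
  }
  for (g in doc$genes) for (r in g$regulators)
    if (!r$tf %in% names(doc$tfs))
      stop("gene '", g$id, "' references unknown transcription factor '",
           r$tf, "'", call. = FALSE)
  for (tf in doc$tfs) {
    vars <- all.vars(str2lang(tf$signal))
    bad <- setdiff(vars, ids)
    if (length(bad) > 0)
      stop("transcription factor '", tf$id, "' signal references unknown ",
           "metabolite '", bad[1], "'", call. = FALSE)
  }
  for (p in c(doc$moieties$pools, doc$moieties$quinones)) {
    bad <- setdiff(p$members, ids)
    if (length(bad) > 0)
      stop("moiety pool '", p$name, "' references unknown metabolite '",
           bad[1], "'", call. = FALSE)
  }
  if (!is.null(doc$biomass)) {
    bad <- setdiff(c(names(doc$biomass$stoich$nu),
                     names(doc$biomass$stoich$byproducts)), ids)
    if (length(bad) > 0)
      stop("biomass stoichiometry references unknown metabolite '", bad[1],
           "'", call. = FALSE)
  }
  bad <- setdiff(names(doc$start), c(ids, "c_X"))
  if (length(bad) > 0)
    stop("[start] references unknown metabolite '", bad[1], "'", call. = FALSE)
  # structural independence of the quasi-equilibrium constraints
  qe <- Filter(function(r) r$kind == "qe", doc$reactions)
  if (length(qe) > 1) {
    S <- matrix(0, nrow = length(ids), ncol = length(qe),
                dimnames = list(ids, names(qe)))
    for (j in seq_along(qe)) S[names(qe[[j]]$stoich), j] <- qe[[j]]$stoich
    if (qr(S)$rank < length(qe))
      stop("quasi-equilibrium reactions are structurally dependent (cycle ",
           "over-determines the reduced system): ",
           paste(names(qe), collapse = ", "), call. = FALSE)
  }
  invisible(doc)
}

#' Serialize a model document
#'
#' Deterministic inverse of [parse_model()]: `parse_model(serialize_model(doc))`
#' reproduces the document (stable ordering, provenance header preserved).
#'
#' @param doc a `tkm_model`.
#' @return Character vector of lines.
#' @export
serialize_model <- function(doc) {
  out <- character(0)
  push <- function(...) out <<- c(out, ...)
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (length(doc$header) > 0) push(paste("#", doc$header), "")
  ctx <- doc$context
  push("[context]",
       paste0("T = ", num(ctx$T)), paste0("p = ", num(ctx$p)),
       paste0("pH = ", num(ctx$pH)), paste0("I = ", num(ctx$I)),
       paste0("a_h2o = ", num(ctx$a_h2o)), paste0("c_ref = ", num(ctx$c_ref)), "")
  if (nrow(doc$compartments) > 0) {
    push("[compartments]")
    for (k in seq_len(nrow(doc$compartments)))
      push(sprintf("%s: phi = %s", doc$compartments$name[k],
                   num(doc$compartments$phi[k])))
    push("")
  }
  if (nrow(doc$metabolites) > 0) {
    push("[metabolites]")
    for (k in seq_len(nrow(doc$metabolites))) {
      m <- doc$metabolites[k, ]
      s <- sprintf("%s: dfg0 = %s, z = %d, compartment = %s",
                   m$id, num(m$dfg0 / 1000), m$z, m$compartment)
      if (m$carbon != 0) s <- paste0(s, ", carbon = ", num(m$carbon))
      if (m$clamped && m$xi_clamped != 1) s <- paste0(s, ", xi = ", num(m$xi_clamped))
      if (m$external) s <- paste0(s, ", external")
      if (m$gas) s <- paste0(s, ", gas")
      if (m$clamped) s <- paste0(s, ", clamped")
      push(s)
    }
    push("")
  }
  if (length(doc$reactions) > 0) {
    push("[reactions]")
    for (r in doc$reactions) {
      if (r$kind == "qe") {
        push(sprintf("%s: %s", r$id, format_stoich(r$stoich, "=")))
      } else {
        s <- sprintf("%s: %s | k = %d", r$id, format_stoich(r$stoich, "<->"),
                     r$log10_k_plus)
        if (!is.null(r$enzyme)) s <- paste0(s, ", enzyme = ", r$enzyme)
        for (m in r$modifiers)
          s <- paste0(s, sprintf(", %s = %s @ %s", m$type, m$metabolite,
                                 num(m$theta)))
        push(s)
      }
    }
    push("")
  }
  if (length(doc$tfs) > 0) {
    push("[transcription_factors]")
    for (tf in doc$tfs)
      push(sprintf('%s: signal = "%s", k_half = %s, n = %s',
                   tf$id, tf$signal, num(tf$k_half), num(tf$hill_n)))
    push("")
  }
  if (length(doc$genes) > 0) {
    push("[genes]")
    for (g in doc$genes) {
      s <- sprintf("%s: basal = %s", g$id, num(g$basal_rate))
      if (length(g$regulators) > 0)
        s <- paste0(s, ", reg = ", paste(vapply(g$regulators, function(r)
          sprintf("%s %s%d", r$tf, if (r$mode == "activator") "+" else "-",
                  r$strength), character(1)), collapse = "; "))
      push(s)
    }
    push("")
  }
  if (!is.null(doc$biomass)) {
    b <- doc$biomass
    push("[biomass]",
         paste0("x_carbon = ", num(b$stoich$x_carbon)),
         paste0("k_a = ", num(b$growth$k_a)), paste0("k_b = ", num(b$growth$k_b)),
         paste0("k_lo = ", num(b$growth$k_lo)), paste0("k_hi = ", num(b$growth$k_hi)),
         paste0("m_max = ", num(b$maintenance$m_max)),
         paste0("m_lo = ", num(b$maintenance$m_lo)),
         paste0("m_hi = ", num(b$maintenance$m_hi)))
    for (n in names(b$stoich$nu))
      push(sprintf("nu.%s = %s", n, num(b$stoich$nu[[n]])))
    push("")
  }
  if (length(doc$moieties$pools) + length(doc$moieties$quinones) > 0 ||
      doc$moieties$dead_pool_ox != 0) {
    push("[moieties]")
    for (p in doc$moieties$pools)
      push(sprintf("pool %s: members = %s, base = %s, total = %s",
                   p$name, paste(p$members, collapse = " "), p$base, num(p$total)))
    for (q in doc$moieties$quinones)
      push(sprintf("quinone %s: members = %s, base = %s, intercept = %s, slope = %s",
                   q$name, paste(q$members, collapse = " "), q$base,
                   num(q$intercept), num(q$slope)))
    if (doc$moieties$dead_pool_ox != 0)
      push(paste0("dead_pool_ox = ", num(doc$moieties$dead_pool_ox)))
    push("")
  }
  if (!is.null(doc$chemostat)) {
    ch <- doc$chemostat
    push("[chemostat]", paste0("D = ", num(ch$D)),
         paste0("v_cell = ", num(ch$v_cell)))
    for (n in names(ch$c_in)) push(sprintf("c_in.%s = %s", n, num(ch$c_in[[n]])))
    for (n in names(ch$k_in)) push(sprintf("k_in.%s = %s", n, num(ch$k_in[[n]])))
    for (n in names(ch$k_out)) push(sprintf("k_out.%s = %s", n, num(ch$k_out[[n]])))
    if (!is.na(ch$k_in_o2_100)) push(paste0("k_in_o2_100 = ", num(ch$k_in_o2_100)))
    if (!is.na(ch$o2_id)) push(paste0("o2_id = ", ch$o2_id))
    push("")
  }
  if (length(doc$start) > 0) {
    push("[start]")
    for (n in names(doc$start))
      push(sprintf("%s = %s", n, num(doc$start[[n]])))
    push("")
  }
  if (length(doc$drains) > 0) {
    push("[drains]")
    for (d in doc$drains)
      push(sprintf("%s: %s | J = %s", d$id, format_stoich(d$stoich, "->"),
                   format(d$J_fixed, digits = 15)))
    push("")
  }
  out
}

#' Write a model to a file
#' @param doc a `tkm_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tkm <- function(doc, path) {
  writeLines(serialize_model(doc), path)
  invisible(path)
}

#' Add an enforced production drain to a model
#'
#' Introduces the stoichiometric shadow of a production pathway: an
#' irreversible exchange reaction whose biomass-specific flux is clamped to
#' `J_prod` regardless of the thermokinetic state (enforced flux, not
#' kinetic). For example a pathway consuming two acetyl-CoA and four NADH is
#' written `"2 accoa + 4 nadh -> 2 coa + 4 nad"`; the product itself leaves
#' the balance.
#'
#' @param doc a `tkm_model`.
#' @param drain stoichiometry string (products optional).
#' @param J_prod enforced biomass-specific flux (mmol/gDCW/h, >= 0).
#' @param id drain reaction id.
#' @return The model with the drain added.
#' @export
add_drain_reaction <- function(doc, drain, J_prod = 0, id = "PROD") {
  if (J_prod < 0) stop("J_prod must be non-negative", call. = FALSE)
  st <- parse_stoich(drain, allow_noninteger = TRUE, allow_empty_side = TRUE)
  bad <- setdiff(names(st$stoich), doc$metabolites$id)
  if (length(bad) > 0)
    stop("drain references unknown metabolite '", bad[1], "'", call. = FALSE)
  doc$drains[[id]] <- reaction(id, st$stoich, kind = "drain", J_fixed = J_prod)
  validate_model(doc)
  doc
}
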