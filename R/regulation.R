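#' Define a transcription factor
#'
#' Transcription-factor activity is a phenomenological Hill function of a
#' metabolic signal x: a = x^n / (x^n + k^n). For n > 0 the factor is
#' activated by its signal, for n < 0 it is inhibited. The signal itself is
#' an arithmetic expression over metabolite concentrations (for example a
#' single concentration, or a ratio such as `pep / pyr`).
#'
#' @param id identifier.
#' @param signal signal expression as a string over metabolite ids; evaluated
#'   on concentrations by the solver.
#' @param k_half half-saturation constant in signal units (positive).
#' @param hill_n Hill exponent (nonzero; negative = inhibition).
#' @return An object of class `tk_tf`.
#' @examples
#' transcription_factor("fnr", "o2", k_half = 0.001, hill_n = -2)
#' transcription_factor("crp", "pep / pyr", k_half = 0.2, hill_n = 2)
#' @export
transcription_factor <- function(id, signal, k_half, hill_n) {
  if (k_half <= 0) stop("k_half must be positive for TF '", id, "'", call. = FALSE)
  if (hill_n == 0) stop("hill_n must be nonzero for TF '", id, "'", call. = FALSE)
  structure(list(id = id, signal = signal, k_half = k_half, hill_n = hill_n),
            class = "tk_tf")
}

#' Transcription-factor activity
#'
#' a = x^n / (x^n + k^n), strictly inside (0, 1), monotone in the signal
#' with the sign of n, and exactly 1/2 at x = k_half.
#'
#' @param x signal value (positive).
#' @param tf a [transcription_factor()].
#' @return Activity in (0, 1). Vectorised over `x`.
#' @examples
#' tf <- transcription_factor("t", "x", k_half = 2, hill_n = 2)
#' tf_activity(2, tf)  # 0.5
#' tf_activity(4, tf)  # 0.8
#' @export
tf_activity <- function(x, tf) {
  if (any(x <= 0)) stop("TF signal must be positive (log-scale signal)", call. = FALSE)
  # computed on the log scale for numeric stability at extreme signals
  t <- tf$hill_n * (log(x) - log(tf$k_half))
  1 / (1 + exp(-t))
}

#' Define a gene
#'
#' @param id identifier (also names the enzyme it encodes).
#' @param basal_rate maximal synthesis rate J_syn,max (concentration/h,
#'   positive); realised when all regulating factors are fully permissive.
#' @param regulators list of regulator terms, each
#'   `list(tf = , mode = "activator"|"inhibitor", strength = integer k)`.
#' @return An object of class `tk_gene`.
#' @export
gene <- function(id, basal_rate, regulators = list()) {
  if (basal_rate <= 0) stop("basal_rate must be positive for gene '", id, "'",
                            call. = FALSE)
  for (r in regulators) {
    if (abs(r$strength - round(r$strength)) > 1e-12)
      stop("regulation strength must be an integer for gene '", id, "'",
           call. = FALSE)
    if (!r$mode %in% c("activator", "inhibitor"))
      stop("regulator mode must be activator or inhibitor (gene '", id, "')",
           call. = FALSE)
  }
  regulators <- lapply(regulators, function(r) {
    r$strength <- as.integer(round(r$strength)); r
  })
  structure(list(id = id, basal_rate = basal_rate, regulators = regulators),
            class = "tk_gene")
}

#' Expression modifier of a single transcription factor
#'
#' s(k, a) = 2^-k + (1 - 2^-k) * a: one transcription factor can change the
#' expression of a gene by at most a factor of 2^k. s(k, 1) = 1 and
#' s(k, 0) = 2^-k.
#'
#' @param k integer regulation strength.
#' @param a activity in `[0, 1]` (for inhibitors pass 1 - a).
#' @return Modifier in `[2^-k, 1]` for k >= 0.
#' @examples
#' expression_modifier(3, 0)   # 1/8
#' expression_modifier(2, 0.5) # 0.625
#' @export
expression_modifier <- function(k, a) {
  if (any(a < 0 | a > 1)) stop("activity must lie in [0, 1]", call. = FALSE)
  2^-k + (1 - 2^-k) * a
}

#' Synthesis rate of a gene
#'
#' Multiplicative interaction of regulators:
#' J_syn = basal_rate * prod over regulators of s(k_r, a_r), where a_r is the
#' regulating factor's activity for activators and 1 - activity for
#' inhibitors.
#'
#' @param gene a [gene()].
#' @param activities named numeric vector of TF activities.
#' @return Synthesis rate (concentration/h).
#' @export
synthesis_rate <- function(gene, activities) {
  J <- gene$basal_rate
  for (r in gene$regulators) {
    a <- if (r$tf %in% names(activities)) activities[[r$tf]] else NULL
    if (is.null(a) || is.na(a))
      stop("gene '", gene$id, "': unknown transcription factor '", r$tf, "'",
           call. = FALSE)
    if (identical(r$mode, "inhibitor")) a <- 1 - a
    J <- J * expression_modifier(r$strength, a)
  }
  J
}

#' Right-hand side of the enzyme-concentration balance
#'
#' dc_E/dt = J_syn - mu * c_E: synthesis minus dilution by growth. At steady
#' state c_E = J_syn / mu.
#'
#' @param c_E enzyme concentration (non-negative).
#' @param J_syn synthesis rate (concentration/h).
#' @param mu specific growth rate (1/h, non-negative).
#' @return Time derivative of c_E (concentration/h).
#' @export
enzyme_rhs <- function(c_E, J_syn, mu) {
  if (any(c_E < 0)) stop("enzyme concentration must be non-negative", call. = FALSE)
  if (any(mu < 0)) stop("growth rate must be non-negative", call. = FALSE)
  J_syn - mu * c_E
}
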