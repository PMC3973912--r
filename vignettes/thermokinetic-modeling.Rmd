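---
title: "Thermokinetic modeling of steady-state metabolism and regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermokinetic modeling of steady-state metabolism and regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermokin)
```

## The modeling formalism

thermokin describes a metabolic network in thermokinetic variables. Each
metabolite $i$ carries a dimensionless *thermokinetic potential* $\xi_i$
related to its concentration by $c_i = C_i\,\xi_i$, where the
*thermokinetic capacity*

$$C_i = c^{\circ}\exp\!\big(-(\mu''^{\circ}_i + z_i F \phi_i)/(R T)\big)$$

is computed from the transformed standard Gibbs formation energy
$\mu''^{\circ}_i$ (J/mol, at fixed temperature, pH, water activity and
ionic strength), the charge number $z_i$ and the electrical potential
$\phi_i$ of the metabolite's compartment. The chemical potential of a
species is then simply $RT\ln\xi_i$ up to a common constant, so equal
potentials mean chemical equilibrium, and all equilibrium constants are
inherited from the formation energies. Because capacities are per-species
quantities, products of equilibrium constants around any stoichiometric
cycle are exactly one (Wegscheider consistency) by construction; the test
suite verifies this on the null space of the packaged network.

The flux of reaction $j$ with enzyme concentration $c_{E,j}$ obeys the
linear force/resistance law

$$\frac{R_j(\xi)}{c_{E,j}}\,J_j = F_j(\xi), \qquad
  F_j = \prod_{i \in \text{reactants}} \xi_i^{|\nu_{ij}|}
      - \prod_{i \in \text{products}} \xi_i^{\nu_{ij}},$$

so the flux always has the sign of the force: the model cannot violate
the second law, whatever its parameters. The resistance is tied to the
reactant capacities, $R_j = k_{+j}^{-1}\prod_{i\in E_j} C_i^{-|\nu_{ij}|}$,
and the forward constant is restricted to integer powers of ten,
$k_{+j} = 10^{x_j}$; this deliberately coarse parameterisation reflects
the view that orders of magnitude of the resistances determine most of
the behaviour. Enzymatic regulation enters as multiplicative saturation
terms on the resistance: an activator $m$ with threshold $\theta$
contributes $1/(1 + \xi_m/\theta)$, an inhibitor the reciprocal. The
packaged core model uses a single such term, the activation of
phosphofructokinase by ADP.

With constant resistances the law is algebraically identical to
reversible mass action with $k_f = c_E k_+ \prod_{E_j} C_i^{|\nu_{ij}|}$
and the equilibrium constant from the formation energies. The test suite
exploits this: the steady state of the packaged toy chain is checked
against brute-force time integration of independently assembled
mass-action kinetics.

## Regulation

Transcription-factor activity is a phenomenological Hill function
$a = x^n/(x^n + k^n)$ of a metabolic signal $x$ — a concentration or an
arithmetic expression over concentrations (for example the pep/pyr ratio
for CRP, or the mean quinone reduction state for ArcA); negative $n$
encodes inhibition by the signal. Gene expression multiplies one factor
$s(k, a) = 2^{-k} + (1 - 2^{-k})\,a$ per regulator (activities replaced
by $1-a$ for repressors), so each regulator spans at most a factor
$2^k$, with integer $k$. Enzymes are diluted by growth,
$\dot c_E = J_{\rm syn} - \mu c_E$; at a chemostat steady state
$\mu = D$ and $c_E = J_{\rm syn}/D$, which the solver uses directly.
Basal synthesis rates in the packaged model equal $D$, so an unregulated
gene has enzyme level one and the resistances absorb the absolute scale.

## Growth, maintenance, and the chemostat

Biomass formation consumes precursors with fixed stoichiometry
(mmol/gDCW, Neidhardt-style values at the precursor level, with the
pentose-phosphate demands folded into the hexose entry in the core
network). The growth rate is linlog in the precursor concentrations,
gated by a ramp in the ATP/ADP ratio that is zero below `k_lo`, linear
to `k_hi` and saturates at one: growth requires a minimal adenylate
energy state. The cofactor demands (ATP, NAD, NADPH) are excluded from
the linlog sum — they are governed by the ramp — a package design choice
to avoid counting the energy state twice. Maintenance is an
uncoupled ATP hydrolysis with its own, wider ramp (`m_lo = 1`,
`m_hi = 30`, `m_max = 45` mmol/gDCW/h in the fixture): it acts as the
elastic ATP sink that pins the adenylate state over a broad range of
oxygen supplies; the published observation that the energy charge is
nearly invariant emerges from this ramp together with the ADP activation
of phosphofructokinase.

The environment is a glucose-limited chemostat: biomass follows
$\dot c_X = (\mu - D) c_X$, dissolved species
$\dot c_i = J_i c_X + D(c_{in,i} - c_i)$, and gas species (O$_2$,
CO$_2$) exchange with the gas phase,
$\dot c_i = J_i c_X + k_{in,i} - k_{out,i} c_i$. Conserved moieties
(adenylates, NAD(H), NADP(H), CoA thioesters) keep constant totals; de
novo synthesis at rate $\mu \times$ total into the least-phosphorylated
/ most-oxidized member exactly balances dilution, which the trajectory
tests verify. Quinone pool totals are affine in aerobiosis on
$[0, 100]$ and clamp above 100%; a constant non-reactive oxidized
quinone pool is carried for reporting redox states.

## The aerobiosis scale

The scale is operational: 0% is the anaerobic chemostat and 100% is the
minimal oxygen input at which fermentation products are no longer
excreted; the scale is linear in the oxygen input.
`calibrate_aerobiosis()` reproduces this definition numerically: it
marches the oxygen supply upward with continuation and bisects on the
biomass-specific acetate excretion until it falls to 1% of its anaerobic
value (the package's operational zero; thermokinetic reversibility makes
exact zero unattainable), storing the resulting `k_in_o2_100` in the
model so aerobiosis percentages map to supply rates.

## Quasi-equilibrium reduction and the solver

Fast reactions are declared with zero resistance ("=" in the model
format). Each contributes an algebraic constraint $F_j(\xi) = 0$ —
linear in log-potentials — while its flux becomes an algebraic unknown;
the coupled species behave as one lumped pool and the
differential-algebraic system has index one. `assemble()` performs this
reduction and rejects structurally dependent quasi-equilibrium sets at
load time.

Steady states are found by a damped Newton iteration on the reduced
residual with: log-concentration variables (positivity built in; only
stoichiometric combinations of capacities are ever exponentiated, so
large formation energies cannot overflow), analytic row scaling, a
line search, and central finite differences near the solution. When a
cold start stalls, the solver escalates through (i) pseudo-transient
continuation — implicit Euler on the physical dynamics with growing
steps, using the mass pairing of balances with their species; (ii) a
relaxation homotopy replacing quasi-equilibrium constraints by very fast
finite reactions so the unreduced system can be settled by stiff time
integration (deSolve); and (iii) a bordered strategy for the chemostat
closure: the biomass is frozen, the metabolic core is solved, a guarded
secant iteration moves the biomass until $\mu = D$, and a final full
Newton run polishes everything. Wash-out (the culture cannot match the
dilution rate) is detected and reported as a distinct, valid outcome.
Singular directions — for example dissolved oxygen in a strictly
anaerobic reactor, which the balances cannot see — are handled by a
rank-revealing QR step that leaves such directions untouched. The
default residual tolerance is $10^{-9}$ in natural units (mmol/gDCW/h
for intracellular balances); quasi-equilibrium constraints, being linear
in the solved variables, close to near machine precision.

Parameter sweeps use natural continuation (each solution seeds the next
grid point) with a backward fill for isolated failures. Model files may
carry a `[start]` section with a reference operating point; the packaged
core model ships its anaerobic steady state there, which makes cold
starts deterministic and fast.

## Production-capability assessment

A production pathway is represented only by its stoichiometric shadow:
an enforced, thermokinetics-independent drain of precursors at a
biomass-specific rate $J_{\rm prod}$ (for example
`"2 accoa + 4 nadh -> 2 coa + 4 nad"` for a butanol route). The
assessment follows the steady state from the undisturbed chemostat along
increasing $J_{\rm prod}$, at frozen absolute aeration (the culture's
aerobiosis may shift as the biomass responds); concentrations are
reported relative to the undisturbed state of the same run and the
volumetric productivity is $q_{\rm prod} = J_{\rm prod}\,c_X$. The grid
stops where the steady state ceases to exist; the failure boundary is
refined by three rounds of step halving — the package's own choice, as
no termination rule is inherent in the method. The species with the
largest relative concentration drop at the last converged point is
reported as limiting, with ties reported explicitly rather than broken
arbitrarily.

## The packaged models and what they do and do not show

The `core` fixture covers glucose uptake (PTS), glycolysis, the
fermentation branches (pyruvate formate lyase,
phosphotransacetylase/acetate kinase, aldehyde-alcohol dehydrogenase,
acetyl-CoA synthetase), the branched versus cyclic citric acid cycle
with menaquinone-using fumarate reductase against ubiquinone-using
succinate dehydrogenase, anaplerosis, an electron transport chain with
pumping and non-pumping NADH dehydrogenases and the bo/bd oxidases, ATP
synthase, FNR/ArcA/CRP/FruR regulation, biomass, maintenance and the
chemostat. Several deliberate simplifications keep it at core scale:

* The transformed formation energies are **synthetic stand-ins** on the
  scale of Alberty-style tables, assigned so that every reaction's
  standard transformed Gibbs energy takes a literature-typical value via
  a spanning-tree construction (the cycle closure fixes the CO$_2$
  anchor). They are thermodynamically consistent but not a curated
  compilation.
* Charges are set to zero and membrane energetics are carried entirely
  by a lumped translocated-proton species (`pmf`) balanced at steady
  state, with the cytoplasmic proton clamped (pH buffered). The
  membrane potential declared for the cytoplasmic compartment is
  therefore inert in the fixture, although the capacity computation
  supports it fully. Proton stoichiometries are fixture
  choices (4 per NADH at the pumping dehydrogenase, 8/4 per O$_2$ at the
  bo/bd oxidases, 4 per ATP, 2 for the menaquinone branch, chosen so
  fumarate respiration remains thermodynamically feasible).
* Excretion steps produce extracellular species directly, oxidases
  consume dissolved O$_2$ directly, and succinate export is included so
  the reductive branch can carry steady-state flux.
* Transcription-factor signals and Hill parameters, the ramp thresholds
  and the biomass linlog offset are stand-ins chosen so the model
  reproduces the qualitative oxygen-response phenotype at
  $D = 0.2\,h^{-1}$ with a 20 mmol/l glucose feed; they are not fitted
  to any measured data set. Passing tests therefore demonstrate the
  *mechanisms* — thermodynamic consistency, the regulatory switching
  pattern, the shape of the production-capability curves — not
  quantitative agreement with measured concentrations or transcripts.

The `toy` fixture is a four-reaction chain with explicit ATP
stoichiometry and a conserved adenylate pool; it exists so that solver
claims can be checked against closed forms and brute-force integration.

Problem sizes used by the tests: the acceptance-style suite runs a
41-point aerobiosis sweep (0–200%), 1000-state randomized
thermodynamic-consistency checks, 100 random scaling-factor pairs, and
production curves with initial steps of 0.25–0.5 mmol/gDCW/h; these
sizes were chosen as the smallest that exercise every claimed behaviour
clearly.

## Numerical choices and limitations

* Tolerances: residual $10^{-9}$ (absolute, natural units), continuation
  warm-start acceptance $10^{-8}$ relative; ramps are exactly piecewise
  linear by default, with an optional C$^1$ smoothing of width $10^{-3}$
  ratio units for continuation work.
* Time integration is a solver fallback and test oracle only, not a
  product surface; transient predictions of the package should not be
  interpreted.
* The chemostat equations admit multiple steady states in parts of
  parameter space (an energized and a de-energized branch); the shipped
  `[start]` point selects the physiological branch, and forward/backward
  sweeps can be compared to detect hysteresis.
* The ATP/ADP *ratio* at strongly aerobic operating points is a
  ill-conditioned readout (ADP is small); the energy state is better
  summarised by the ATP concentration or the adenylate energy charge,
  which the assessment tests use.
* Relative measurement overlay assumes a common multiplicative scale per
  variable across the sweep; fluxes and biomass are treated as absolute.
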