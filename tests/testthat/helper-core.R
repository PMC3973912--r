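# Shared, lazily computed core-model results so that the expensive
# calibration + sweep run once per test session.

.core_cache <- new.env(parent = emptyenv())

core_calibrated <- function() {
  if (is.null(.core_cache$cal))
    .core_cache$cal <- calibrate_aerobiosis(build_fixture("core"))
  .core_cache$cal
}

core_aerobiosis_sweep <- function() {
  if (is.null(.core_cache$sweep))
    .core_cache$sweep <- sweep_states(core_calibrated(), "aerobiosis",
                                      seq(0, 200, length.out = 41))
  .core_cache$sweep
}

core_anaerobic_state <- function() {
  if (is.null(.core_cache$anaer))
    .core_cache$anaer <- solve_steady_state(
      assemble(build_fixture("core"), k_in_o2 = 0))
  .core_cache$anaer
}

# biomass-specific excretion rate of an extracellular species, mmol/gDCW/h
# (at a converged chemostat steady state mu equals the dilution rate)
specific_excretion <- function(sweep, id) {
  sweep$mu * sweep[[paste0("c.", id)]] / sweep$c_X
}
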