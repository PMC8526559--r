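# shared fixtures, memoised so expensive simulations run once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_geometry <- function() memo("geometry", build_valve_geometry())
default_panels <- function() memo("panels", build_canonical_aorta())

# coupled-cycle trajectories for the three reference valve conditions
fixture_trajectory <- function(label, multiplier = 8, sv_ml = 72) {
  key <- paste("traj", label, multiplier, sv_ml, sep = "_")
  memo(key, {
    scn <- hemodynamic_scenario(label, multiplier = multiplier,
                                sv_ml = sv_ml, seed = 1L)
    simulate_valve_cycle(scn, default_geometry())
  })
}

# the default development dataset and trained pipeline (the study
# conditions: 7 healthy + 22 stenotic, SMOTE balanced to 44, seed 0)
fixture_report <- function() memo("report", run_end_to_end(default_config(seed = 0L)))

# one small propagated record set for source-level checks
fixture_small_dataset <- function() {
  memo("small_dataset", generate_dataset(n_healthy = 2, n_stenotic = 2,
                                         seed = 42L))
}
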