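# Shared simulated fixtures, built once per test run.
.fixtures <- new.env(parent = emptyenv())

# A 3-year J-surface dataset and its fit with a lighter spec, reused by
# tests that only need *some* plausible fitted model.
fixture_fit <- function() {
  if (is.null(.fixtures$fit)) {
    sim <- simulate_daily(sim_config(n_years = 3, seed = 42),
                          true_surface("J"))
    .fixtures$sim <- sim
    .fixtures$fit <- suppressWarnings(
      dlnm_nb(sim, model_spec(max_lag = 14, lag_df = 4, var_df = 4)))
  }
  .fixtures$fit
}

fixture_sim <- function() {
  fixture_fit()
  .fixtures$sim
}
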