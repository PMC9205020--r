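# Shared simulation scenarios. Cohorts are generated once per test run
# and reused across files where the scenario matches.

zero_betas <- function() setNames(rep(0, 9), c("ba", "cd", "co", "cs", "mo",
                                               "pb", "sb", "tl", "tu"))

# no metal effect anywhere (aging -> OA path kept): exposure-outcome null
null_metal_config <- function(n = 1000, seed = 1) {
  simulation_config(n_participants = n, seed = seed,
                    beta_metal_to_aging = zero_betas(),
                    beta_metal_to_telomere = zero_betas(),
                    beta_metal_direct = zero_betas())
}

# a single causal metal acting directly on OA (weight-recovery scenario)
cd_only_config <- function(n = 5000, seed = 1, effect = 0.6) {
  b <- zero_betas()
  b["cd"] <- effect
  simulation_config(n_participants = n, seed = seed,
                    beta_metal_to_aging = zero_betas(),
                    beta_metal_to_telomere = zero_betas(),
                    beta_metal_direct = b)
}

kdm_panel_constants_for_tests <- function() metalage:::kdm_panel_constants()
pheno_cols_for_tests <- function() metalage:::pheno_biomarker_columns()

default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(simulation_config(n_participants = 3000, seed = 42))
      coh <- add_exposure_columns(coh)
      cache <<- suppressMessages(attach_aging_markers(coh, quiet = TRUE))
    }
    cache
  }
})
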