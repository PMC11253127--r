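# Shared fixtures: the published population parameters used as generating
# truth, and small synthetic cohorts built in code.

published_truth <- function() {
  structural_params(k0 = 1500, k1 = 4.84, k2 = 0.0902, k2_hd_pop = 0.125,
                    beta_cag = 2.74, cnfl_brain = 15.5)
}

truth_vector <- function() {
  c(k0 = 1500, k1 = 4.84, k2_hc = 0.0902, k2_hd_pop = 0.125,
    beta_cag = 2.74, cnfl_brain = 15.5, omega_k0 = 40, omega_k2 = 0.3,
    sigma_prop_nfl = 0.216, sigma_add_vol = 11)
}

# small study-design cohort (20/20/40, two visits)
small_cohort <- function(seed = 101, re = random_effects_spec(),
                         err = error_model_spec(), design = cohort_design()) {
  subj <- sample_subjects(design, re, published_truth(), seed = seed)
  simulate_observations(subj, published_truth(), clearance_table(), err,
                        design, seed = seed + 1L)
}

# noise-free, fixed-effects-only cohort: observations equal the model
noise_free_cohort <- function(seed = 77, design = cohort_design()) {
  subj <- sample_subjects(design, random_effects_spec(0, 0),
                          published_truth(), seed = seed)
  simulate_observations(subj, published_truth(), clearance_table(),
                        error_model_spec(0, 0), design, seed = seed + 1L)
}
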