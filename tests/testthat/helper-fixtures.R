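# Fixture parameter sets used across tests. Rates are the package's study
# scenarios: a neutral mark (mPAS-like) and an advantaged mark (KDM6A-like).

mpas_params <- function() {
  rate_params(rho = 0.007, phi = 0.003, mu_fix = 2.5e-5, c_part = 4.4e-4)
}

kdm6a_params <- function() {
  rate_params(rho = 0.036, phi = 0.007, mu_fix = 6.04e-6, c_part = 2.626e-5,
              d_coef = 1.05, s0 = 0.265)
}

kdm6a_config <- function(n_patients = 60, crypts_mean = 1e4, seed = 1L) {
  cohort_config(n_patients = n_patients, age_range = c(21, 93),
                crypts_mean = crypts_mean,
                mark_params = list(KDM6A = kdm6a_params()), seed = seed)
}

mpas_config <- function(n_patients = 60, crypts_mean = 2e4, seed = 1L) {
  cohort_config(n_patients = n_patients, age_range = c(20, 90),
                crypts_mean = crypts_mean,
                mark_params = list(mPAS = mpas_params()), seed = seed)
}

# Small map set at the fixture diffusion coefficient with clone ages drawn
# from the natural conditional distribution at the given patient age.
fixture_maps <- function(n_maps, seed = 1L, clone_age = NULL, d_coef = 1.05,
                         patient_age = 70, n_crypts = 500) {
  kd <- rate_params(rho = 0.036, mu_fix = 6.04e-6, d_coef = d_coef,
                    s0 = 0.265)
  ages <- if (!is.null(clone_age)) rep(clone_age, n_maps) else {
    tr <- simulate_trajectories(kd$mu_fix, kd$rho, patient_age, 10,
                                n_paths = n_maps, seed = seed + 5000L)
    vapply(tr, function(h) h$mutation_time, numeric(1))
  }
  lapply(seq_len(n_maps), function(i)
    generate_spatial_map(kd, clone_age = ages[i], patch_size = 10,
                         seed = seed + i, n_crypts = n_crypts,
                         patient_age = patient_age))
}
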