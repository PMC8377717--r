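# Shared setup for the analysis drivers: study-scenario parameters and a
# results/ output helper. Run scripts from the repository root, e.g.
#   Rscript analysis/01_simulate_cohort.R

suppressPackageStartupMessages(library(cryptdyn))

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)
out <- function(...) file.path(res_dir, ...)

SEED <- 20260923L

# Clonal-mark scenarios: neutral (mPAS-like) and advantaged (STAG2- and
# KDM6A-like), rates per crypt per year.
marks <- list(
  mPAS = rate_params(rho = 0.007, phi = 0.003, mu_fix = 2.5e-5,
                     c_part = 4.4e-4),
  STAG2 = rate_params(rho = 0.021, phi = 0.004, mu_fix = 2e-5,
                      c_part = 8e-5),
  KDM6A = rate_params(rho = 0.036, phi = 0.007, mu_fix = 6.04e-6,
                      c_part = 2.626e-5, d_coef = 1.05, s0 = 0.265)
)

study_config <- function(mark_names = names(marks), n_patients = 120,
                         seed = SEED) {
  cohort_config(n_patients = n_patients, age_range = c(21, 93),
                crypts_mean = 2e4, mark_params = marks[mark_names],
                seed = seed)
}
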