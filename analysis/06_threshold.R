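# Lesion threshold: escalate the fission rate over the homeostatic baseline,
# find the accommodation limit, and quantify lesion risk for the KRAS
# scenario with and without a decade of fission inhibition.

source("analysis/00_common.R")

cat(sprintf("hexagonal whitespace threshold: %.5f\n", hexagonal_whitespace()))

base <- lesion_sim_config(rho0 = 0.007, d_coef = 1.05, s0 = 0.265,
                          horizon = 90, n_reps = 1e5, seed = SEED)
sweep <- find_threshold_multiple(base, k_grid = 8:20,
                                 criterion_prob = 1e-3, criterion_year = 90)
cat("breach probability by 90y per fission multiple:\n")
print(signif(sweep$probs, 3))
cat(sprintf("smallest multiple breaching 1e-3: %s\n", format(sweep$k)))
write_table_tsv(data.frame(k = as.integer(names(sweep$probs)),
                           prob_90y = sweep$probs),
                out("threshold_sweep.tsv"), list(seed = SEED))

for (k in c(17, 19)) {
  res <- simulate_clone_lesion(lesion_sim_config(
    fission_multiple = k, horizon = 50, n_reps = 4e5, seed = SEED + k))
  cat(sprintf("k=%d: %.2f%% of clones lesion by 50y (MC se %.3f%%)\n",
              k, 100 * res$prob_at_horizon, 100 * res$mc_se))
  if (k == 17)
    write_table_tsv(res$cum_prob, out("lesion_cum_prob_k17.tsv"),
                    list(seed = SEED + k, k = k))
}

iv <- intervention_comparison(
  lesion_sim_config(fission_multiple = 17, horizon = 50, n_reps = 2e5,
                    seed = SEED),
  windows = list(c(0, 10), c(10, 20), c(20, 30)), at_year = 50,
  max_reps = 5e5)
print(iv)
write_table_tsv(iv, out("interventions.tsv"), list(seed = SEED))
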