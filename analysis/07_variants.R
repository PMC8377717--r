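# Amplicon mutation calling: cross-sample noise profiling, KDM6A patch
# calling, KRAS codon 12/13 calling, clone sizes from allele frequencies,
# and simulation-based inference of the KRAS fission rate.

source("analysis/00_common.R")

# KDM6A: three serial sections of one patch plus wild-type references
np <- data.frame(position = 0:59, alt = "T", mean_maf = 8e-4, sd_maf = 3e-4)
sp <- data.frame(sample_id = 1:3, position = 23, maf = 0.04)
tab <- generate_amplicon_table(9, 60, noise_profile = np,
                               spiked_mutations = sp, seed = SEED,
                               depth_mean = 2e4, min_depth = 8000)
noise <- build_noise_profile(tab[tab$sample_id >= 4, ])
groups <- data.frame(sample_id = 1:9,
                     patch_id = c("p1", "p1", "p1", rep(NA, 6)))
calls <- call_kdm6a(tab, noise, groups)
conf <- calls[calls$status == "confirmed", ]
cat(sprintf("KDM6A calls: %d confirmed at position(s) %s, corrected MAF %.4f\n",
            nrow(conf), paste(unique(conf$position), collapse = ","),
            mean(conf$corrected_maf)))
write_table_tsv(calls, out("kdm6a_calls.tsv"), list(seed = SEED))

# KRAS: both gene amplicons plus a mimic control
kras <- data.frame(amplicon_id = c("KRAS_1", "KRAS_2"),
                   alt_count = c(52, 61), depth = c(11000, 12500))
mimic <- data.frame(amplicon_id = "mimic_1", alt_count = 4, depth = 10500)
kc <- call_kras(kras, mimic, noise = list(mean_maf = 4e-4, sd_maf = 2e-4))
cat(sprintf("KRAS G12D-type call: %s, corrected MAF %.4f -> clone of %d crypts\n",
            kc$status, kc$corrected_maf,
            clone_size_from_maf(kc$corrected_maf, 15000, 2)))
cat("codon 12/13 alternate set:",
    paste(kras_codon_alternates()$aa_change, collapse = " "), "\n")

# KRAS fission rate from clone sizes with the MAF detection floor
set.seed(SEED)
age <- runif(600, 20, 91)
t <- age * runif(600)
size <- ryule(600, 0.12, t)
clones <- data.frame(age = age, size = size)[size >= 24, ][1:35, ]
est <- infer_kras_fission(clones, detection_floor = 24, seed = SEED)
cat(sprintf("KRAS fission rate: %.1f%%/yr (95%% CrI %.1f-%.1f), %.0f-fold homeostatic\n",
            100 * est$rho, 100 * est$ci_low, 100 * est$ci_high,
            est$rho / 0.007))
write_table_tsv(est$loglik_profile, out("kras_fission_posterior.tsv"),
                list(seed = SEED))
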