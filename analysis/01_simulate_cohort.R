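# Generate the synthetic study cohort: clone surveys, FUFI scoring and
# neighbour records for all three clonal marks, with ground-truth sidecars.

source("analysis/00_common.R")

cfg <- study_config()
survey <- generate_clone_survey(cfg)
fufi <- generate_fufi_survey(cfg, survey)

write_table_tsv(survey$sections, out("sections.tsv"),
                list(seed = cfg$seed, stage = "simulate"))
write_table_tsv(survey$patches, out("patches.tsv"),
                list(seed = cfg$seed, stage = "simulate"))
write_table_tsv(fufi$fufis, out("fufis.tsv"),
                list(seed = cfg$seed, stage = "simulate"))
write_table_tsv(fufi$neighbors, out("fufi_neighbors.tsv"),
                list(seed = cfg$seed, stage = "simulate"))
write_table_tsv(fufi$truth, out("fufi_truth.tsv"),
                list(seed = cfg$seed, stage = "simulate"))

for (mk in names(marks)) {
  sec <- survey$sections[survey$sections$mark == mk, ]
  cat(sprintf(
    "%-6s %d patients, %.2g crypts, %d mutant crypts, %d patches scored\n",
    mk, nrow(sec), sum(sec$n_crypts), sum(sec$n_wpc),
    sum(survey$patches$count[survey$patches$mark == mk])))
}
cat("wrote cohort tables under", res_dir, "\n")
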