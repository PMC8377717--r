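test_that("noise profile moments match their construction", {
  np <- data.frame(position = 0:9, alt = "T", mean_maf = 0, sd_maf = 0)
  tab <- generate_amplicon_table(4, 10, noise_profile = np, seed = 1)
  prof <- build_noise_profile(tab)
  expect_true(all(prof$mean_maf == 0) && all(prof$sd_maf == 0))
  # constant alternate fraction: mean recovered, sd zero
  tab2 <- tab
  tab2$alt_count <- round(0.01 * tab2$depth)
  tab2$ref_count <- tab2$depth - tab2$alt_count
  prof2 <- build_noise_profile(tab2)
  expect_equal(mean(prof2$mean_maf), 0.01, tolerance = 1e-3)
  expect_lt(max(prof2$sd_maf), 2e-4)
  # beta-binomial noise: moments within Monte-Carlo error of the generator
  np3 <- data.frame(position = 0:19, alt = "T", mean_maf = 2e-3, sd_maf = 8e-4)
  tab3 <- generate_amplicon_table(200, 20, noise_profile = np3, seed = 3,
                                  depth_mean = 2e4, min_depth = 1e4)
  prof3 <- build_noise_profile(tab3)
  expect_lt(abs(mean(prof3$mean_maf) - 2e-3), 3 * 8e-4 / sqrt(200 * 20) + 1e-4)
  expect_lt(abs(mean(prof3$sd_maf) - sqrt(8e-4^2 + 2e-3 / 2e4)), 3e-4)
  expect_error(build_noise_profile(tab[tab$sample_id == 1, ]), "2 samples")
})

test_that("candidate thresholds are strict inequalities", {
  noise <- data.frame(amplicon_id = "a", position = 0L, alt = "T",
                      mean_maf = 0.001, sd_maf = 0.002, n_samples = 5)
  class(noise) <- c("noise_profile", "data.frame")
  depth <- 1e5
  mk <- function(maf, sample_id = 1) data.frame(
    sample_id = sample_id, amplicon_id = "a", position = 0L, alt = "T",
    ref_count = depth - round(maf * depth), alt_count = round(maf * depth),
    depth = depth)
  groups <- data.frame(sample_id = 1, patch_id = "p1")
  # exactly 4 x mean and within 3.29 sd of the mean: not a candidate
  calls <- call_kdm6a(mk(0.004), noise, groups)
  expect_false(calls$candidate)
  # just above the mean rule fires even below the sd rule
  calls2 <- call_kdm6a(mk(0.0041), noise, groups)
  expect_true(calls2$candidate)
  calls3 <- call_kdm6a(mk(0.009), noise, groups)
  expect_true(calls3$candidate)
  expect_equal(calls3$corrected_maf, 0.009 - 0.001)
  # sd rule alone: excess over the mean must exceed 3.29 sd
  noise2 <- data.frame(amplicon_id = "a", position = 0L, alt = "T",
                       mean_maf = 0.002, sd_maf = 3e-4, n_samples = 5)
  class(noise2) <- c("noise_profile", "data.frame")
  expect_false(call_kdm6a(mk(0.0029), noise2, groups)$candidate)
  expect_true(call_kdm6a(mk(0.0031), noise2, groups)$candidate)
})

test_that("patch-serial confirmation rules are enforced", {
  np <- data.frame(position = 0:29, alt = "T", mean_maf = 3e-4, sd_maf = 1e-4)
  groups <- data.frame(sample_id = 1:6,
                       patch_id = c("p1", "p1", "p1", NA, NA, NA))
  # spiked in all three serial sections of the patch, absent in wild-type
  sp_all <- data.frame(sample_id = 1:3, position = 11, maf = 0.03)
  tab <- generate_amplicon_table(6, 30, noise_profile = np,
                                 spiked_mutations = sp_all, seed = 5,
                                 depth_mean = 8000, min_depth = 4000)
  ref_noise <- build_noise_profile(tab[tab$sample_id >= 4, ])
  calls <- call_kdm6a(tab, ref_noise, groups)
  hit <- calls[calls$position == 11 & calls$sample_id <= 3, ]
  expect_true(all(hit$status == "confirmed"))
  # spiked in only 2 of 3 serial sections: rejected with the stated reason
  sp_2 <- data.frame(sample_id = 1:2, position = 17, maf = 0.03)
  tab2 <- generate_amplicon_table(6, 30, noise_profile = np,
                                  spiked_mutations = sp_2, seed = 6,
                                  depth_mean = 8000, min_depth = 4000)
  calls2 <- call_kdm6a(tab2, build_noise_profile(tab2[tab2$sample_id >= 4, ]),
                       groups)
  miss <- calls2[calls2$position == 17 & calls2$sample_id <= 2, ]
  expect_true(all(miss$status == "rejected"))
  expect_true(all(miss$reason == "not in all patch samples"))
  # spiked also in a wild-type sample: rejected
  sp_wt <- data.frame(sample_id = c(1:3, 5), position = 23, maf = 0.03)
  tab3 <- generate_amplicon_table(6, 30, noise_profile = np,
                                  spiked_mutations = sp_wt, seed = 7,
                                  depth_mean = 8000, min_depth = 4000)
  calls3 <- call_kdm6a(tab3, build_noise_profile(tab3[tab3$sample_id >= 4, ]),
                       groups)
  bad <- calls3[calls3$position == 23 & calls3$sample_id <= 3, ]
  expect_true(all(bad$status == "rejected"))
})

test_that("false-positive rate on pure noise respects the design level", {
  # both filters combined target P <= .001; at moderate overdispersion the
  # per-position candidate rate stays below 0.2% over ~1e5 position-samples
  np <- data.frame(position = 0:499, alt = "T", mean_maf = 1e-3,
                   sd_maf = 1.5e-4)
  tab <- generate_amplicon_table(150, 500, noise_profile = np, seed = 11,
                                 depth_mean = 3e4, min_depth = 15000)
  prof <- build_noise_profile(tab)
  groups <- data.frame(sample_id = 1:150,
                       patch_id = rep(NA_character_, 150))
  calls <- call_kdm6a(tab, prof, groups)
  expect_lt(mean(calls$candidate), 0.002)
  # heavy cross-sample overdispersion inflates the 3.29-sd rule's tail, but
  # the rate stays well under 1%
  nph <- data.frame(position = 0:499, alt = "T", mean_maf = 1e-3,
                    sd_maf = 4e-4)
  tabh <- generate_amplicon_table(60, 500, noise_profile = nph, seed = 12,
                                  depth_mean = 5000, min_depth = 2000)
  callsh <- call_kdm6a(tabh, build_noise_profile(tabh),
                       data.frame(sample_id = 1:60,
                                  patch_id = rep(NA_character_, 60)))
  expect_lt(mean(callsh$candidate), 0.01)
})

test_that("KRAS calling enforces depth, MAF and read floors strictly", {
  noise <- list(mean_maf = 4e-4, sd_maf = 2e-4)
  kras_ok <- data.frame(amplicon_id = c("k1", "k2"),
                        alt_count = c(25, 30), depth = c(5000, 6000))
  mimic_ok <- data.frame(amplicon_id = "m1", alt_count = 2, depth = 5000)
  expect_equal(call_kras(kras_ok, mimic_ok, noise)$status, "confirmed")
  # depth exactly 1000 fails the strict inequality
  kras_d <- transform(kras_ok, depth = c(1000, 6000), alt_count = c(5, 30))
  expect_equal(call_kras(kras_d, mimic_ok, noise)$status, "rejected")
  # nine mutant reads fail the read floor even above 0.1% MAF
  kras_9 <- data.frame(amplicon_id = c("k1", "k2"),
                       alt_count = c(9, 12), depth = c(4000, 5000))
  r9 <- call_kras(kras_9, mimic_ok, noise)
  expect_equal(r9$status, "rejected")
  expect_match(r9$reason, "10 mutant reads")
  # mimic contamination is disqualifying
  mim_bad <- data.frame(amplicon_id = "m1", alt_count = 40, depth = 5000)
  expect_equal(call_kras(kras_ok, mim_bad, noise)$status, "rejected")
  # missing mimic: insufficient evidence, not an error
  expect_equal(call_kras(kras_ok, mimic_ok[0, ], noise)$status,
               "insufficient-evidence")
  # corrected MAF subtracts the mean noise and never exceeds the raw MAF
  res <- call_kras(kras_ok, mimic_ok, noise)
  expect_equal(res$corrected_maf, res$maf - 4e-4)
  expect_lte(res$corrected_maf, res$maf)
})

test_that("normal-quantile thresholds match their stated p-values", {
  expect_equal(signif(stats::qnorm(1 - 0.001 / 2), 3), 3.29)
  expect_equal(signif(stats::qnorm(1 - 0.025), 3), 1.96)
})

test_that("the KRAS codon 12/13 alternate set is the 12 missense changes", {
  alts <- kras_codon_alternates()
  expect_equal(nrow(alts), 12)
  expect_equal(sum(alts$codon == "G12"), 6)
  expect_equal(sum(alts$codon == "G13"), 6)
  expect_true(all(alts$position_in_codon %in% 1:2))
  expect_true(!any(duplicated(alts$mutant_codon)))
})

test_that("clone sizes follow from allele frequencies", {
  expect_equal(clone_size_from_maf(0, 12000), 0)
  expect_equal(clone_size_from_maf(0.005, 10000, 2), 100)
  expect_equal(clone_size_from_maf(0.005, 10000, 1), 50)
  expect_warning(clone_size_from_maf(0.7, 1000, 2), "inconsist")
  # generator truth: a 150-crypt clone in 15000 crypts, X-linked male
  set.seed(12)
  depth <- 2e5
  maf_true <- 150 / 15000
  alt <- rbinom(1, depth, maf_true)
  expect_lt(abs(clone_size_from_maf(alt / depth, 15000, 1) - 150),
            3 * sqrt(depth * maf_true) / depth * 15000 + 1)
})

test_that("KRAS fission-rate inference recovers the generative rate", {
  set.seed(31)
  mk_clones <- function(rho, n) {
    age <- runif(4 * n, 20, 91)
    t <- age * runif(4 * n)
    size <- ryule(4 * n, rho, t)
    keep <- size >= 24
    data.frame(age = age[keep], size = size[keep])[seq_len(n), ]
  }
  cl <- mk_clones(0.12, 120)
  est <- infer_kras_fission(cl, detection_floor = 24, seed = 2)
  expect_gt(est$rho, 0.09)
  expect_lt(est$rho, 0.16)
  # posterior concentrates with more clones
  w10 <- infer_kras_fission(mk_clones(0.12, 15), seed = 3)
  w100 <- infer_kras_fission(mk_clones(0.12, 300), seed = 4)
  expect_lt(w100$ci_high - w100$ci_low, w10$ci_high - w10$ci_low + 1e-9)
})
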