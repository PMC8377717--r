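test_that("config validation rejects impossible parameter sets", {
  expect_error(rate_params(rho = -1), ">= 0")
  expect_error(rate_params(rho = Inf), "finite")
  expect_error(cohort_config(age_range = c(-5, 60)), "age_range")
  expect_error(cohort_config(mark_params = list(rate_params())), "named")
  expect_error(cohort_config(fufi_duration = 0))
})

test_that("degenerate rates produce the expected degenerate surveys", {
  cfg0 <- cohort_config(n_patients = 20, crypts_mean = 5000,
                        mark_params = list(m = rate_params(rho = 0, mu_fix = 1e-4)),
                        seed = 2)
  sv0 <- generate_clone_survey(cfg0)
  expect_true(all(sv0$patches$size == 1))      # no fission: singletons only
  cfg1 <- cohort_config(n_patients = 20,
                        mark_params = list(m = rate_params(mu_fix = 0)),
                        seed = 2)
  sv1 <- generate_clone_survey(cfg1)
  expect_equal(sum(sv1$sections$n_wpc), 0)     # no mutations: nothing scored
  expect_equal(nrow(sv1$patches), 0)
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- kdm6a_config(n_patients = 15, crypts_mean = 5000, seed = 77)
  a <- generate_clone_survey(cfg); b <- generate_clone_survey(cfg)
  expect_identical(a$sections, b$sections)
  expect_identical(a$patches, b$patches)
  fa <- generate_fufi_survey(cfg, a); fb <- generate_fufi_survey(cfg, b)
  expect_identical(fa$fufis, fb$fufis)
  expect_identical(fa$neighbors, fb$neighbors)
})

test_that("generated mean patch size matches the pure-birth closed form", {
  # closed-form mean of the uniform-timing marginal, by quadrature
  cfg <- cohort_config(n_patients = 200, age_range = c(20, 90),
                       crypts_mean = 2e4,
                       mark_params = list(m = rate_params(rho = 0.007,
                                                          mu_fix = 2.5e-5)),
                       seed = 13)
  sv <- generate_clone_survey(cfg)
  p <- sv$patches
  obs_mean <- sum(p$size * p$count) / sum(p$count)
  exp_mean_patient <- function(T_age)
    stats::integrate(function(s) exp(0.007 * (T_age - s)) / T_age,
                     0, T_age)$value
  ages <- sv$sections$age
  theo <- mean(vapply(ages, exp_mean_patient, numeric(1)))
  mc_se <- sd(rep(p$size, p$count)) / sqrt(sum(p$count))
  expect_lt(abs(obs_mean - theo), 3 * mc_se + 0.02)
})

test_that("patch-size marginal passes goodness of fit on 1e4 clones", {
  cfg <- cohort_config(n_patients = 400, age_range = c(60, 60.01),
                       crypts_mean = 2e4,
                       mark_params = list(m = rate_params(rho = 0.02,
                                                          mu_fix = 2e-5)),
                       seed = 21)
  sv <- generate_clone_survey(cfg)
  sizes <- rep(sv$patches$size, sv$patches$count)
  expect_gt(length(sizes), 8000)
  kmax <- max(sizes)
  p <- vapply(1:kmax, function(k) yule_size_marginal(0.02, 60, k), numeric(1))
  obs <- tabulate(sizes, kmax)
  keep <- p * length(sizes) >= 5
  gof <- stats::chisq.test(c(obs[keep], sum(obs[!keep])),
                           p = c(p[keep], 1 - sum(p[keep])), rescale.p = TRUE)
  expect_gt(gof$p.value, 0.01)
})

test_that("hexagonal patch neighbourhoods have the right structure", {
  expect_equal(hex_patch_neighbors(1), 0L)
  expect_equal(hex_patch_neighbors(7), c(6L, rep(3L, 6)))
  m19 <- hex_patch_neighbors(19)        # two full rings
  expect_equal(sum(m19 == 6), 7)        # centre + ring 1 fully enclosed
  expect_equal(length(m19), 19)
  expect_true(all(m19 >= 2 & m19 <= 6))
})

test_that("FUFI generation respects its ground-truth bookkeeping", {
  cfg <- mpas_config(n_patients = 40, crypts_mean = 2e4, seed = 5)
  sv <- generate_clone_survey(cfg)
  fu <- generate_fufi_survey(cfg, sv)
  tr <- fu$truth
  # M/W forms arise from fusions only
  expect_true(all(tr$type[tr$label == "MW"] == "fusion"))
  # counts in the observable table equal the event log
  expect_equal(sum(fu$fufis$n_mm), sum(tr$label == "MM"))
  expect_equal(sum(fu$fufis$n_mw), sum(tr$label == "MW"))
  # singleton-dominated neutral clones: all-wild-type neighbourhoods make
  # every M/M FUFI a fission in the log
  allw <- tr$m_neighbors == 0 & tr$label == "MM"
  expect_true(all(tr$type[allw] == "fission"))
})

test_that("fission and fusion event counts scale with their rates", {
  # ~7:3 by construction at rho = 0.007, phi = 0.003 over many crypt-years
  cfg <- cohort_config(n_patients = 60, age_range = c(40, 90),
                       crypts_mean = 3e4,
                       mark_params = list(m = rate_params(rho = 0.007,
                                                          phi = 0.003,
                                                          mu_fix = 1e-4)),
                       seed = 31)
  sv <- generate_clone_survey(cfg)
  fu <- generate_fufi_survey(cfg, sv)
  nf <- sum(fu$truth$type == "fission"); nu <- sum(fu$truth$type == "fusion")
  expect_gt(nf + nu, 150)
  p <- nf / (nf + nu)
  se <- sqrt(0.7 * 0.3 / (nf + nu))
  expect_lt(abs(p - 0.7), 3 * se)
})

test_that("amplicon generator honours its contracts", {
  # zero noise, no spikes: all alternate counts zero
  np <- data.frame(position = 0:19, alt = "T", mean_maf = 0, sd_maf = 0)
  tab <- generate_amplicon_table(4, 20, noise_profile = np, seed = 2)
  expect_true(all(tab$alt_count == 0))
  expect_equal(tab$depth, tab$ref_count + tab$alt_count)
  # minimum-depth flag
  tab2 <- generate_amplicon_table(3, 20, noise_profile = np, seed = 3,
                                  depth_mean = 1200, min_depth = 1000)
  expect_true(all(tab2$depth >= 1000))
  # spiked MAF recovered within binomial error
  sp <- data.frame(sample_id = 1, position = 7, maf = 0.5)
  np2 <- data.frame(position = 0:19, alt = "T", mean_maf = 1e-3, sd_maf = 0)
  tab3 <- generate_amplicon_table(1, 20, noise_profile = np2,
                                  spiked_mutations = sp, seed = 4,
                                  depth_mean = 8000, min_depth = 5000)
  row <- tab3[tab3$position == 7, ]
  phat <- row$alt_count / row$depth
  expect_lt(abs(phat - 0.501), 3 * sqrt(0.5 * 0.5 / row$depth))
})
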