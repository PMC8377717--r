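test_that("deficit field relaxes to ambient and conserves mass", {
  h <- event_history(40, c(35, 20, 10, 2))
  # all events ancient: ambient everywhere
  s_inf <- deficit_field(h, 1.05, 0.25, r = c(0, 2, 5), t_obs = 1e7)
  expect_true(all(abs(s_inf - 0.25) < 1e-6))
  # mass conservation: integral of the perturbation equals event count
  for (np in c(4, 19)) {
    h2 <- event_history(60, sort(runif(np, 0, 60), decreasing = TRUE))
    mass <- stats::integrate(function(r)
      2 * pi * r * cryptdyn:::deficit_perturbation(h2, 1.05, r),
      0, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(mass - np) / np, 1e-3)
  }
  # single event: field at the centroid decreases with elapsed time
  h1 <- event_history(30, 5)
  s_seq <- vapply(c(0, 2, 8, 20), function(dt)
    deficit_field(h1, 1.05, 0.25, 0, t_obs = dt), numeric(1))
  expect_true(all(diff(s_seq) > 0))       # stroma recovers monotonically
})

test_that("predicted profiles are invariant under D*t rescaling", {
  h <- event_history(20, c(15, 8, 3))
  h2 <- event_history(10, c(7.5, 4, 1.5))  # halve all times
  r <- seq(0, 6, by = 0.5)
  a <- cryptdyn:::deficit_perturbation(h, 1.05, r)
  b <- cryptdyn:::deficit_perturbation(h2, 2.10, r)  # double D
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("conditioned trajectories follow the analytic conditional law", {
  # target size 2: single fission time t1 given {n(T)=2, mutation at T}
  # has density prop. to rho e^{-rho t} e^{-2 rho (T-t)} on (0, T)
  rho <- 0.05; T_age <- 30
  tr <- simulate_trajectories(1e-5, rho, T_age, 2, n_paths = 400, seed = 8)
  ages <- vapply(tr, function(h) h$mutation_time, numeric(1))
  t1 <- ages - vapply(tr, function(h) h$fission_times[1], numeric(1))
  expect_true(all(t1 >= 0 & t1 <= ages))
  # weights sum to one
  expect_equal(sum(vapply(tr, function(h) h$weight, numeric(1))), 1,
               tolerance = 1e-9)
  # analytic check: P(t1 < t | clone age tau) = (e^{rho t}-1)/(e^{rho tau}-1)
  tau <- ages
  u <- expm1(rho * t1) / expm1(rho * tau)
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("higher fission rates imply younger conditioned clones", {
  age_med <- vapply(c(0.02, 0.05, 0.12), function(rho) {
    tr <- simulate_trajectories(1e-5, rho, 70, 10, n_paths = 300,
                                seed = round(1000 * rho))
    stats::median(vapply(tr, function(h) h$mutation_time, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(age_med) < 0))
})

test_that("trajectory ranking and infeasible conditioning behave", {
  tr <- simulate_trajectories(1e-5, 0.05, 70, 6, n_paths = 60, seed = 2)
  top <- top_trajectories(tr, 10)
  expect_length(top, 10)
  lls <- vapply(tr, function(h) h$loglik, numeric(1))
  expect_equal(top[[1]]$loglik, max(lls))
  expect_warning(
    simulate_trajectories(1e-5, 1e-4, 5, 10, n_paths = 20, max_tries = 3),
    "empty-ensemble|paths")
})

test_that("stromal measurement recovers the generator's ambient fraction", {
  kd <- rate_params(rho = 0.036, d_coef = 1e5, s0 = 0.25)
  vals <- unlist(lapply(1:3, function(i) {
    m <- generate_spatial_map(kd, clone_age = 40, patch_size = 10,
                              seed = 1100 + i)
    c(stromal_fraction(m, "patch"),
      stromal_fraction(m, "control_1"),
      stromal_fraction(m, "control_2"),
      stromal_fraction(m, "control_3"))
  }))
  expect_lt(abs(mean(vals) - 0.25), 0.02)
  # shrinking every crypt raises the stromal fraction (monotone contract)
  m <- generate_spatial_map(kd, clone_age = 40, patch_size = 10, seed = 1200)
  m2 <- m; m2$area <- m$area / 2
  expect_gt(stromal_fraction(m2, "patch"), stromal_fraction(m, "patch"))
  expect_error(stromal_fraction(m[1:2, ], group = c(TRUE, TRUE)), "at least 3")
})

test_that("radial profiles are flat for relaxed clones, dipped for young", {
  kd_flat <- rate_params(rho = 0.036, d_coef = 1e5, s0 = 0.265)
  m <- generate_spatial_map(kd_flat, clone_age = 40, patch_size = 10,
                            seed = 21)
  pr <- radial_profile(m)
  expect_true(!is.unsorted(pr$r))          # windows ordered by distance
  win <- pr[pr$kind == "window", ]
  fit <- stats::lm(stromal_fraction ~ r, data = win)
  expect_gt(summary(fit)$coefficients["r", 4], 0.01)  # no radial trend
  # young clones: centre below far field (one-sided test over maps)
  kd <- rate_params(rho = 0.036, d_coef = 1.05, s0 = 0.265)
  diffs <- vapply(1:6, function(i) {
    my <- generate_spatial_map(kd, clone_age = 15, patch_size = 10,
                               seed = 1300 + i)
    p <- radial_profile(my)
    p$stromal_fraction[1] - mean(p$stromal_fraction[p$r > max(p$r) * 0.6])
  }, numeric(1))
  expect_lt(t.test(diffs, alternative = "less")$p.value, 0.05)
})

test_that("diffusion coefficient is recovered within a factor of three", {
  maps <- fixture_maps(12, seed = 3000)
  fit <- infer_diffusion(maps, mu_fix = 6.04e-6, rho = 0.036,
                         n_draws = 60, seed = 5)
  expect_gt(fit$d_coef, 1.05 / 3)
  expect_lt(fit$d_coef, 1.05 * 3)
  expect_true(fit$ci_low <= fit$d_coef && fit$d_coef <= fit$ci_high)
})

test_that("flat maps leave the diffusion likelihood uninformative", {
  maps <- fixture_maps(4, seed = 3100, clone_age = 35, d_coef = 1e5)
  fit <- infer_diffusion(maps, mu_fix = 6.04e-6, rho = 0.036,
                         n_draws = 30, seed = 6)
  # ensemble spans a wide range of d rather than concentrating
  expect_gt(fit$ci_high / fit$ci_low, 3)
})

test_that("null comparison detects radial structure and stays calibrated", {
  maps_y <- fixture_maps(6, seed = 3200, clone_age = 15)
  nf <- null_ambient_fit(maps_y, mu_fix = 6.04e-6, rho = 0.036,
                         n_perm = 49, seed = 4)
  expect_lt(nf$p_value, 0.05)
  expect_gt(nf$delta_sse, 0)
  # null calibration: flat maps should rarely reject
  pv <- vapply(1:8, function(r) {
    maps_f <- fixture_maps(4, seed = 3300 + 10 * r, clone_age = 35,
                           d_coef = 1e5)
    null_ambient_fit(maps_f, mu_fix = 6.04e-6, rho = 0.036,
                     n_perm = 19, seed = r)$p_value
  }, numeric(1))
  expect_lte(mean(pv <= 0.05), 0.25)
})

test_that("crypt shape statistics read the generator truth", {
  kd <- rate_params(rho = 0.036, d_coef = 1e5, s0 = 0.265)
  # identical mutant and wild-type crypts: ratio ~ 1, p not small
  ps <- vapply(1:5, function(i) {
    m <- generate_spatial_map(kd, clone_age = 60, patch_size = 10,
                              seed = 1400 + i)
    st <- crypt_shape_stats(m, n_perm = 199, seed = i)
    expect_lt(abs(st$area_ratio - 1), 0.12)
    st$area_p
  }, numeric(1))
  expect_gte(sum(ps >= 0.05), 4)
  # generator ratio 1.3 recovered
  rats <- vapply(1:4, function(i) {
    m <- generate_spatial_map(kd, clone_age = 60, patch_size = 10,
                              seed = 1500 + i, area_ratio = 1.3)
    crypt_shape_stats(m, n_perm = 99, seed = i)$area_ratio
  }, numeric(1))
  expect_lt(abs(mean(rats) - 1.3), 0.05)
  # circular crypts have eccentricity zero
  m <- generate_spatial_map(kd, clone_age = 60, patch_size = 10, seed = 1600)
  m$axis_ratio <- 1
  st <- crypt_shape_stats(m, n_perm = 19)
  expect_true(all(st$eccentricity == 0))
})

test_that("domain accommodation counts obey area conservation", {
  # calibration reproducing the worked example: 264 at 1% implies 53 at 5%
  expect_equal(domains_affected(10, 0.01, s0 = 0.264), 264L)
  expect_lte(abs(domains_affected(10, 0.05, s0 = 0.264) - 53L), 1)
  # count x fraction constant across fractions
  d1 <- domains_affected(10, 0.01, s0 = 0.265)
  d5 <- domains_affected(10, 0.05, s0 = 0.265)
  expect_lt(abs(d1 * 0.01 - d5 * 0.05), 0.05)
  # limit: fraction -> 1 returns the rounded-up area demand
  expect_equal(domains_affected(10, 0.999, s0 = 0.265),
               as.integer(ceiling(10 * 0.265 / 0.999)))
  expect_error(domains_affected(10, 0), "reduction_fraction")
})
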