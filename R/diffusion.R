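#' Event history of a clone (mutation plus fission times)
#'
#' Times are expressed in years before the observation instant (decreasing
#' toward observation). A clone observed as a patch of `k` crypts carries
#' `k - 1` fission events.
#'
#' @param mutation_time Years before observation of the founding mutation.
#' @param fission_times Numeric vector, years before observation of each
#'   fission.
#' @param weight Likelihood weight of the path within its ensemble.
#' @param loglik Optional conditional log-density of the path (for ranking).
#' @export
event_history <- function(mutation_time, fission_times, weight = 1,
                          loglik = NA_real_) {
  stopifnot(mutation_time >= 0, all(fission_times >= 0),
            all(fission_times <= mutation_time + 1e-9))
  structure(list(mutation_time = mutation_time,
                 fission_times = sort(fission_times, decreasing = TRUE),
                 weight = weight, loglik = loglik),
            class = "event_history")
}

# Perturbation predicted for each profile row: averaged over the window's
# member radii when available (matching how the observable is measured),
# else evaluated at the row's mean radius.
predict_window_P <- function(history, d, profile, sigma0_sq = 1) {
  mem <- attr(profile, "members_r")
  if (is.null(mem))
    return(deficit_perturbation(history, d, profile$r_domain_lengths,
                                sigma0_sq = sigma0_sq))
  rr <- unlist(mem, use.names = FALSE)
  idx <- rep(seq_along(mem), lengths(mem))
  P <- deficit_perturbation(history, d, rr, sigma0_sq = sigma0_sq)
  as.numeric(rowsum(P, idx) / tabulate(idx))
}

# Raw crypt-coverage perturbation (dimensionless) of a fission history at
# radial distance r (crypt-domain lengths, where one length^2 = one domain
# area). Each fission contributes a 2-D Gaussian kernel of unit domain-area
# mass with per-axis variance v = 2*(2*D*dt + sigma0_sq); sigma0_sq
# pre-spreads newborn mass over one crypt domain.
deficit_perturbation <- function(history, d_coef, r, t_obs = 0,
                                 sigma0_sq = 1) {
  dts <- history$fission_times + t_obs
  if (!length(dts)) return(rep(0, length(r)))
  v <- 2 * (2 * d_coef * dts + sigma0_sq)
  colSums(exp(-outer(1 / (2 * v), r^2)) / (2 * pi * v))
}

#' Local stromal fraction around a clone under the crypt-diffusion model
#'
#' Growth of a patch is modelled as a stochastically firing point source of
#' crypt mass at the clone centroid: each fission injects one crypt-domain
#' area of mass, which then disperses as a 2-D heat kernel with per-axis
#' variance `2 * (2 * d_coef * dt + sigma0_sq)` (`dt` years since the event;
#' `sigma0_sq`, one domain area, regularizes the newborn crypt's own
#' footprint). The local stromal fraction is the ambient value minus the
#' crypt-coverage excess: `s0 - perturbation * (1 - s0)`, floored at 0.
#'
#' @param history An [event_history()].
#' @param d_coef Diffusion coefficient, crypt-domain areas per year (> 0).
#' @param s0 Ambient stromal fraction.
#' @param r Radial distance(s) from the clone centroid, in crypt-domain
#'   lengths (one length^2 = one domain area).
#' @param t_obs Extra years elapsed after the history's observation instant.
#' @param sigma0_sq Newborn-mass regularization variance (domain areas).
#' @return Stromal fraction at each `r`.
#' @export
deficit_field <- function(history, d_coef, s0, r, t_obs = 0, sigma0_sq = 1) {
  stopifnot(d_coef > 0, s0 > 0, s0 < 1)
  P <- deficit_perturbation(history, d_coef, r, t_obs, sigma0_sq)
  pmax(0, s0 - P * (1 - s0))
}

#' Sample clone trajectories conditioned on observed patch size
#'
#' Rejection-samples (mutation time, fission times) for a clone that is
#' exactly `target_size` crypts when the patient is observed at
#' `patient_age`: the mutation time is uniform over life (constant fixation
#' rate) and growth is pure-birth at rate `rho` per crypt. Accepted paths
#' are exact draws from the conditional law, so weights are uniform; the
#' conditional log-density is attached for "most likely trajectory"
#' summaries.
#'
#' @param mu_fix Fixation rate (enters only through the uniform mutation
#'   timing; kept explicit for interface clarity).
#' @param rho Fission rate per crypt per year.
#' @param patient_age Observation age (years).
#' @param target_size Patch size at observation (>= 2).
#' @param n_paths Ensemble size.
#' @param seed Integer seed.
#' @param max_tries Max rejection batches before giving up.
#' @return List of [event_history()]; empty (with a warning) if conditioning
#'   is infeasible at these rates.
#' @export
simulate_trajectories <- function(mu_fix, rho, patient_age, target_size,
                                  n_paths = 200, seed = 1L,
                                  max_tries = 400) {
  stopifnot(target_size >= 2, rho > 0, patient_age > 0)
  set.seed(seed)
  k <- as.integer(target_size)
  out <- vector("list", n_paths)
  got <- 0L
  for (try in seq_len(max_tries)) {
    B <- 2000L
    tt <- patient_age - stats::runif(B, 0, patient_age)  # clone age
    G <- matrix(stats::rexp(B * k), B, k)
    G <- sweep(G, 2, rho * seq_len(k), "/")              # gap j: Exp(j rho)
    cum <- t(apply(G, 1, cumsum))
    ok <- cum[, k - 1] <= tt & tt < cum[, k]
    idx <- which(ok)
    for (i in idx) {
      if (got >= n_paths) break
      got <- got + 1L
      ev <- tt[i] - cum[i, seq_len(k - 1)]               # years before obs
      ll <- sum(log(rho * seq_len(k - 1)) - rho * seq_len(k - 1) * G[i, seq_len(k - 1)]) -
        rho * k * (tt[i] - cum[i, k - 1])
      out[[got]] <- event_history(tt[i], ev, weight = 1 / n_paths,
                                  loglik = ll)
    }
    if (got >= n_paths) break
  }
  if (got < n_paths) {
    warning("trajectory conditioning yielded only ", got, " of ", n_paths,
            " paths (empty-ensemble warning)")
    out <- out[seq_len(got)]
  }
  out
}

#' Rank trajectories by conditional likelihood
#'
#' @param trajectories List of [event_history()].
#' @param n Keep the `n` most likely (default 25, the ensemble summary used
#'   for overlay curves).
#' @export
top_trajectories <- function(trajectories, n = 25) {
  ll <- vapply(trajectories, function(h) h$loglik, numeric(1))
  trajectories[order(ll, decreasing = TRUE)][seq_len(min(n, length(trajectories)))]
}

#' Infer the crypt diffusion coefficient from spatial maps
#'
#' For each ensemble draw, one event history per patch is sampled from its
#' conditional trajectory ensemble; the diffusion coefficient minimizing the
#' squared error between [deficit_field()] predictions and the observed
#' radial stromal-fraction profiles is found (ambient `s0` fitted per patch
#' neighbourhood, linear given the perturbation). Repeating over draws
#' yields the ensemble distribution of `d`; the fit reports its median and
#' 2.5/97.5 percentiles.
#'
#' @param maps List of spatial crypt maps ([generate_spatial_map()] or maps
#'   with the same columns).
#' @param trajectories List (one element per map) of trajectory ensembles
#'   from [simulate_trajectories()]; if `NULL`, ensembles are simulated from
#'   each map's `patient_age` attribute.
#' @param mu_fix,rho Rates used to simulate trajectory ensembles.
#' @param n_draws Ensemble draws.
#' @param window_size Rolling-window size for [radial_profile()].
#' @param d_interval Search interval for `d` (domain areas per year).
#' @param sigma0_sq Kernel regularization (domain areas).
#' @param n_paths Trajectory ensemble size per map when simulating here.
#' @param seed Integer seed.
#' @return Object of class `diffusion_fit`: list with `d_coef` (ensemble
#'   median), `ci_low`, `ci_high`, `s0` (mean fitted ambient fraction),
#'   `ensemble` (all per-draw `d` values).
#' @export
infer_diffusion <- function(maps, trajectories = NULL, mu_fix = 1e-5,
                            rho = 0.036, n_draws = 200, window_size = 10,
                            d_interval = c(0.01, 50), sigma0_sq = 1,
                            n_paths = 100, seed = 1L) {
  stopifnot(length(maps) >= 2)
  set.seed(seed)
  profs <- lapply(maps, function(m) radial_profile(m, window_size))
  if (is.null(trajectories)) {
    trajectories <- lapply(seq_along(maps), function(i) {
      age <- attr(maps[[i]], "patient_age")
      if (is.null(age)) age <- 70
      ps <- sum(maps[[i]]$group == "patch")
      simulate_trajectories(mu_fix, rho, age, ps, n_paths = n_paths,
                            seed = seed + i)
    })
  }
  sse_draw <- function(logd, pick) {
    d <- exp(logd)
    tot <- 0
    for (i in seq_along(maps)) {
      pr <- profs[[i]]
      P <- predict_window_P(trajectories[[i]][[pick[i]]], d, pr, sigma0_sq)
      x <- 1 + P                       # s = s0*(1+P) - P, linear in s0
      s0 <- sum(x * (pr$stromal_fraction + P)) / sum(x^2)
      s0 <- min(max(s0, 0.01), 0.99)
      tot <- tot + sum((pr$stromal_fraction - (s0 * x - P))^2)
    }
    tot
  }
  ens <- numeric(n_draws)
  s0s <- numeric(n_draws)
  for (b in seq_len(n_draws)) {
    pick <- vapply(trajectories, function(tr) sample.int(length(tr), 1),
                   integer(1))
    o <- stats::optimize(sse_draw, log(d_interval), pick = pick, tol = 1e-3)
    ens[b] <- exp(o$minimum)
  }
  qs <- stats::quantile(ens, c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(d_coef = qs[2], ci_low = qs[1], ci_high = qs[3],
                 s0 = NA_real_, ensemble = ens,
                 profiles = profs, trajectories = trajectories,
                 sigma0_sq = sigma0_sq),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "Crypt diffusion coefficient: %.3g domain areas/yr (ensemble 95%% %.3g-%.3g)\n",
    x$d_coef, x$ci_low, x$ci_high))
  invisible(x)
}

#' Compare the diffusion model with a no-radial-dependence null
#'
#' Fits a constant-stromal-fraction model per patch neighbourhood and
#' reports the improvement in summed squared error achieved by the diffusion
#' model, with a permutation p-value obtained by shuffling stromal fractions
#' across windows within each map (destroying any radial dependence while
#' preserving the marginal distribution).
#'
#' @inheritParams infer_diffusion
#' @param fit Optional [infer_diffusion()] result to reuse.
#' @param n_perm Number of permutations.
#' @return List with `sse_null`, `sse_diffusion`, `delta_sse`, `p_value`.
#' @export
null_ambient_fit <- function(maps, trajectories = NULL, mu_fix = 1e-5,
                             rho = 0.036, fit = NULL, n_perm = 99,
                             window_size = 10, sigma0_sq = 1, seed = 1L) {
  if (is.null(fit))
    fit <- infer_diffusion(maps, trajectories, mu_fix, rho,
                           n_draws = 40, window_size = window_size,
                           sigma0_sq = sigma0_sq, seed = seed)
  set.seed(seed + 7L)
  # non-overlapping windows: overlapping ones share crypts, so their noise is
  # autocorrelated and would not be exchangeable under permutation
  profs <- lapply(maps, function(m)
    radial_profile(m, window_size, stride = window_size))
  trajs <- fit$trajectories
  sse_d <- function(logd, profs) {
    tot <- 0
    for (i in seq_along(profs)) {
      pr <- profs[[i]]
      P <- predict_window_P(trajs[[i]][[1]], exp(logd), pr, sigma0_sq)
      x <- 1 + P
      s0 <- sum(x * (pr$stromal_fraction + P)) / sum(x^2)
      tot <- tot + sum((pr$stromal_fraction - (s0 * x - P))^2)
    }
    tot
  }
  sse_pair <- function(profs) {
    sse0 <- sum(vapply(profs, function(pr)
      sum((pr$stromal_fraction - mean(pr$stromal_fraction))^2), numeric(1)))
    # d re-optimized on every data set (including permuted ones), so the
    # model-selection advantage is shared by the null distribution
    sse1 <- stats::optimize(sse_d, log(c(0.01, 50)), profs = profs,
                            tol = 1e-2)$objective
    c(sse0, sse1)
  }
  obs <- sse_pair(profs)
  delta <- obs[1] - obs[2]
  perm <- replicate(n_perm, {
    pp <- lapply(profs, function(pr) {
      pr$stromal_fraction <- sample(pr$stromal_fraction)
      pr
    })
    d <- sse_pair(pp)
    d[1] - d[2]
  })
  list(sse_null = obs[1], sse_diffusion = obs[2], delta_sse = delta,
       p_value = (1 + sum(perm >= delta)) / (n_perm + 1))
}

#' Crypt domains affected by absorbing a mutant patch
#'
#' By conservation of ceded area, accommodating a patch whose spacing demand
#' is `patch_size * s0` crypt-domain areas requires
#' `ceiling(patch_size * s0 / reduction_fraction)` surrounding domains to
#' each cede `reduction_fraction` of their area. The product
#' `count * reduction_fraction` is therefore constant for a given patch.
#'
#' @param patch_size Crypts in the mutant patch.
#' @param reduction_fraction Fractional spacing reduction per affected
#'   domain, in (0, 1).
#' @param s0 Ambient stromal fraction (the stroma share of each domain).
#' @return Integer count of affected crypt domains.
#' @examples
#' domains_affected(10, 0.01, s0 = 0.264)  # 264
#' domains_affected(10, 0.05, s0 = 0.264)  # 53
#' @export
domains_affected <- function(patch_size, reduction_fraction, s0 = 0.265) {
  stopifnot(patch_size >= 1, reduction_fraction > 0, reduction_fraction < 1,
            s0 > 0, s0 < 1)
  as.integer(ceiling(patch_size * s0 / reduction_fraction))
}
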