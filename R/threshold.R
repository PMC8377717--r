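#' Whitespace fraction of optimal hexagonal circle packing
#'
#' The stromal fraction remaining when circular crypt sections are packed at
#' the hexagonal optimum: `1 - pi / (2 * sqrt(3))`. Below this floor crypts
#' would be directly touching, so it serves as the lesion threshold.
#'
#' @return A number in (0, 1), approximately 0.09310.
#' @export
hexagonal_whitespace <- function() 1 - pi / (2 * sqrt(3))

#' Configuration for the lesion-threshold simulation
#'
#' @param fission_multiple Fold-increase `k` over the homeostatic fission
#'   rate (clone rate = `k * rho0` per crypt per year).
#' @param rho0 Homeostatic fission rate (default 0.007/yr).
#' @param d_coef Crypt diffusion coefficient (domain areas per year).
#' @param s0 Ambient stromal fraction.
#' @param horizon Simulation horizon in years.
#' @param intervention `NULL`, or `list(start, duration, mode)` with mode
#'   `"zero"` (complete fission inhibition) or `"baseline"` (rate reduced to
#'   the homeostatic value) applied inside the window.
#' @param n_reps Monte-Carlo replicates.
#' @param seed Integer seed.
#' @param max_size Clone size through which the passage is simulated (the
#'   point-source model is evaluated at the measured 10-crypt patch scale).
#' @param sigma0_sq Kernel regularization (domain areas).
#' @param threshold_s Stromal fraction at which a lesion is declared
#'   (default [hexagonal_whitespace()]).
#' @return Object of class `lesion_sim_config`.
#' @export
lesion_sim_config <- function(fission_multiple = 1, rho0 = 0.007,
                              d_coef = 1.05, s0 = 0.265, horizon = 90,
                              intervention = NULL, n_reps = 1e5, seed = 1L,
                              max_size = 10, sigma0_sq = 1,
                              threshold_s = hexagonal_whitespace()) {
  stopifnot(fission_multiple >= 0, rho0 >= 0, d_coef > 0, horizon > 0,
            s0 > 0, s0 < 1, n_reps >= 1, max_size >= 2)
  if (!is.null(intervention)) {
    stopifnot(is.list(intervention),
              intervention$start >= 0,
              intervention$duration > 0,
              intervention$start + intervention$duration <= horizon + 1e-9)
    if (is.null(intervention$mode)) intervention$mode <- "zero"
    stopifnot(intervention$mode %in% c("zero", "baseline"))
  }
  structure(list(fission_multiple = fission_multiple, rho0 = rho0,
                 d_coef = d_coef, s0 = s0, horizon = horizon,
                 intervention = intervention, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), max_size = as.integer(max_size),
                 sigma0_sq = sigma0_sq, threshold_s = threshold_s),
            class = "lesion_sim_config")
}

# Map cumulative fission exposure to calendar time under an intervention
# window where the rate is multiplied by `mult` (0 for "zero", 1/k for
# "baseline"); outside the window the multiplier is 1.
exposure_to_time <- function(E, start, duration, mult) {
  Ewin <- mult * duration                 # exposure accrued inside the window
  ifelse(E < start, E,
         ifelse(E < start + Ewin,
                if (mult > 0) start + (E - start) / mult else Inf,
                E - Ewin + duration))
}

#' Simulate clone growth to the lesion threshold under crypt diffusion
#'
#' Each replicate clone starts as one crypt at `t = 0` and fissions by
#' Gillespie at rate `k * rho0 * n(t)` through the 10-crypt passage scale.
#' Every fission injects one crypt-domain area of mass at the clone centroid
#' which disperses under the [deficit_field()] kernel. A lesion is declared
#' the first time a new crypt arrives while the pre-existing deficit already
#' holds the local stromal fraction at or below `threshold_s`: the tissue
#' has no stroma left to cede, so the newly generated crypt cannot be
#' accommodated.
#'
#' @param config A [lesion_sim_config()].
#' @return Object of class `lesion_sim_result`: `lesion_times` (years, `Inf`
#'   if censored at the horizon), `cum_prob` (data frame `year`, `prob`,
#'   `ci_low`, `ci_high` with Wilson intervals), `threshold_s`, `config`.
#' @export
simulate_clone_lesion <- function(config) {
  stopifnot(inherits(config, "lesion_sim_config"))
  set.seed(config$seed)
  a <- config$fission_multiple * config$rho0
  m <- config$max_size - 1L
  n <- config$n_reps
  thr <- config$threshold_s
  # degenerate: ambient tissue already at/below the declared threshold
  if (config$s0 <= thr || a == 0) {
    bt <- if (config$s0 <= thr) rep(0, n) else rep(Inf, n)
    return(lesion_result(bt, config))
  }
  gaps <- sweep(matrix(stats::rexp(n * m), n, m), 2, a * seq_len(m), "/")
  Tev <- gaps
  for (j in seq_len(m)[-1]) Tev[, j] <- Tev[, j - 1] + gaps[, j]
  iv <- config$intervention
  if (!is.null(iv)) {
    mult <- if (iv$mode == "zero") 0 else 1 / max(config$fission_multiple, 1)
    Tev <- exposure_to_time(Tev, iv$start, iv$duration, mult)
  }
  # maximum excess coverage the ambient stroma can absorb
  Pstar <- (config$s0 - thr) / (1 - config$s0)
  Kpeak <- 1 / (2 * pi * 2 * config$sigma0_sq)
  btime <- rep(Inf, n)
  for (j in seq_len(m)[-1]) {
    P <- 0
    for (i in seq_len(j - 1)) {
      tau <- Tev[, j] - Tev[, i]
      P <- P + 1 / (2 * pi * 2 * (2 * config$d_coef * tau + config$sigma0_sq))
    }
    hit <- is.infinite(btime) & P >= Pstar & is.finite(Tev[, j])
    btime[hit] <- Tev[hit, j]
  }
  lesion_result(btime, config)
}

lesion_result <- function(btime, config) {
  yrs <- seq(0, config$horizon, by = 1)
  n <- length(btime)
  cp <- vapply(yrs, function(y) mean(btime <= y), numeric(1))
  ci <- wilson_ci(cp * n, n)
  res <- list(lesion_times = ifelse(btime <= config$horizon, btime, Inf),
              cum_prob = data.frame(year = yrs, prob = cp,
                                    ci_low = ci[, 1], ci_high = ci[, 2]),
              threshold_s = config$threshold_s,
              prob_at_horizon = cp[length(cp)],
              mc_se = sqrt(cp[length(cp)] * (1 - cp[length(cp)]) / n),
              config = config)
  class(res) <- "lesion_sim_result"
  res
}

# Wilson score interval for x successes out of n.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(pmax(ctr - hw, 0), pmin(ctr + hw, 1))
}

#' @export
print.lesion_sim_result <- function(x, ...) {
  cat(sprintf(
    "lesion simulation: k = %.1f, %.3g reps; P(lesion by %gy) = %.4g (MC se %.2g)\n",
    x$config$fission_multiple, x$config$n_reps, x$config$horizon,
    x$prob_at_horizon, x$mc_se))
  invisible(x)
}

#' Smallest fission multiple that breaches the lesion criterion
#'
#' Runs [simulate_clone_lesion()] over an ascending grid of fission
#' multiples and returns the smallest whose cumulative lesion probability at
#' `criterion_year` exceeds `criterion_prob`.
#'
#' @param config_base A [lesion_sim_config()] used as template.
#' @param k_grid Ascending fission multiples to scan.
#' @param criterion_prob Probability criterion (default 1e-3).
#' @param criterion_year Evaluation age (default 90 years).
#' @return List with `k` (smallest breaching multiple, `NA` if none within
#'   the grid), and `probs`, the per-multiple probabilities.
#' @export
find_threshold_multiple <- function(config_base, k_grid = 8:20,
                                    criterion_prob = 1e-3,
                                    criterion_year = 90) {
  stopifnot(!is.unsorted(k_grid))
  probs <- numeric(length(k_grid))
  for (i in seq_along(k_grid)) {
    cfg <- config_base
    cfg$fission_multiple <- k_grid[i]
    cfg$seed <- config_base$seed + i
    res <- simulate_clone_lesion(cfg)
    probs[i] <- res$cum_prob$prob[res$cum_prob$year == criterion_year]
    if (!length(probs[i])) probs[i] <- res$prob_at_horizon
  }
  hit <- which(probs > criterion_prob)
  list(k = if (length(hit)) k_grid[hit[1]] else NA_real_,
       none_within_grid = !length(hit),
       probs = stats::setNames(probs, k_grid))
}

#' Lesion probability under decade-long fission-inhibition windows
#'
#' Compares the cumulative lesion probability at `at_year` with no
#' intervention and with complete fission inhibition applied during each
#' window. The replicate count is auto-scaled so the smallest probability
#' is supported by at least `min_events` expected lesion events (capped at
#' `max_reps`).
#'
#' @param config A [lesion_sim_config()] (typically `fission_multiple = 17`).
#' @param windows List of `c(start, end)` year pairs.
#' @param at_year Evaluation age.
#' @param min_events Minimum expected lesion events per row.
#' @param max_reps Replicate cap.
#' @return Data frame (`window`, `prob`, `ci_low`, `ci_high`, `n_reps`).
#' @export
intervention_comparison <- function(config,
                                    windows = list(c(0, 10), c(10, 20), c(20, 30)),
                                    at_year = 50, min_events = 20,
                                    max_reps = 2e6) {
  run <- function(iv, n_reps, seed_off) {
    cfg <- config
    cfg$horizon <- max(config$horizon, at_year)
    cfg$intervention <- iv
    cfg$n_reps <- as.integer(n_reps)
    cfg$seed <- config$seed + seed_off
    res <- simulate_clone_lesion(cfg)
    res$cum_prob[res$cum_prob$year == at_year, ]
  }
  rows <- list()
  base <- run(NULL, config$n_reps, 0L)
  rows[["none"]] <- base
  for (w in seq_along(windows)) {
    iv <- list(start = windows[[w]][1],
               duration = diff(windows[[w]]), mode = "zero")
    first <- run(iv, config$n_reps, w)
    p <- max(first$prob, 0.5 / config$n_reps)
    need <- min(max_reps, ceiling(min_events / p))
    if (need > config$n_reps) first <- run(iv, need, 100L + w)
    rows[[sprintf("%d-%d", windows[[w]][1], windows[[w]][2])]] <- first
  }
  out <- do.call(rbind, rows)
  data.frame(window = names(rows), prob = out$prob,
             ci_low = out$ci_low, ci_high = out$ci_high,
             row.names = NULL)
}
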