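#' Patch-size distribution of a clone growing by crypt fission
#'
#' A monoclonal patch founded by a single crypt and growing by fission at a
#' constant per-crypt rate follows a pure-birth (Yule) process, so after
#' `clone_age` years its size is geometric:
#' \deqn{P(K = k) = e^{-\rho t}\,(1 - e^{-\rho t})^{k-1},\qquad k \ge 1.}
#'
#' @param rho Fission rate per crypt per year (>= 0).
#' @param clone_age Age of the clone in years (time since fixation).
#' @param k Patch size(s), integer >= 1.
#' @param log Return log-probabilities?
#' @return Probability (or log-probability) of each size in `k`.
#' @examples
#' yule_patch_pmf(0.036, 19.25, 1)   # ~0.5: the median 1->2 transition
#' sum(yule_patch_pmf(0.05, 40, 1:500))
#' @export
yule_patch_pmf <- function(rho, clone_age, k, log = FALSE) {
  stopifnot(is.numeric(rho), rho >= 0, is.finite(rho),
            is.numeric(clone_age), clone_age >= 0)
  if (any(k < 1 | k != floor(k))) stop("patch size k must be an integer >= 1")
  p <- exp(-rho * clone_age)               # success probability of the geometric
  lp <- log(p) + (k - 1) * log1p(-p)
  lp[k == 1 & p == 1] <- 0                 # rho*t = 0: all mass at size 1
  if (log) lp else exp(lp)
}

#' Patch-size distribution marginalized over uniform mutation timing
#'
#' For a patient of age `T`, a surviving clone fixed at a uniformly
#' distributed time `s ~ U(0, T)` has size distribution
#' \deqn{q_k(\rho, T) = \frac{1}{T}\int_0^T e^{-\rho u}(1-e^{-\rho u})^{k-1}
#'  \,du = \frac{(1 - e^{-\rho T})^k}{k\,\rho\,T},}
#' the closed form used by the fission-rate likelihood.
#'
#' @inheritParams yule_patch_pmf
#' @param age Patient age in years (> 0).
#' @return Probability (or log) of each size in `k`.
#' @export
yule_size_marginal <- function(rho, age, k, log = FALSE) {
  stopifnot(rho >= 0, age > 0)
  if (any(k < 1 | k != floor(k))) stop("patch size k must be an integer >= 1")
  if (rho == 0) {
    lp <- ifelse(k == 1, 0, -Inf)
  } else {
    x <- -expm1(-rho * age)                # 1 - e^{-rho T}
    lp <- k * log(x) - log(k) - log(rho * age)
  }
  if (log) lp else exp(lp)
}

#' Simulate pure-birth patch sizes
#'
#' @param n Number of clones.
#' @param rho Fission rate per crypt per year.
#' @param clone_age Clone age(s) in years (recycled).
#' @return Integer vector of patch sizes.
#' @export
ryule <- function(n, rho, clone_age) {
  p <- exp(-rho * clone_age)
  1L + stats::rgeom(n, p)
}

#' Waiting times for patch-size transitions
#'
#' With `from_size` crypts all firing independently at rate `rho`, the wait to
#' the next fission is exponential with rate `from_size * rho`; its median is
#' `log(2) / (from_size * rho)`. At the fission rate associated with KDM6A
#' loss (3.6%/yr) the median 1 -> 2 transition takes 19 years but 10 -> 11
#' takes only 2, which is why recently formed large patches are the place to
#' look for local crowding.
#'
#' @param rho Fission rate per crypt per year.
#' @param from_size Current patch size (>= 1).
#' @return List with `median` (years), `mean`, `rate`, and `quantile(p)`,
#'   the exponential quantile function. `rho = 0` returns infinite times
#'   with `infinite_time = TRUE`.
#' @examples
#' round(transition_time_stats(0.036, 1)$median)   # 19
#' round(transition_time_stats(0.036, 10)$median)  # 2
#' @export
transition_time_stats <- function(rho, from_size) {
  stopifnot(from_size >= 1, from_size == floor(from_size), rho >= 0)
  if (rho == 0) {
    return(list(median = Inf, mean = Inf, rate = 0,
                quantile = function(p) ifelse(p > 0, Inf, 0),
                infinite_time = TRUE))
  }
  r <- from_size * rho
  list(median = log(2) / r, mean = 1 / r, rate = r,
       quantile = function(p) stats::qexp(p, rate = r),
       infinite_time = FALSE)
}

#' Infer the crypt fission rate from age-stratified patch sizes
#'
#' Maximizes the likelihood of the observed patch-size histograms under the
#' pure-birth model with mutation timing marginalized uniformly over each
#' patient's life ([yule_size_marginal]). The per-crypt fixation rate enters
#' only through the (Poisson) number of clones and cancels from the
#' conditional size likelihood, so it is treated as a nuisance. The 95% CI is
#' a profile-likelihood interval (chi-square cutoff 3.84).
#'
#' @param survey A `clone_survey` object or a data frame of patches with
#'   columns `age`, `size`, `count`.
#' @param mu_fix Fixation rate per crypt per year (nuisance; kept for
#'   interface compatibility, may be `NULL`).
#' @param rho_max Upper bound of the search interval (per year).
#' @param profile_points Number of points in the returned likelihood profile.
#' @return Object of class `fission_estimate`: list with `rho`, `ci_low`,
#'   `ci_high` (per year) and `loglik_profile` (data frame `rho`, `loglik`).
#' @export
infer_fission_rate <- function(survey, mu_fix = NULL, rho_max = 0.5,
                               profile_points = 60) {
  patches <- as_patch_table(survey)
  if (nrow(patches) == 0 || sum(patches$count) == 0)
    stop("no patches observed; fission rate is not identifiable")
  if (length(unique(patches$age)) < 2 && length(unique(patches$size)) < 2)
    warning("patch data span a single age and size; estimate may be weak")
  ll <- function(rho) {
    sum(patches$count *
          yule_size_marginal(rho, patches$age, patches$size, log = TRUE))
  }
  opt <- stats::optimize(ll, interval = c(1e-8, rho_max), maximum = TRUE,
                         tol = 1e-7)
  rho_hat <- opt$maximum
  ll_max <- opt$objective
  # all patches size 1: MLE is at the boundary rho = 0
  if (all(patches$size == 1)) {
    rho_hat <- 0
    ll_max <- ll(1e-12)
  }
  cut <- ll_max - stats::qchisq(0.95, df = 1) / 2
  lo <- if (rho_hat <= 1e-8 || ll(1e-8) >= cut) 0 else
    stats::uniroot(function(r) ll(r) - cut, c(1e-8, rho_hat))$root
  hi <- if (ll(rho_max) >= cut) rho_max else
    stats::uniroot(function(r) ll(r) - cut, c(max(rho_hat, 1e-8), rho_max))$root
  grid <- seq(max(lo * 0.5, 1e-4), min(hi * 1.5, rho_max), length.out = profile_points)
  prof <- data.frame(rho = grid, loglik = vapply(grid, ll, numeric(1)))
  structure(list(rho = rho_hat, ci_low = lo, ci_high = hi,
                 loglik = ll_max, loglik_profile = prof),
            class = "fission_estimate")
}

#' @export
print.fission_estimate <- function(x, ...) {
  cat(sprintf("Crypt fission rate: %.3f%%/yr (95%% profile CI %.3f-%.3f)\n",
              100 * x$rho, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Fraction of clones found as patches above a size cutoff
#'
#' Integrates the uniform-timing size marginal: the probability a surviving
#' clone in a patient of the given age comprises more than `min_size` crypts.
#'
#' @inheritParams yule_size_marginal
#' @param min_size Size cutoff (fraction counts sizes strictly greater).
#' @param mu_fix Unused (clone count cancels); kept for interface symmetry.
#' @export
predict_large_patch_fraction <- function(rho, mu_fix = NULL, age, min_size) {
  stopifnot(age > 0, min_size >= 0)
  if (rho == 0) return(if (min_size >= 1) 0 else 1)
  if (min_size == 0) return(1)
  1 - sum(yule_size_marginal(rho, age, seq_len(min_size)))
}

#' Expected number of fission-added crypts
#'
#' Expected crypts added by fission (in excess of each fixed clone's founding
#' crypt) per `per` crypts of epithelium by the given age:
#' \deqn{per \cdot \mu_{fix} \int_0^T (e^{\rho(T-s)} - 1)\,ds
#'   = per \cdot \mu_{fix}\left(\frac{e^{\rho T}-1}{\rho} - T\right).}
#'
#' @param rho Fission rate per crypt per year.
#' @param mu_fix Mutation-fixation rate per crypt per year.
#' @param age Patient age in years.
#' @param per Reference crypt count (default 1e5).
#' @export
expected_new_crypts <- function(rho, mu_fix, age, per = 1e5) {
  stopifnot(rho >= 0, mu_fix >= 0, age >= 0)
  if (rho == 0) return(0)
  per * mu_fix * (expm1(rho * age) / rho - age)
}

# Normalize survey-ish inputs to a patch table (age, size, count).
as_patch_table <- function(survey) {
  if (inherits(survey, "clone_survey")) {
    p <- survey$patches
    if (!"age" %in% names(p))
      p$age <- survey$sections$age[match(p$patient_id, survey$sections$patient_id)]
    return(p[, c("age", "size", "count")])
  }
  df <- as.data.frame(survey)
  stopifnot(all(c("age", "size", "count") %in% names(df)))
  df[, c("age", "size", "count")]
}
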