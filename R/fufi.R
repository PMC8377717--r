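#' Estimate chi, the fusion share of mutant/mutant branched forms
#'
#' All M/W branched forms (FUFIs) are fusions, but M/M forms can be either
#' fissions or fusions. Under a uniform-random-neighbour fusion model, the
#' mutational state of crypts neighbouring patch-border FUFIs identifies the
#' split: with `p_bar` the mean mutant-neighbour fraction, the expected
#' number of mutant-involving fusions `F` solves `n_mw = F * (1 - p_bar)`,
#' and `chi = F * p_bar / n_mm` (clamped to \[0, 1\]) is the proportion of
#' M/M FUFIs that are fusions. The CI is a bootstrap over scored FUFIs.
#'
#' @param neighbors Neighbour table (`fufi_type`, `m_neighbors`,
#'   `w_neighbors`), one row per scored border FUFI.
#' @param fufis FUFI count table with columns `n_mm`, `n_mw` (rows are
#'   summed).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return Object of class `chi_estimate`: `chi`, `p_bar`, `ci_low`,
#'   `ci_high`, plus the totals used.
#' @export
estimate_chi <- function(neighbors, fufis, n_boot = 1000, seed = 1L) {
  n_mm <- sum(fufis$n_mm); n_mw <- sum(fufis$n_mw)
  if (n_mm == 0) stop("no M/M FUFIs: chi undefined")
  if (nrow(neighbors) == 0) stop("chi needs scored FUFI neighbours")
  pfrac <- neighbors$m_neighbors /
    (neighbors$m_neighbors + neighbors$w_neighbors)
  chi_of <- function(pb, mm, mw) {
    if (pb >= 1) {
      if (mw > 0) stop("p_bar = 1 with M/W FUFIs observed: inconsistent data")
      return(1)
    }
    min(max((mw / (1 - pb)) * pb / mm, 0), 1)
  }
  p_bar <- mean(pfrac)
  chi <- chi_of(p_bar, n_mm, n_mw)
  set.seed(seed)
  labs <- c(rep("MM", n_mm), rep("MW", n_mw))
  bs <- replicate(n_boot, {
    pb <- mean(sample(pfrac, length(pfrac), replace = TRUE))
    tab <- sample(labs, length(labs), replace = TRUE)
    mm <- sum(tab == "MM"); mw <- sum(tab == "MW")
    if (mm == 0 || pb >= 1) NA_real_ else chi_of(pb, mm, mw)
  })
  ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(chi = chi, p_bar = p_bar, ci_low = ci[1], ci_high = ci[2],
                 n_mm = n_mm, n_mw = n_mw, boot = bs),
            class = "chi_estimate")
}

#' @export
print.chi_estimate <- function(x, ...) {
  cat(sprintf("chi = %.3f (95%% CI %.3f-%.3f), p_bar = %.3f, n_mm = %d, n_mw = %d\n",
              x$chi, x$ci_low, x$ci_high, x$p_bar, x$n_mm, x$n_mw))
  invisible(x)
}

#' Estimate the crypt fusion rate by fission/fusion proportionality
#'
#' Fission and fusion intermediates share the same visibility duration, so
#' observed event counts are proportional to the underlying rates:
#' fission events `S = (1 - chi) * n_mm`, fusion events
#' `F = chi * n_mm + n_mw`, and `phi = rho * F / S`. The CI combines a
#' bootstrap over FUFIs with the uncertainty of `rho`.
#'
#' @param rho Fission rate (numeric, or a `fission_estimate` whose CI is
#'   propagated).
#' @param fufis FUFI count table (`n_mm`, `n_mw`).
#' @param chi A [estimate_chi()] result (or numeric chi).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed.
#' @return Object of class `fusion_estimate`: `phi`, `ci_low`, `ci_high`.
#' @export
estimate_fusion_rate <- function(rho, fufis, chi, n_boot = 1000, seed = 1L) {
  n_mm <- sum(fufis$n_mm); n_mw <- sum(fufis$n_mw)
  chiv <- if (inherits(chi, "chi_estimate")) chi$chi else chi
  rho_hat <- if (inherits(rho, "fission_estimate")) rho$rho else rho
  S <- (1 - chiv) * n_mm
  if (S <= 0) stop("no fission events implied ((1 - chi) * n_mm = 0): rate undefined")
  Fv <- chiv * n_mm + n_mw
  phi <- rho_hat * Fv / S
  set.seed(seed)
  labs <- c(rep("MM", n_mm), rep("MW", n_mw))
  chib <- if (inherits(chi, "chi_estimate") && length(chi$boot)) chi$boot else
    rep(chiv, n_boot)
  rho_draw <- if (inherits(rho, "fission_estimate") && is.finite(rho$ci_low)) {
    se <- (rho$ci_high - rho$ci_low) / (2 * 1.96)
    pmax(stats::rnorm(n_boot, rho_hat, se), 1e-6)
  } else rep(rho_hat, n_boot)
  bs <- vapply(seq_len(n_boot), function(b) {
    tab <- sample(labs, length(labs), replace = TRUE)
    mm <- sum(tab == "MM"); mw <- sum(tab == "MW")
    cv <- chib[min(b, length(chib))]
    if (is.na(cv) || (1 - cv) * mm <= 0) return(NA_real_)
    rho_draw[b] * (cv * mm + mw) / ((1 - cv) * mm)
  }, numeric(1))
  ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(phi = phi, ci_low = ci[1], ci_high = ci[2],
                 fission_events = S, fusion_events = Fv),
            class = "fusion_estimate")
}

#' @export
print.fusion_estimate <- function(x, ...) {
  cat(sprintf("Crypt fusion rate: %.3f%%/yr (95%% CI %.3f-%.3f)\n",
              100 * x$phi, 100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

# Probability a contiguous mutant arc of k cells on a ring of N segregates
# wholly into one branch when the ring is cut into two contiguous halves.
segregation_prob <- function(k, N) {
  m <- floor(N / 2)
  if (k > max(m, N - m)) return(0)
  (max(m - k + 1, 0) + max(N - m - k + 1, 0)) / N
}

# Quasi-stationary distribution of the biased boundary walk on 1..N-1
# (mutant stem-cell count conditioned on non-absorption).
moran_qsd <- function(n_stem, bias) {
  N <- n_stem
  if (N == 2) return(stats::setNames(1, "1"))
  Tm <- matrix(0, N - 1, N - 1)
  for (k in seq_len(N - 1)) {
    if (k < N - 1) Tm[k, k + 1] <- bias
    if (k > 1) Tm[k, k - 1] <- 1 - bias
  }
  e <- eigen(t(Tm))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  stats::setNames(v / sum(v), seq_len(N - 1))
}

#' Expected M/W branched forms under the two fission-origin hypotheses
#'
#' Tests whether heterotypic (M/W) branched forms could be fission rather
#' than fusion intermediates. Hypothesis 1: a de novo mutation arises in one
#' branch during the visibility window and reaches monoclonality there.
#' Hypothesis 2: a pre-existing partially populated crypt fissions with
#' complete segregation of the mutant epithelium into one branch (the
#' segregation probability follows from the quasi-stationary intracrypt
#' state distribution). Both expectations are compared with the observed
#' M/W count via Poisson tail probabilities; if both are rejected the forms
#' must be genuine fusion intermediates.
#'
#' @param params An [intracrypt_params()].
#' @param fufi_freq Branched forms per crypt (tissue-wide).
#' @param fufi_duration Visibility window (years).
#' @param n_crypts_scored Crypts scored.
#' @param rho Fission rate per crypt per year.
#' @param c_part Partially populated crypt frequency.
#' @param observed_mw Observed M/W count (optional, for the report).
#' @return List with `hyp1`, `hyp2` expectations, per-hypothesis Poisson
#'   p-values (if `observed_mw` given) and `reject_both`.
#' @export
predict_mw_under_fission_hypotheses <- function(params, fufi_freq,
                                                fufi_duration,
                                                n_crypts_scored,
                                                rho = 0.007,
                                                c_part = 2.6e-5,
                                                observed_mw = NULL) {
  stopifnot(inherits(params, "intracrypt_params"),
            fufi_freq >= 0, fufi_duration >= 0, n_crypts_scored >= 0)
  n_fufis <- fufi_freq * n_crypts_scored
  hyp1 <- n_fufis * params$mut_rate * fufi_duration *
    moran_fixation_prob(params$n_stem, params$bias)
  qsd <- moran_qsd(params$n_stem, params$bias)
  seg <- sum(qsd * vapply(as.integer(names(qsd)), segregation_prob,
                          numeric(1), N = params$n_stem))
  hyp2 <- c_part * rho * seg * n_crypts_scored * fufi_duration
  out <- list(hyp1 = hyp1, hyp2 = hyp2, segregation_prob = seg)
  if (!is.null(observed_mw)) {
    out$p_hyp1 <- stats::ppois(observed_mw - 1, hyp1, lower.tail = FALSE)
    out$p_hyp2 <- stats::ppois(observed_mw - 1, hyp2, lower.tail = FALSE)
    out$observed_mw <- observed_mw
    out$reject_both <- out$p_hyp1 < 0.05 && out$p_hyp2 < 0.05
  }
  out
}
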