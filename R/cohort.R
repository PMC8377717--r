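#' Per-mark rate parameters
#'
#' Bundles the stochastic rates attached to one clonal mark: the
#' mutation-fixation rate `mu_fix` (fixed clones per crypt per year), the
#' crypt fission rate `rho` and fusion rate `phi` (events per crypt per
#' year), the stationary partially-populated-crypt frequency `c_part`, the
#' crypt diffusion coefficient `d_coef` (crypt-domain areas per year) and the
#' ambient stromal fraction `s0`.
#'
#' @param rho,phi,mu_fix,c_part Non-negative rates (see description).
#' @param d_coef Diffusion coefficient, crypt-domain areas per year.
#' @param s0 Ambient stromal fraction in (0, 1).
#' @return An object of class `rate_params`.
#' @export
rate_params <- function(rho = 0.007, phi = 0.003, mu_fix = 1e-5,
                        c_part = 0, d_coef = 1.05, s0 = 0.265) {
  vals <- c(rho = rho, phi = phi, mu_fix = mu_fix, c_part = c_part,
            d_coef = d_coef, s0 = s0)
  if (any(!is.finite(vals))) stop("rate parameters must be finite")
  if (any(vals[c("rho", "phi", "mu_fix", "c_part")] < 0))
    stop("rates must be >= 0")
  if (s0 <= 0 || s0 >= 1) stop("s0 must be in (0, 1)")
  if (d_coef <= 0) stop("d_coef must be > 0")
  structure(as.list(vals), class = "rate_params")
}

#' Configuration of a synthetic clone-scoring cohort
#'
#' Describes a virtual cohort of en-face colonic sections scored for one or
#' more clonal marks, with enough statistical structure for every downstream
#' estimator in the package: ages drawn uniformly over `age_range`, crypt
#' totals negative-binomial around `crypts_mean`, fixation events Poisson at
#' `mu_fix` per crypt per year over life, patches growing as independent
#' pure-birth processes, and fission/fusion intermediates (FUFIs) visible for
#' `fufi_duration` years.
#'
#' @param n_patients Number of virtual patients.
#' @param age_range Two ages in years, within \[0, 120\].
#' @param crypts_mean,crypts_dispersion Mean and negative-binomial size of
#'   the per-section crypt count.
#' @param mark_params Named list of [rate_params()], one per clonal mark.
#' @param fufi_duration Years a fission/fusion remains visible as a branched
#'   form (> 0).
#' @param neighbors_per_crypt Crypt neighbourhood size (hexagonal packing: 6).
#' @param rho_wt,phi_wt Homeostatic (wild-type) fission and fusion rates used
#'   for wild-type FUFI generation.
#' @param exclude_outliers Drop patients whose average patch size z-score
#'   exceeds `outlier_z` (off by default).
#' @param outlier_z Z-score cutoff for the outlier flag.
#' @param seed Integer seed; every generator consuming the config is
#'   deterministic given it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 100,
                          age_range = c(13, 93),
                          crypts_mean = 2e4,
                          crypts_dispersion = 20,
                          mark_params = list(mPAS = rate_params()),
                          fufi_duration = 1,
                          neighbors_per_crypt = 6,
                          rho_wt = 0.007,
                          phi_wt = 0.003,
                          exclude_outliers = FALSE,
                          outlier_z = 4,
                          seed = 1L) {
  stopifnot(n_patients >= 1, length(age_range) == 2,
            age_range[1] >= 0, age_range[2] <= 120,
            age_range[1] <= age_range[2],
            crypts_mean > 0, fufi_duration > 0, neighbors_per_crypt >= 1)
  if (!length(mark_params) || is.null(names(mark_params)))
    stop("mark_params must be a named list of rate_params")
  for (mp in mark_params)
    if (!inherits(mp, "rate_params")) stop("each mark needs rate_params()")
  if (!all(is.finite(c(rho_wt, phi_wt))) || rho_wt < 0 || phi_wt < 0)
    stop("wild-type rates must be finite and >= 0")
  structure(list(n_patients = as.integer(n_patients), age_range = age_range,
                 crypts_mean = crypts_mean,
                 crypts_dispersion = crypts_dispersion,
                 mark_params = mark_params, fufi_duration = fufi_duration,
                 neighbors_per_crypt = as.integer(neighbors_per_crypt),
                 rho_wt = rho_wt, phi_wt = phi_wt,
                 exclude_outliers = exclude_outliers, outlier_z = outlier_z,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a clone survey (sections, patch histograms, ground truth)
#'
#' For each patient and mark, fixation events arise as a Poisson process at
#' `mu_fix` per crypt per year over the patient's life; each fixed clone then
#' grows as an independent pure-birth process at per-crypt rate `rho` from
#' its fixation time to the patient's age. Partially populated crypts are
#' emitted at the stationary frequency `c_part`. A ground-truth event log
#' (`$truth`) is returned alongside the observable tables so every
#' downstream estimator can be scored against it.
#'
#' @param config A [cohort_config()].
#' @return Object of class `clone_survey`: list with `sections` (one row per
#'   patient x mark: `patient_id`, `age`, `sex`, `mark`, `n_crypts`, `n_wpc`,
#'   `n_ppc`), `patches` (`patient_id`, `mark`, `age`, `size`, `count`) and
#'   `truth` (per-clone fixation times and sizes, plus the config).
#' @export
generate_clone_survey <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  np <- config$n_patients
  age <- stats::runif(np, config$age_range[1], config$age_range[2])
  sex <- sample(c("F", "M"), np, replace = TRUE)
  ncry <- pmax(1000L, stats::rnbinom(np, mu = config$crypts_mean,
                                     size = config$crypts_dispersion))
  sections <- NULL; patches <- NULL; clones <- NULL
  for (mark in names(config$mark_params)) {
    mp <- config$mark_params[[mark]]
    nev <- stats::rpois(np, mp$mu_fix * ncry * age)
    n_wpc <- integer(np)
    for (i in seq_len(np)) {
      if (nev[i] > 0) {
        s <- stats::runif(nev[i], 0, age[i])
        sz <- ryule(nev[i], mp$rho, age[i] - s)
        # patches cannot exceed the section
        while (sum(sz) > ncry[i]) sz <- sz[-which.max(sz)]
        if (length(sz)) {
          tab <- table(sz)
          patches <- rbind(patches, data.frame(
            patient_id = i, mark = mark, age = age[i],
            size = as.integer(names(tab)), count = as.integer(tab)))
          clones <- rbind(clones, data.frame(
            patient_id = i, mark = mark, t_fix = s[seq_along(sz)],
            size = sz))
          n_wpc[i] <- sum(sz)
        }
      }
    }
    n_ppc <- stats::rpois(np, ncry * mp$c_part)
    sections <- rbind(sections, data.frame(
      patient_id = seq_len(np), age = age, sex = sex, mark = mark,
      n_crypts = ncry, n_wpc = n_wpc, n_ppc = n_ppc))
  }
  if (is.null(patches))
    patches <- data.frame(patient_id = integer(), mark = character(),
                          age = numeric(), size = integer(), count = integer())
  out <- list(sections = sections, patches = patches,
              truth = list(clones = clones, config = config))
  class(out) <- "clone_survey"
  if (config$exclude_outliers) out <- drop_patch_outliers(out, config$outlier_z)
  out
}

# Remove patients with extreme average patch size (z-score rule, default off).
drop_patch_outliers <- function(survey, z = 4) {
  p <- survey$patches
  if (!nrow(p)) return(survey)
  avg <- tapply(p$size * p$count, p$patient_id, sum) /
    tapply(p$count, p$patient_id, sum)
  zs <- (avg - mean(avg)) / stats::sd(avg)
  bad <- as.integer(names(avg))[!is.na(zs) & abs(zs) > z]
  if (length(bad)) {
    survey$sections <- survey$sections[!survey$sections$patient_id %in% bad, ]
    survey$patches <- survey$patches[!survey$patches$patient_id %in% bad, ]
    survey$truth$excluded <- bad
  }
  survey
}

#' @export
print.clone_survey <- function(x, ...) {
  cat(sprintf("clone_survey: %d section rows, %d patch rows, marks: %s\n",
              nrow(x$sections), nrow(x$patches),
              paste(unique(x$sections$mark), collapse = ", ")))
  invisible(x)
}

# ---- hexagonal patch geometry ------------------------------------------------

# Axial coordinates of a size-n spiral hex cluster (ring by ring).
hex_spiral <- function(n) {
  if (n > 20000) stop("hex cluster too large")
  q <- 0L; r <- 0L
  dirs <- matrix(c(1L, 0L, 0L, 1L, -1L, 1L, -1L, 0L, 0L, -1L, 1L, -1L),
                 ncol = 2, byrow = TRUE)   # axial step directions
  out <- matrix(0L, n, 2)
  if (n == 1) return(out)
  i <- 1L; ring <- 1L
  while (i < n) {
    cq <- ring; cr <- 0L                   # ring start; walk pushes then steps
    for (d in c(3L, 4L, 5L, 6L, 1L, 2L)) { # order keeps the walk on the ring
      for (s in seq_len(ring)) {
        i <- i + 1L
        out[i, ] <- c(cq, cr)
        if (i == n) return(out)
        cq <- cq + dirs[d, 1]; cr <- cr + dirs[d, 2]
      }
    }
    ring <- ring + 1L
  }
  out
}

.hex_cache <- new.env(parent = emptyenv())

#' Mutant-neighbour counts inside a compact hexagonal patch
#'
#' Builds a spiral hexagonal cluster of `k` crypts and counts, for each
#' member, how many of its 6 lattice neighbours also belong to the patch.
#' This is the neighbourhood composition that determines whether a fusion at
#' a patch crypt produces an M/M or an M/W branched form.
#'
#' @param k Patch size (>= 1).
#' @return Integer vector of length `k` of mutant-neighbour counts (0..6).
#' @export
hex_patch_neighbors <- function(k) {
  stopifnot(k >= 1)
  key <- as.character(k)
  if (!is.null(.hex_cache[[key]])) return(.hex_cache[[key]])
  ax <- hex_spiral(k)
  keys <- paste(ax[, 1], ax[, 2])
  dirs <- matrix(c(1L, 0L, 0L, 1L, -1L, 1L, -1L, 0L, 0L, -1L, 1L, -1L),
                 ncol = 2, byrow = TRUE)
  m <- integer(k)
  for (d in seq_len(6))
    m <- m + as.integer(paste(ax[, 1] + dirs[d, 1], ax[, 2] + dirs[d, 2]) %in% keys)
  .hex_cache[[key]] <- m
  m
}

#' Generate a FUFI survey with neighbour scoring and ground-truth event log
#'
#' Fission and fusion events remain visible as branched forms (FUFIs) for
#' `fufi_duration` years. Fissions occur at the mark's rate `rho` per mutant
#' crypt (wild-type crypts use `rho_wt`); fusion involvements occur at `phi`
#' per crypt, the partner drawn uniformly from the crypt's 6 neighbours whose
#' mutant fraction reflects the patch geometry ([hex_patch_neighbors]).
#' Branched forms are labelled M/M, M/W or W/W accordingly; neighbour records
#' are emitted for FUFIs at patch borders (at least one wild-type neighbour).
#'
#' @param config The [cohort_config()] used to build `survey`.
#' @param survey A [generate_clone_survey()] result.
#' @return List with `fufis` (per patient x mark counts `n_ww`, `n_mm`,
#'   `n_mw`), `neighbors` (`fufi_id`, `fufi_type`, `m_neighbors`,
#'   `w_neighbors`), and `truth` (every mutant-linked event with its type).
#' @export
generate_fufi_survey <- function(config, survey) {
  stopifnot(inherits(config, "cohort_config"), inherits(survey, "clone_survey"))
  set.seed(config$seed + 104729L)          # decouple from survey stream
  dur <- config$fufi_duration
  nb <- config$neighbors_per_crypt
  fufis <- NULL; neigh <- NULL; truth <- NULL
  fid <- 0L
  for (mark in names(config$mark_params)) {
    mp <- config$mark_params[[mark]]
    sec <- survey$sections[survey$sections$mark == mark, ]
    for (i in seq_len(nrow(sec))) {
      pid <- sec$patient_id[i]
      pp <- survey$patches[survey$patches$patient_id == pid &
                             survey$patches$mark == mark, , drop = FALSE]
      n_mm <- 0L; n_mw <- 0L
      # wild-type branched forms: homeostatic fission + fusion
      n_wt <- sec$n_crypts[i] - sec$n_wpc[i]
      n_ww <- stats::rpois(1, n_wt * (config$rho_wt + config$phi_wt) * dur)
      if (nrow(pp)) {
        # per-crypt mutant-neighbour counts, patch-size weighted
        mcounts <- unlist(lapply(seq_len(nrow(pp)), function(j)
          rep(hex_patch_neighbors(pp$size[j]), pp$count[j])))
        M <- length(mcounts)
        nfis <- stats::rpois(1, M * mp$rho * dur)
        nfus <- stats::rpois(1, M * mp$phi * dur)
        if (nfis > 0) {
          m <- sample(mcounts, nfis, replace = TRUE)
          n_mm <- n_mm + nfis
          for (mm in m) {
            fid <- fid + 1L
            truth <- rbind(truth, data.frame(
              fufi_id = fid, patient_id = pid, mark = mark, type = "fission",
              label = "MM", m_neighbors = mm))
            if (mm < nb) {
              neigh <- rbind(neigh, data.frame(
                fufi_id = fid, fufi_type = "MM",
                m_neighbors = mm, w_neighbors = nb - mm))
            }
          }
        }
        if (nfus > 0) {
          m <- sample(mcounts, nfus, replace = TRUE)
          partner_mut <- stats::runif(nfus) < m / nb
          for (j in seq_len(nfus)) {
            fid <- fid + 1L
            lab <- if (partner_mut[j]) "MM" else "MW"
            if (partner_mut[j]) n_mm <- n_mm + 1L else n_mw <- n_mw + 1L
            truth <- rbind(truth, data.frame(
              fufi_id = fid, patient_id = pid, mark = mark, type = "fusion",
              label = lab, m_neighbors = m[j]))
            if (m[j] < nb) {
              neigh <- rbind(neigh, data.frame(
                fufi_id = fid, fufi_type = lab,
                m_neighbors = m[j], w_neighbors = nb - m[j]))
            }
          }
        }
      }
      fufis <- rbind(fufis, data.frame(
        patient_id = pid, mark = mark, n_ww = n_ww, n_mm = n_mm, n_mw = n_mw))
    }
  }
  if (is.null(neigh))
    neigh <- data.frame(fufi_id = integer(), fufi_type = character(),
                        m_neighbors = integer(), w_neighbors = integer())
  if (is.null(truth))
    truth <- data.frame(fufi_id = integer(), patient_id = integer(),
                        mark = character(), type = character(),
                        label = character(), m_neighbors = integer())
  list(fufis = fufis, neighbors = neigh, truth = truth)
}

#' Generate an amplicon read-count table with beta-binomial noise
#'
#' Alternate-read counts are beta-binomial around per-position noise means
#' (overdispersion across samples, as implied by SD-based calling
#' thresholds); spiked mutations add their allele frequency on top.
#'
#' @param n_samples,n_positions Table dimensions.
#' @param noise_profile Data frame (`position`, `alt`, `mean_maf`, `sd_maf`)
#'   or `NULL` for a default low-noise profile.
#' @param spiked_mutations Data frame (`sample_id`, `position`, `maf`) of
#'   true mutations to spike, or `NULL`.
#' @param seed Integer seed.
#' @param depth_mean,depth_dispersion Negative-binomial read-depth model.
#' @param min_depth If set, depths are floored at this value.
#' @param amplicon_id Amplicon label for the output rows.
#' @return Data frame (`sample_id`, `amplicon_id`, `position`, `alt`,
#'   `ref_count`, `alt_count`, `depth`) of class `amplicon_counts`.
#' @export
generate_amplicon_table <- function(n_samples, n_positions,
                                    noise_profile = NULL,
                                    spiked_mutations = NULL,
                                    seed = 1L,
                                    depth_mean = 5000, depth_dispersion = 20,
                                    min_depth = NULL,
                                    amplicon_id = "amp1") {
  set.seed(seed)
  if (is.null(noise_profile)) {
    noise_profile <- data.frame(position = seq_len(n_positions) - 1L,
                                alt = "A",
                                mean_maf = 1e-3, sd_maf = 5e-4)
  }
  stopifnot(all(noise_profile$mean_maf >= 0), all(noise_profile$sd_maf >= 0))
  out <- NULL
  for (s in seq_len(n_samples)) {
    depth <- stats::rnbinom(n_positions, mu = depth_mean,
                            size = depth_dispersion)
    if (!is.null(min_depth)) depth <- pmax(depth, as.integer(min_depth))
    m <- noise_profile$mean_maf
    v <- noise_profile$sd_maf^2
    p <- ifelse(m <= 0, 0, m)
    use_bb <- m > 0 & v > 0 & v < m * (1 - m)
    if (any(use_bb)) {
      ab <- m * (1 - m) / v - 1
      a <- m * ab; b <- (1 - m) * ab
      p[use_bb] <- stats::rbeta(sum(use_bb), a[use_bb], b[use_bb])
    }
    if (!is.null(spiked_mutations)) {
      sp <- spiked_mutations[spiked_mutations$sample_id == s, , drop = FALSE]
      if (nrow(sp)) {
        idx <- match(sp$position, noise_profile$position)
        p[idx] <- pmin(1, p[idx] + sp$maf)
      }
    }
    alt <- stats::rbinom(n_positions, depth, p)
    out <- rbind(out, data.frame(
      sample_id = s, amplicon_id = amplicon_id,
      position = noise_profile$position, alt = noise_profile$alt,
      ref_count = depth - alt, alt_count = alt, depth = depth))
  }
  class(out) <- c("amplicon_counts", "data.frame")
  out
}
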