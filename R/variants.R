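#' Build a per-position sequencing noise profile
#'
#' Per (amplicon, position, alternate base): mean and standard deviation of
#' the alternate-allele fraction across samples. Zero-depth positions are
#' flagged and excluded from the moments.
#'
#' @param tables One `amplicon_counts` data frame or a list of them
#'   (columns `sample_id`, `amplicon_id`, `position`, `alt`, `alt_count`,
#'   `depth`).
#' @return Data frame (`amplicon_id`, `position`, `alt`, `mean_maf`,
#'   `sd_maf`, `n_samples`) of class `noise_profile`.
#' @export
build_noise_profile <- function(tables) {
  tab <- if (is.data.frame(tables)) tables else do.call(rbind, tables)
  if (length(unique(tab$sample_id)) < 2)
    stop("noise profile needs at least 2 samples")
  zero <- tab$depth == 0
  if (any(zero)) {
    warning(sum(zero), " zero-depth position-samples excluded")
    tab <- tab[!zero, ]
  }
  tab$maf <- tab$alt_count / tab$depth
  key <- interaction(tab$amplicon_id, tab$position, tab$alt, drop = TRUE)
  agg <- data.frame(
    amplicon_id = tapply(as.character(tab$amplicon_id), key, `[`, 1),
    position = as.integer(tapply(tab$position, key, `[`, 1)),
    alt = tapply(as.character(tab$alt), key, `[`, 1),
    mean_maf = as.numeric(tapply(tab$maf, key, mean)),
    sd_maf = as.numeric(tapply(tab$maf, key, function(x)
      if (length(x) > 1) stats::sd(x) else 0)),
    n_samples = as.integer(tapply(tab$maf, key, length)),
    row.names = NULL)
  agg <- agg[order(agg$amplicon_id, agg$position), ]
  class(agg) <- c("noise_profile", "data.frame")
  agg
}

#' Call KDM6A mutations with per-position noise thresholds
#'
#' A position is a candidate when its mutant allele frequency strictly
#' exceeds 4 times the mean noise at that position OR 3.29 times its
#' standard deviation (two-sided normal P <= .001). Candidates are
#' confirmed only if present in every sample of the same patch (serial
#' sections) and absent from all wild-type samples of the same sections.
#' The corrected MAF subtracts the mean noise (floored at 0).
#'
#' @param counts `amplicon_counts` rows for all samples to call.
#' @param noise A [build_noise_profile()] result covering the positions.
#' @param patch_groups Data frame (`sample_id`, `patch_id`); `patch_id` `NA`
#'   or `"WT"` marks wild-type samples.
#' @param mean_factor,sd_factor Candidate thresholds (defaults 4 and 3.29).
#' @return Data frame of variant calls (`sample_id`, `amplicon_id`,
#'   `position`, `alt`, `maf`, `corrected_maf`, `candidate`, `status`,
#'   `reason`).
#' @export
call_kdm6a <- function(counts, noise, patch_groups,
                       mean_factor = 4, sd_factor = 3.29) {
  stopifnot(all(c("sample_id", "patch_id") %in% names(patch_groups)))
  if (!nrow(patch_groups)) stop("empty patch grouping")
  d <- as.data.frame(counts)
  d$maf <- ifelse(d$depth > 0, d$alt_count / d$depth, 0)
  ni <- match(interaction(d$amplicon_id, d$position, d$alt),
              interaction(noise$amplicon_id, noise$position, noise$alt))
  if (anyNA(ni)) stop("noise profile does not cover all sample positions")
  d$mean_noise <- noise$mean_maf[ni]
  d$sd_noise <- noise$sd_maf[ni]
  # sd rule is centred on the per-position mean so that 3.29 sd corresponds
  # to the stated two-sided P <= .001 for an excess above noise
  d$candidate <- d$maf > mean_factor * d$mean_noise |
    (d$maf - d$mean_noise) > sd_factor * d$sd_noise
  d$candidate <- d$candidate & d$maf > 0
  d$corrected_maf <- pmax(d$maf - d$mean_noise, 0)
  gi <- match(d$sample_id, patch_groups$sample_id)
  d$patch_id <- patch_groups$patch_id[gi]
  wt_samples <- patch_groups$sample_id[is.na(patch_groups$patch_id) |
                                         patch_groups$patch_id == "WT"]
  d$status <- "rejected"; d$reason <- "not a candidate"
  pos_key <- interaction(d$amplicon_id, d$position, d$alt)
  for (pid in setdiff(unique(d$patch_id), c(NA, "WT"))) {
    smp <- patch_groups$sample_id[!is.na(patch_groups$patch_id) &
                                    patch_groups$patch_id == pid]
    if (!length(smp)) stop("patch group ", pid, " has zero samples")
    for (k in unique(pos_key[d$candidate & d$patch_id %in% pid])) {
      rows <- d$patch_id %in% pid & pos_key == k
      in_all <- all(d$candidate[rows]) && sum(rows) == length(smp)
      wt_rows <- d$sample_id %in% wt_samples & pos_key == k
      in_wt <- any(d$candidate[wt_rows])
      d$status[rows] <- if (in_all && !in_wt) "confirmed" else "rejected"
      d$reason[rows] <- if (!in_all) "not in all patch samples" else
        if (in_wt) "present in wild-type samples" else "passed all filters"
    }
  }
  d$status[d$candidate & d$status == "rejected" & d$reason == "not a candidate"] <-
    "rejected"
  d$reason[d$candidate & d$reason == "not a candidate"] <- "candidate only"
  d[, c("sample_id", "amplicon_id", "position", "alt", "maf",
        "corrected_maf", "candidate", "status", "reason")]
}

#' Call KRAS codon 12/13 mutations with mimic-amplicon controls
#'
#' A mutation is called when (1) more than 1000 reads were obtained for both
#' KRAS amplicons and at least one mimic amplicon, (2) the MAF exceeds 0.1%
#' with at least 10 mutant reads in both KRAS amplicons, and (3) the mimic
#' amplicons show only background (MAF <= mean + 1.96 sd of the noise,
#' one-sided P .025). The corrected MAF subtracts the mean noise.
#'
#' @param kras Data frame with one row per KRAS amplicon (`amplicon_id`,
#'   `alt_count`, `depth`) for the tested mutation.
#' @param mimic Same columns for the mimic amplicon(s).
#' @param noise Optional noise summary for the mutation (`mean_maf`,
#'   `sd_maf`); zero noise assumed if `NULL`.
#' @param min_depth,min_maf,min_reads Calling thresholds (defaults 1000,
#'   0.001, 10).
#' @return One-row data frame (`maf`, `corrected_maf`, `status`, `reason`).
#' @export
call_kras <- function(kras, mimic, noise = NULL,
                      min_depth = 1000, min_maf = 0.001, min_reads = 10) {
  if (is.null(noise)) noise <- list(mean_maf = 0, sd_maf = 0)
  if (nrow(kras) < 2 || nrow(mimic) < 1) {
    return(data.frame(maf = NA_real_, corrected_maf = NA_real_,
                      status = "insufficient-evidence",
                      reason = "need both KRAS amplicons and >= 1 mimic"))
  }
  maf <- kras$alt_count / kras$depth
  out_maf <- mean(maf)
  fail <- function(reason) data.frame(
    maf = out_maf, corrected_maf = pmax(out_maf - noise$mean_maf, 0),
    status = "rejected", reason = reason)
  if (!all(kras$depth > min_depth) || !any(mimic$depth > min_depth))
    return(fail("depth <= 1000 on a required amplicon"))
  if (!all(maf > min_maf)) return(fail("MAF below 0.1% in a KRAS amplicon"))
  if (!all(kras$alt_count >= min_reads)) return(fail("fewer than 10 mutant reads"))
  mim_maf <- mimic$alt_count / mimic$depth
  if (any(mim_maf > noise$mean_maf + 1.96 * noise$sd_maf))
    return(fail("signal above background in a mimic amplicon"))
  data.frame(maf = out_maf,
             corrected_maf = pmax(out_maf - noise$mean_maf, 0),
             status = "confirmed", reason = "passed all filters")
}

#' Enumerate amino-acid-changing KRAS codon 12/13 substitutions
#'
#' The 12 single-base substitutions of GGT (G12) and GGC (G13) that change
#' the encoded glycine, generated programmatically from the codons.
#'
#' @return Data frame (`codon`, `position_in_codon`, `ref_base`, `alt_base`,
#'   `mutant_codon`, `aa_change`).
#' @export
kras_codon_alternates <- function() {
  gencode <- c(GGT = "G", GGC = "G", GGA = "G", GGG = "G",
               AGT = "S", AGC = "S", CGT = "R", CGC = "R", CGA = "R",
               CGG = "R", AGA = "R", AGG = "R", TGT = "C", TGC = "C",
               GAT = "D", GAC = "D", GCT = "A", GCC = "A", GCA = "A",
               GCG = "A", GTT = "V", GTC = "V", GTA = "V", GTG = "V",
               TGA = "*", TGG = "W", GAA = "E", GAG = "E")
  bases <- c("A", "C", "G", "T")
  out <- NULL
  for (cd in c("GGT", "GGC")) {
    lab <- if (cd == "GGT") "G12" else "G13"
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(cd, pos, pos))) {
        mut <- cd
        substr(mut, pos, pos) <- b
        aa <- gencode[mut]
        if (!is.na(aa) && aa != "G") {
          out <- rbind(out, data.frame(
            codon = lab, position_in_codon = pos,
            ref_base = substr(cd, pos, pos), alt_base = b,
            mutant_codon = mut,
            aa_change = paste0(lab, substring(aa, 1, 1))))
        }
      }
    }
  }
  out
}

#' Estimate clone size from a corrected mutant allele frequency
#'
#' For a heterozygous autosomal mutation, a fraction `maf` of alleles mutant
#' implies `ploidy_factor * maf * total_crypts` mutant crypts (the
#' `ploidy_factor` is 1 for X-linked loci in males). An optional
#' multiplicative `stromal_correction` accounts for non-epithelial DNA.
#'
#' @param corrected_maf Noise-corrected MAF in \[0, 1/ploidy_factor\].
#' @param total_crypts Crypts in the sequenced section.
#' @param ploidy_factor Alleles per mutant genome copy context (default 2).
#' @param stromal_correction Multiplicative correction (default 1).
#' @return Estimated crypt count (nearest crypt).
#' @export
clone_size_from_maf <- function(corrected_maf, total_crypts,
                                ploidy_factor = 2, stromal_correction = 1) {
  stopifnot(corrected_maf >= 0, total_crypts >= 0)
  if (any(corrected_maf > 1 / ploidy_factor))
    warning("corrected MAF exceeds 1/ploidy_factor: inconsistent input")
  round(ploidy_factor * corrected_maf * total_crypts * stromal_correction)
}

#' Infer the KRAS-associated fission rate from clone sizes
#'
#' Simulation-based (approximate Bayesian) inference of the per-crypt
#' fission rate under the pure-birth, uniform-mutation-time model, with a
#' detection floor matching the MAF sensitivity limit: for each candidate
#' rate, clone sizes are simulated at the observed ages, floored, and
#' compared with the data on log-size quantiles; rates are weighted by a
#' Gaussian kernel on the distance.
#'
#' @param clones Data frame (`age`, `size`) of detected clones (crypts).
#' @param detection_floor Minimum detectable clone size (crypts).
#' @param rho_grid Candidate rates (per year).
#' @param n_sim Simulated clones per candidate rate.
#' @param seed Integer seed.
#' @return A `fission_estimate` (posterior mean and 95% credible interval).
#' @export
infer_kras_fission <- function(clones, detection_floor = 24,
                               rho_grid = seq(0.01, 0.30, by = 0.005),
                               n_sim = 4000, seed = 1L) {
  stopifnot(nrow(clones) >= 10)
  set.seed(seed)
  qs <- seq(0.05, 0.95, by = 0.1)
  obs <- log(stats::quantile(clones$size, qs, names = FALSE))
  if (all(clones$size <= detection_floor))
    warning("all clone sizes at the detection floor: rate unidentifiable")
  dist <- vapply(rho_grid, function(rho) {
    age <- sample(clones$age, n_sim, replace = TRUE)
    t <- age * stats::runif(n_sim)
    sz <- ryule(n_sim, rho, t)
    sz <- sz[sz >= detection_floor]
    if (length(sz) < 30) return(NA_real_)
    sim <- log(stats::quantile(sz, qs, names = FALSE))
    sqrt(mean((sim - obs)^2))
  }, numeric(1))
  ok <- is.finite(dist)
  if (!any(ok)) stop("no candidate rate produced detectable clones")
  h <- stats::quantile(dist[ok], 0.25, names = FALSE)  # kernel bandwidth
  w <- ifelse(ok, exp(-0.5 * (dist / h)^2), 0)
  w <- w / sum(w)
  post_mean <- sum(w * rho_grid)
  cdf <- cumsum(w)
  ci <- c(rho_grid[which(cdf >= 0.025)[1]], rho_grid[which(cdf >= 0.975)[1]])
  structure(list(rho = post_mean, ci_low = ci[1], ci_high = ci[2],
                 loglik_profile = data.frame(rho = rho_grid,
                                             weight = w, distance = dist)),
            class = "fission_estimate")
}
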