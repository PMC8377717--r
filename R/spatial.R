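# Gap times of a pure-birth path conditioned to be exactly size k at time t
# (rejection sampling; returns cumulative event times since clone birth).
yule_times_conditioned <- function(rho, t, k, seed = NULL, max_tries = 4000) {
  if (!is.null(seed)) set.seed(seed)
  if (k == 1) return(numeric(0))
  for (i in seq_len(max_tries)) {
    B <- 500L
    G <- sweep(matrix(stats::rexp(B * k), B, k), 2, rho * seq_len(k), "/")
    cum <- t(apply(G, 1, cumsum))
    ok <- which(cum[, k - 1] <= t & t < cum[, k])
    if (length(ok)) return(cum[ok[1], seq_len(k - 1)])
  }
  stop("could not condition a size-", k, " clone on age ", t,
       " at rho = ", rho)
}

#' Generate a spatial crypt map around a mutant patch
#'
#' Crypts are placed on a jittered hexagonal lattice (one crypt domain per
#' cell); a mutant patch of `patch_size` crypts sits at the centre. The
#' local crypt areal coverage is perturbed according to [deficit_field()]
#' for an event history sampled conditional on (`patch_size`, `clone_age`),
#' so younger clones show depressed stromal fraction near the centroid.
#' Mutant crypt sections can be scaled relative to wild-type
#' (`area_ratio`), with their lattice spacing expanded area-preservingly so
#' the stromal field is unchanged.
#'
#' @param params A [rate_params()] (uses `rho`, `d_coef`, `s0`).
#' @param clone_age Years since the clone's founding mutation.
#' @param patch_size Crypts in the mutant patch (>= 1).
#' @param seed Integer seed.
#' @param n_crypts Total crypts on the map.
#' @param area_ratio Mutant / wild-type crypt section area ratio.
#' @param domain_area_um2 Physical area of one crypt domain (microns^2).
#' @param jitter Positional jitter, fraction of lattice spacing.
#' @param area_sdlog Log-sd of crypt-area noise.
#' @param patient_age Patient age recorded as metadata (years).
#' @param sigma0_sq Kernel regularization (domain areas).
#' @return Data frame (`id`, `x`, `y`, `area`, `axis_ratio`, `mutant`,
#'   `group`) of class `spatial_crypt_map`, positions and areas in microns;
#'   attributes: `patch_centroid`, `domain_area_um2`, `patient_age`, `truth`
#'   (history, params, clone age).
#' @export
generate_spatial_map <- function(params, clone_age, patch_size, seed = 1L,
                                 n_crypts = 600, area_ratio = 1,
                                 domain_area_um2 = 9000, jitter = 0.06,
                                 area_sdlog = 0.06, patient_age = NULL,
                                 sigma0_sq = 1) {
  stopifnot(inherits(params, "rate_params"), patch_size >= 1, clone_age >= 0)
  if (patch_size > n_crypts / 4)
    stop("patch_size exceeds map capacity (", n_crypts, " crypts)")
  set.seed(seed)
  hist <- event_history(
    clone_age,
    if (patch_size > 1)
      clone_age - yule_times_conditioned(params$rho, clone_age, patch_size)
    else numeric(0))
  ax <- hex_spiral(n_crypts)
  sp <- sqrt(2 / sqrt(3))                 # lattice spacing: unit cell area
  x <- sp * (ax[, 1] + ax[, 2] / 2)
  y <- sp * (sqrt(3) / 2) * ax[, 2]
  mutant <- seq_len(n_crypts) <= patch_size
  r0 <- sqrt(x^2 + y^2)                   # radii before patch expansion
  s_loc <- deficit_field(hist, params$d_coef, params$s0, r0,
                         sigma0_sq = sigma0_sq)
  if (area_ratio != 1) {                  # area-preserving radial expansion
    R0 <- max(r0[mutant]) + sp / 2
    inside <- r0 <= R0
    rnew <- ifelse(inside, sqrt(area_ratio) * r0,
                   sqrt(area_ratio * R0^2 + r0^2 - R0^2))
    scl <- ifelse(r0 > 0, rnew / r0, 1)
    x <- x * scl; y <- y * scl
  }
  x <- x + stats::rnorm(n_crypts, 0, jitter * sp)
  y <- y + stats::rnorm(n_crypts, 0, jitter * sp)
  cell_area <- ifelse(mutant, area_ratio, 1)
  area <- (1 - s_loc) * cell_area *
    stats::rlnorm(n_crypts, -area_sdlog^2 / 2, area_sdlog)
  group <- rep("neighborhood", n_crypts)
  group[mutant] <- "patch"
  # three control groupings of patch_size adjacent wild-type crypts
  rmax <- max(r0)
  ang0 <- stats::runif(1, 0, 2 * pi)
  wt_idx <- which(!mutant)
  for (g in 1:3) {
    cx <- 0.55 * rmax * cos(ang0 + 2 * pi * (g - 1) / 3)
    cy <- 0.55 * rmax * sin(ang0 + 2 * pi * (g - 1) / 3)
    free <- wt_idx[group[wt_idx] == "neighborhood"]
    d2 <- (x[free] - cx)^2 + (y[free] - cy)^2
    group[free[order(d2)][seq_len(patch_size)]] <- paste0("control_", g)
  }
  L <- sqrt(domain_area_um2)              # micron per domain length
  map <- data.frame(id = seq_len(n_crypts), x = x * L, y = y * L,
                    area = area * domain_area_um2,
                    axis_ratio = exp(abs(stats::rnorm(n_crypts, 0, 0.12))),
                    mutant = mutant, group = group)
  class(map) <- c("spatial_crypt_map", "data.frame")
  attr(map, "patch_centroid") <- c(x = mean(map$x[mutant]),
                                   y = mean(map$y[mutant]))
  attr(map, "domain_area_um2") <- domain_area_um2
  attr(map, "patient_age") <- if (is.null(patient_age)) clone_age else patient_age
  attr(map, "truth") <- list(history = hist, params = params,
                             clone_age = clone_age, area_ratio = area_ratio)
  map
}

# Local lattice spacing per crypt: mean distance to its k nearest neighbours
# (for roughly triangular packing this estimates the centre-to-centre
# spacing without the downward bias of nearest-neighbour minima).
local_spacing <- function(map, k = 6) {
  n <- nrow(map)
  d <- as.matrix(stats::dist(cbind(map$x, map$y)))
  diag(d) <- Inf
  vapply(seq_len(n), function(i) mean(sort(d[i, ])[seq_len(min(k, n - 1))]),
         numeric(1))
}

#' Stromal fraction of a crypt group
#'
#' One minus the summed crypt section area over the group's domain area.
#' Crypt domains are taken as hexagonal cells of the locally estimated
#' spacing (`sqrt(3)/2 * spacing^2` each, exact for triangular packing), so
#' the group's domain partition is `n * sqrt(3)/2 * median(spacing)^2`.
#'
#' @param map A `spatial_crypt_map` (or data frame with `x`, `y`, `area`,
#'   `group`).
#' @param group Group label (`"patch"`, `"control_1"`, ...), or a logical /
#'   integer index of crypts.
#' @param spacing Optional precomputed [local_spacing()] vector.
#' @return Stromal fraction in \[0, 1\].
#' @export
stromal_fraction <- function(map, group = "patch", spacing = NULL) {
  idx <- if (is.character(group)) which(map$group == group) else which(group)
  if (length(idx) < 3) stop("group needs at least 3 crypts")
  if (stats::sd(map$x[idx]) < 1e-9 || stats::sd(map$y[idx]) < 1e-9)
    stop("degenerate (collinear) group geometry")
  if (is.null(spacing)) spacing <- local_spacing(map)
  cell <- sqrt(3) / 2 * stats::median(spacing[idx])^2
  s <- 1 - sum(map$area[idx]) / (length(idx) * cell)
  min(max(s, 0), 1)
}

#' Radial stromal-fraction profile around the mutant patch
#'
#' Rolling windows of `window_size` wild-type crypts ordered by distance
#' from the patch centroid, preceded by the mutant patch itself (r ~ 0) and
#' including the three control groupings as fixed-distance points. Distances
#' are reported both in crypt-domain diameters (`r`) and domain lengths
#' (`r_domain_lengths`, the unit of [deficit_field()]).
#'
#' @param map A `spatial_crypt_map`.
#' @param window_size Crypts per rolling window.
#' @param stride Window stride (crypts).
#' @return Data frame (`r`, `r_domain_lengths`, `stromal_fraction`, `kind`).
#' @export
radial_profile <- function(map, window_size = 10, stride = 5) {
  cen <- attr(map, "patch_centroid")
  if (is.null(cen)) {
    if (!any(map$mutant)) stop("map has no mutant patch and no centroid")
    cen <- c(mean(map$x[map$mutant]), mean(map$y[map$mutant]))
  }
  spacing <- local_spacing(map)
  A_dom <- sqrt(3) / 2 * stats::median(spacing)^2
  L <- sqrt(A_dom)
  ddiam <- 2 * sqrt(A_dom / pi)
  dist <- sqrt((map$x - cen[1])^2 + (map$y - cen[2])^2)
  rows <- list(); members <- list()
  add <- function(idx, kind) {
    members[[length(members) + 1]] <<- dist[idx] / L
    data.frame(r = mean(dist[idx]) / ddiam,
               r_domain_lengths = mean(dist[idx]) / L,
               stromal_fraction = stromal_fraction(map, seq_len(nrow(map)) %in% idx,
                                                   spacing = spacing),
               kind = kind)
  }
  rows[[1]] <- add(which(map$group == "patch"), "patch")
  for (g in paste0("control_", 1:3))
    if (any(map$group == g)) rows[[length(rows) + 1]] <- add(which(map$group == g), g)
  # exclude boundary crypts, whose neighbour-based spacing (and hence the
  # domain partition) is inflated because part of their neighbour ring is
  # missing; interior crypts have spacing at the map-wide typical value
  interior <- spacing <= 1.08 * stats::median(spacing)
  wt <- which(!map$mutant & interior)
  wt <- wt[order(dist[wt])]
  if (length(wt) < window_size) stop("too few wild-type crypts for windowing")
  starts <- seq(1, length(wt) - window_size + 1, by = stride)
  for (s in starts)
    rows[[length(rows) + 1]] <- add(wt[s:(s + window_size - 1)], "window")
  out <- do.call(rbind, rows)
  ord <- order(out$r)
  out <- out[ord, ]
  attr(out, "members_r") <- members[ord]
  out
}

#' Crypt size and shape statistics of a spatial map
#'
#' Mutant / wild-type crypt-section area ratio with a permutation p-value
#' (labels shuffled between the patch and its adjacent control groupings),
#' and per-group eccentricity summaries computed from the stated axis
#' ratios, compared by Kruskal-Wallis rank test.
#'
#' @param map A `spatial_crypt_map`.
#' @param n_perm Label permutations for the area-ratio test.
#' @param seed Seed for the permutation draw.
#' @return List with `area_ratio`, `area_p`, `eccentricity` (per-group
#'   medians), `ecc_p`.
#' @export
crypt_shape_stats <- function(map, n_perm = 999, seed = 1L) {
  adj <- map$group %in% c("patch", paste0("control_", 1:3))
  mm <- map$mutant[adj]; aa <- map$area[adj]
  if (!any(mm) || all(mm)) stop("need both mutant and wild-type crypts")
  ratio <- mean(aa[mm]) / mean(aa[!mm])
  set.seed(seed)
  obs <- abs(log(ratio))
  perm <- replicate(n_perm, {
    sh <- sample(mm)
    abs(log(mean(aa[sh]) / mean(aa[!sh])))
  })
  area_p <- (1 + sum(perm >= obs)) / (n_perm + 1)
  ecc <- sqrt(pmax(0, 1 - 1 / map$axis_ratio^2))
  ecc_med <- tapply(ecc, map$group, stats::median)
  ecc_p <- tryCatch(
    stats::kruskal.test(ecc ~ factor(map$group))$p.value,
    error = function(e) NA_real_)
  list(area_ratio = ratio, area_p = area_p,
       eccentricity = ecc_med, ecc_p = ecc_p)
}
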