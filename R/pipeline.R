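#' Write a table as TSV with a JSON sidecar recording provenance
#'
#' @param df Data frame.
#' @param path Output TSV path.
#' @param meta Named list stored in `<path>.json` alongside the seed and a
#'   parameter hash.
#' @export
write_table_tsv <- function(df, path, meta = list()) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta$written <- basename(path)
  meta$param_hash <- unname(substr(digest_obj(meta), 1, 12))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

# Stable short hash of an R object (via serialization + md5 of a temp file).
digest_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes the stages in dependency order (simulate, infer-fission,
#' infer-fusion, infer-diffusion, threshold-sim, call-variants), writing
#' TSV/JSON artifacts to `out_dir` and returning a manifest of every file
#' with its MD5 hash. Configuration is a YAML file or a named list; the
#' seed must be present before any computation starts and is recorded in
#' every sidecar.
#'
#' @param config Path to a YAML config or a named list. Recognized keys:
#'   `seed` (required), `out_dir`, `stages` (character subset of the stage
#'   names above), and per-stage parameter blocks (`cohort`, `threshold`,
#'   `diffusion`).
#' @return Invisibly, a data frame manifest (`file`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config must provide a seed before any computation")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir %||% "pipeline_out"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("simulate", "infer-fission", "infer-fusion",
                                 "infer-diffusion", "threshold-sim",
                                 "call-variants")
  co <- config$cohort %||% list()
  cfg <- cohort_config(
    n_patients = co$n_patients %||% 60,
    age_range = co$age_range %||% c(20, 90),
    crypts_mean = co$crypts_mean %||% 1e4,
    mark_params = list(
      mPAS = rate_params(rho = 0.007, phi = 0.003, mu_fix = 2.5e-5,
                         c_part = 4.4e-4),
      KDM6A = rate_params(rho = 0.036, phi = 0.007, mu_fix = 6.04e-6,
                          c_part = 2.626e-5)),
    seed = seed)
  paths <- character(0)
  survey <- NULL; fufi <- NULL
  need_survey <- any(c("simulate", "infer-fission", "infer-fusion") %in% stages)
  if (need_survey) {
    survey <- generate_clone_survey(cfg)
    fufi <- generate_fufi_survey(cfg, survey)
  }
  if ("simulate" %in% stages) {
    paths <- c(paths,
               write_table_tsv(survey$sections, file.path(out_dir, "sections.tsv"),
                               list(seed = seed, stage = "simulate")),
               write_table_tsv(survey$patches, file.path(out_dir, "patches.tsv"),
                               list(seed = seed, stage = "simulate")),
               write_table_tsv(fufi$fufis, file.path(out_dir, "fufis.tsv"),
                               list(seed = seed, stage = "simulate")),
               write_table_tsv(fufi$neighbors, file.path(out_dir, "fufi_neighbors.tsv"),
                               list(seed = seed, stage = "simulate")))
  }
  if ("infer-fission" %in% stages) {
    if (is.null(survey)) stop("missing upstream artifact: run the 'simulate' stage first")
    est <- infer_fission_rate(subset_mark(survey, "KDM6A"))
    p <- file.path(out_dir, "fission_estimate.json")
    jsonlite::write_json(list(seed = seed, rho = est$rho, ci = c(est$ci_low, est$ci_high)),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if ("infer-fusion" %in% stages) {
    if (is.null(fufi)) stop("missing upstream artifact: run the 'simulate' stage first")
    f <- fufi$fufis[fufi$fufis$mark == "mPAS", ]
    ids <- fufi$truth$fufi_id[fufi$truth$mark == "mPAS"]
    nb <- fufi$neighbors[fufi$neighbors$fufi_id %in% ids, ]
    chi <- estimate_chi(nb, f)
    rho_mpas <- infer_fission_rate(subset_mark(survey, "mPAS"))
    fus <- estimate_fusion_rate(rho_mpas, f, chi)
    p <- file.path(out_dir, "fusion_estimate.json")
    jsonlite::write_json(list(seed = seed, chi = chi$chi, phi = fus$phi,
                              ci = c(fus$ci_low, fus$ci_high)),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if ("infer-diffusion" %in% stages) {
    dcfg <- config$diffusion %||% list()
    nm <- dcfg$n_maps %||% 6
    kd <- cfg$mark_params$KDM6A
    maps <- lapply(seq_len(nm), function(i)
      generate_spatial_map(kd, clone_age = stats::runif(1, 5, 60),
                           patch_size = 10, seed = seed + i,
                           patient_age = 70))
    fit <- infer_diffusion(maps, mu_fix = kd$mu_fix, rho = kd$rho,
                           n_draws = dcfg$n_draws %||% 50, seed = seed)
    p <- file.path(out_dir, "diffusion_fit.json")
    jsonlite::write_json(list(seed = seed, d_coef = fit$d_coef,
                              ci = c(fit$ci_low, fit$ci_high)),
                         p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  if ("threshold-sim" %in% stages) {
    tcfg <- config$threshold %||% list()
    lc <- lesion_sim_config(
      fission_multiple = tcfg$fission_multiple %||% 17,
      horizon = tcfg$horizon %||% 50,
      n_reps = tcfg$n_reps %||% 2e4, seed = seed)
    res <- simulate_clone_lesion(lc)
    paths <- c(paths,
               write_table_tsv(res$cum_prob, file.path(out_dir, "lesion_cum_prob.tsv"),
                               list(seed = seed, stage = "threshold-sim",
                                    k = lc$fission_multiple)))
  }
  if ("call-variants" %in% stages) {
    amp <- generate_amplicon_table(6, 40, seed = seed)
    noise <- build_noise_profile(amp)
    groups <- data.frame(sample_id = 1:6,
                         patch_id = c("p1", "p1", "p1", NA, NA, NA))
    calls <- call_kdm6a(amp, noise, groups)
    paths <- c(paths,
               write_table_tsv(calls, file.path(out_dir, "variant_calls.tsv"),
                               list(seed = seed, stage = "call-variants")))
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# Restrict a clone survey to one mark.
subset_mark <- function(survey, mark) {
  structure(list(sections = survey$sections[survey$sections$mark == mark, ],
                 patches = survey$patches[survey$patches$mark == mark, ],
                 truth = survey$truth),
            class = "clone_survey")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
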