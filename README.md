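# cryptdyn

Stochastic-process analysis of clonal expansion in human colonic
epithelium, built for quantitative biologists studying field change and
early tumorigenesis. The package simulates and analyses the full chain of
observables a clone-scoring histology survey produces — per-section
wholly/partially populated crypt counts, age-stratified patch-size
histograms, branched-crypt (FUFI) classifications with neighbour scoring,
spatial crypt maps, and amplicon read-count tables — and infers from them
the rates that govern clonal spread:

- **Intracrypt competition.** Biased Moran drift of a mutant stem-cell
  lineage; fixation probability `(1 - q/p) / (1 - (q/p)^N)`; the
  fixation-ratio statistic ΔC_fix / C_part separating advantaged from
  neutral clonal marks.
- **Crypt fission.** Patch growth as a pure-birth (Yule) process,
  `P(K = k | t) = e^{-ρt}(1 - e^{-ρt})^{k-1}`; maximum-likelihood
  inference of ρ from patch-size histograms with mutation timing
  marginalized uniformly over life, `q_k(ρ,T) = (1 - e^{-ρT})^k / (kρT)`,
  with profile-likelihood CIs.
- **Crypt fusion.** The χ estimator (fusion share of mutant/mutant
  branched forms, identified from the mutant status of patch-border
  neighbours) and the fission/fusion proportionality
  φ = ρ · (χ·n_MM + n_MW) / ((1-χ)·n_MM).
- **Crypt diffusion.** A point-source deficit-field model — every fission
  injects one crypt-domain area of mass that disperses as a 2-D heat kernel
  with per-axis variance 2(2D·Δt + σ₀²) — fitted to radial stromal-fraction
  profiles via ensembles of trajectories conditioned on observed patch size
  and patient age, yielding the diffusion coefficient D in crypt-domain
  areas per year.
- **Lesion threshold.** Forward Gillespie simulation of clone growth under
  the deficit field; a lesion is declared when a newly generated crypt
  arrives where local stroma is already at the hexagonal-packing whitespace
  `1 - π/(2√3) ≈ 0.0931` and cannot be accommodated.
- **Mutation calling.** Cross-sample noise profiles, the 4x-mean /
  3.29-SD candidate rules with serial-section patch confirmation, KRAS
  codon 12/13 calling against mimic amplicons, clone sizes from corrected
  allele frequencies, and simulation-based inference of the KRAS-associated
  fission rate.

Every generator emits a ground-truth event log beside its observable
tables, so each estimator in the chain is validated by parameter recovery.
The methods vignette (`vignettes/crypt-dynamics.Rmd`) documents the models,
their assumptions, parameter defaults, and known limitations.

## Worked example

Infer the fission rate of an advantaged clonal mark from a synthetic
120-patient survey, then derive its growth clocks:

```r
library(cryptdyn)

kdm6a <- rate_params(rho = 0.036, phi = 0.007, mu_fix = 6.04e-6,
                     c_part = 2.626e-5, d_coef = 1.05, s0 = 0.265)
cfg <- cohort_config(n_patients = 120, age_range = c(21, 93),
                     crypts_mean = 2e4,
                     mark_params = list(KDM6A = kdm6a), seed = 42)
survey <- generate_clone_survey(cfg)
infer_fission_rate(survey)
#> Crypt fission rate: 3.633%/yr (95% profile CI 3.449-3.829)

round(transition_time_stats(0.036, 1)$median)    # years for 1 -> 2 crypts
#> [1] 19
round(transition_time_stats(0.036, 10)$median)   # years for 10 -> 11
#> [1] 2
```

The recovered 3.6%/yr is the generative rate; the two medians show why
large patches carry the signal of recent growth: a one-crypt clone waits a
median 19 years to double, but a ten-crypt patch adds its next crypt within
2 years.

The numbered drivers under `analysis/` run the full study on the synthetic
cohort and write tables under `results/` — for example `analysis/03_fission.R`
prints, per mark:

```
mPAS   rho 0.70%/yr (0.66-0.75)  1->2   99y  10->11 9.9y  P(>5)@85 0.004  +59/1e5
STAG2  rho 2.11%/yr (2.03-2.20)  1->2   33y  10->11 3.3y  P(>5)@85 0.122  +217/1e5
KDM6A  rho 3.60%/yr (3.41-3.79)  1->2   19y  10->11 1.9y  P(>5)@85 0.326  +187/1e5
fission fold-advantage KDM6A vs mPAS: 5.1
```

i.e. each mark's fission rate with CI, its patch-size transition clocks,
the fraction of clones exceeding 5 crypts by age 85, and the crypts added
by fission per 10^5 by age 75. `analysis/05_diffusion.R` and
`analysis/06_threshold.R` continue through the diffusion fit and the
accommodation threshold:

```
Crypt diffusion coefficient: 1.41 domain areas/yr (ensemble 95% 1.07-2.02)
smallest multiple breaching 1e-3: 12
k=17: 0.62% of clones lesion by 50y (MC se 0.012%)
```

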