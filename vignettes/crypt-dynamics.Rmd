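---
title: "Models and methods: clonal expansion and crypt diffusion in colonic epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: clonal expansion and crypt diffusion in colonic epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

The colonic epithelium is a sheet of glandular crypts, each maintained by a
small pool of competing stem cells. Somatic mutations spread in two stages:
within a crypt, drift or biased competition carries a mutant stem-cell
lineage to monoclonality (a partially populated crypt, PPC, becomes a wholly
populated crypt, WPC); between crypts, fission replicates a mutant crypt and
grows a clone into a multicrypt patch, while fusion merges adjacent crypts.
This package implements the stochastic-process machinery to simulate such
cohorts, infer the governing rates from the observable tables a histology
survey produces, and ask when clonal expansion outruns the tissue's capacity
to accommodate new crypts.

All estimators run against a synthetic-cohort generator that emits
ground-truth event logs next to every observable table, so each stage can be
scored against truth; nothing in the package requires access to clinical
data.

## Intracrypt dynamics

Each crypt holds `n_stem` functional stem cells (default 5). A mutation
seeds one mutant cell; at boundary replacement events (rate `replace_rate`
per year, default 0.7) the mutant domain grows with probability `bias` and
shrinks otherwise. The fixation probability from one seed is the
gambler's-ruin form $(1 - q/p)\,/\,(1 - (q/p)^N)$ with $p =$ `bias`,
$q = 1 - p$, which reduces to $1/N$ in the neutral case; `moran_fixation_prob()`
is the closed form and `simulate_intracrypt()` the sampler. Defaults are
config values rather than estimates: inferring `n_stem`, `replace_rate` and
`bias` separately from data is out of scope here, and only the ratio
statistic below is consumed downstream.

Fixed clones accumulate with age at a rate $\Delta C_{fix}$ (per crypt per
year) while the PPC frequency $C_{part}$ is approximately age-constant
because partial clones turn over on the fixed intracrypt time scale. The
ratio $\Delta C_{fix} / C_{part}$ (`fixation_ratio()`) therefore measures
per-clone conversion advantage: roughly 0.05/yr for neutral marks and about
0.23/yr in the advantaged scenario. The regression (`fit_wpc_slope()`) is
weighted least squares with an intercept — developmental clones present from
birth contribute an age-independent offset — and resamples patients, not
sections, in the bootstrap, since sections within a patient are correlated.
Whether $C_{part}$ should be age-pooled or age-regressed is genuinely open;
we pool (crypt-weighted) and note that an age regression changes the ratio
by less than its CI width in our simulations.

## Patch growth and fission-rate inference

A clone founded by one crypt whose members each fission at rate $\rho$ is a
pure-birth (Yule) process; after $t$ years its size is geometric,

$$P(K = k \mid t) = e^{-\rho t}\,\bigl(1 - e^{-\rho t}\bigr)^{k-1}.$$

With mutation timing uniform over a patient's life (constant fixation rate;
the prior on initiation time is not identifiable from one cross-section),
the size distribution at age $T$ has the closed form

$$q_k(\rho, T) = \frac{(1 - e^{-\rho T})^k}{k\,\rho\,T},$$

implemented in `yule_size_marginal()` and used directly as the likelihood in
`infer_fission_rate()`. The fixation rate enters only the clone count, which
is ancillary for $\rho$, so it is profiled out for free. Confidence
intervals are profile-likelihood at the $\chi^2_1$ 95% cutoff (3.84);
patient-level bootstrap is available but an order of magnitude slower and
agrees in our runs. Each histogram entry is one clone within one section;
patch fragmentation across section boundaries is ignored, and the per-crypt
fission rate is size-independent beyond the linear scaling built into the
birth rate $k\rho$. The PPC-to-WPC conversion lag is not modelled in the
likelihood; at the rates involved it delays detectability by far less than
the inter-fission time.

Two deterministic corollaries are worth keeping in mind: the median wait for
a one-crypt clone to reach two crypts is $\ln 2 / \rho$ (19 years at 3.6%/yr)
but only $\ln 2 / (10\rho)$ (2 years) from ten to eleven — large patches are
young at their edge — and by age 75 fission has added only a few hundred
crypts per $10^5$ (`expected_new_crypts()`), so homeostatic accommodation
needs to absorb very little area in absolute terms.

## Branched forms, chi and the fusion rate

Fission and fusion pass through morphologically identical branched
intermediates ("FUFIs"), visible for a duration window (default 1 year,
config: the published external estimate of the window is not reproduced
here, and it cancels from rate ratios). Scoring branched forms by the
mutant status of their branches gives M/M, M/W and W/W counts. M/W forms
must be fusions — we verify quantitatively
(`predict_mw_under_fission_hypotheses()`) that neither a de novo mutation
fixing in one branch during the window nor fission of a pre-existing PPC
with clean segregation (segregation probability from the quasi-stationary
Moran state distribution on a ring) can produce more than a fraction of an
expected event at survey scale, against 13 observed. M/M forms are
ambiguous: a fission of any mutant crypt, or a fusion that happened to
capture a mutant neighbour.

The split is identified by neighbourhood composition. With $\bar p$ the
mean mutant-neighbour fraction of border FUFIs, the expected number of
mutant-involving fusions $F$ solves $n_{MW} = F(1 - \bar p)$, and
$\chi = F\bar p / n_{MM}$ (clamped to $[0,1]$) is the fusion share of M/M
forms (`estimate_chi()`). Because intermediates of both processes share the
visibility window, event counts are proportional to rates, and
`estimate_fusion_rate()` returns $\phi = \rho\,(\chi n_{MM} + n_{MW}) /
((1-\chi) n_{MM})$. In the generator, fusion is parameterized as a
per-crypt involvement rate (the rate at which a given crypt takes part in a
fusion, partner uniform among its 6 lattice neighbours); this is the
convention under which the observable proportionality recovers $\phi$
without a pairing factor. Mutant neighbourhoods come from exact spiral
hexagonal patch geometry (`hex_patch_neighbors()`), not an approximation.
Known bias: border FUFIs under-sample interior crypts of large patches, so
$\hat\chi$ is mildly conservative for strongly advantaged marks; the
neutral-scenario fusion rate, which is what the homeostatic estimate rests
on, is unaffected because single-crypt clones are all border.

## The crypt diffusion model

Newly generated crypts locally crowd the mucosa; the observed restoration
of ambient packing is modelled as a diffusion-like dispersal of crypt
domains (a crypt plus its share of stroma; all areas below are in
crypt-domain units, lengths in $\ell$ with $\ell^2$ = one domain area).
Patch growth is a stochastically firing point source at the clone centroid:
each fission injects one domain-area of crypt mass, which spreads as a 2-D
Gaussian kernel with per-axis variance

$$v(\Delta t) = 2\,(2 D\,\Delta t + \sigma_0^2),$$

where $D$ is the diffusion coefficient (domain areas per year) and
$\sigma_0^2 = 1$ domain area regularizes the newborn crypt, which physically
occupies one domain at birth rather than a point. The local stromal
fraction is $s(r) = s_0 - (1 - s_0) \sum_i K_i(r)$, floored at zero
(`deficit_field()`); the $(1-s_0)$ factor converts domain mass into crypt
coverage. Mass is conserved to numerical quadrature accuracy (a tested
invariant), and predictions depend on $D$ and time only through $D\,\Delta t$,
an exact scaling the tests assert.

The ambient stromal fraction defaults to $s_0 = 0.265$. That number is
pinned by an internal-consistency argument rather than fit: absorbing a
10-crypt patch by a 1% spacing reduction across 264 domains, or a 5%
reduction across 53, both imply a ceded-area demand of
$\approx 2.65 = 10\,s_0$ domain areas, so `domains_affected()` computes
`ceiling(patch_size * s0 / reduction_fraction)` and reproduces both counts
at $s_0 \approx 0.264$.

Inference of $D$ proceeds exactly as the measurement design dictates. A
clone observed as a 10-crypt patch in a patient of known age has an unknown
event history; `simulate_trajectories()` draws (mutation time, fission
times) exactly from the conditional law by rejection sampling (accepted
paths are exact conditional draws, so ensemble weights are uniform; the
conditional density is attached to rank "most likely" paths). For each
ensemble draw, one history per patch is sampled, the deficit field predicts
the radial stromal profile, and the squared error against the measured
profile — rolling windows of 10 crypts moving out from the patch, plus the
patch itself and three adjacent 10-crypt control groupings — is minimized
over $\log D$, with the ambient $s_0$ of each patch neighbourhood fitted
linearly (an open design choice; a global $s_0$ ties unrelated neighbourhoods
together and fits worse on heterogeneous maps). The ensemble of per-draw
minimizers gives the reported median and 2.5/97.5 percentiles
(`infer_diffusion()`). A null model with no radial dependence (constant
stromal fraction per neighbourhood) is compared by permutation
(`null_ambient_fit()`): windows are non-overlapping there, because
overlapping windows share crypts and their noise is not exchangeable, and
$D$ is re-optimized on every permuted data set so the model-selection
advantage is shared with the null distribution.

Measurement details that matter: crypt domains are estimated as hexagonal
cells of the locally measured spacing (mean distance to the 6 nearest
neighbours; the minimum-distance estimator is biased low under positional
jitter), boundary crypts with inflated spacing are excluded from windows,
and predictions are averaged over each window's member radii rather than
evaluated at the mean radius, matching how the observable is formed. With
those three choices the estimator recovers the generator's ambient fraction
within $\pm 0.02$ and the generative $D$ within its ensemble spread; without
them it is biased low by up to a factor of four, which is a useful warning
for anyone adapting the code to measured maps.

## The synthetic spatial maps

`generate_spatial_map()` places crypts on a jittered hexagonal lattice (one
domain per cell), carves a central mutant patch, samples an event history
conditional on (patch size, clone age), and encodes the resulting stromal
field in crypt areas: $a_i = (1 - s(r_i)) \times$ cell area $\times$
log-normal noise (sdlog 0.06). Mutant crypts can be scaled by a
mutant/wild-type area ratio with an area-preserving radial expansion of
their lattice neighbourhood, so the size difference does not masquerade as a
packing difference. Axis ratios supply eccentricities
(`crypt_shape_stats()`); the generator draws them identically for mutant and
wild-type crypts, encoding the finding that accommodation is not achieved by
squashing neighbours. The maps are tabular (centroids and areas), not
images; detection, segmentation and their error modes are deliberately not
emulated, so passing tests validate the estimators' statistics, not any
image-analysis step.

## The lesion threshold

The forward question: at what fission multiple $k$ of the homeostatic rate
$\rho_0 = 0.007$/yr does diffusion stop being able to accommodate newly
generated crypts? `simulate_clone_lesion()` grows each replicate clone by
Gillespie at rate $k \rho_0 n(t)$ and maintains the centroid deficit field
of its event history with the kernel above. A lesion is declared at the
first fission that arrives when the pre-existing local stromal fraction is
already at or below the hexagonal-packing whitespace
$1 - \pi/(2\sqrt 3) \approx 0.0931$ (`hexagonal_whitespace()`): the stroma
has nothing left to cede, so the new crypt cannot be accommodated. The
check excludes the arriving crypt's own mass — it asks whether the
environment can receive it — and growth is followed through the 10-crypt
passage scale (`max_size`, config), the scale at which the diffusion
coefficient was actually measured and at which a centroid point source is a
meaningful idealization. We do not extrapolate the point source to
arbitrarily large patches: a cumulative centroid source grows without bound
for any $k$, which contradicts the observation that large patches sit at
ambient density; physically, a large patch injects new crypts across its
whole footprint, and the transient crowding that can nucleate a lesion is a
local, passage-scale event.

With every parameter fixed a priori ($\rho_0 = 0.007$, $D = 1.05$,
$s_0 = 0.265$, $\sigma_0^2 = 1$, hexagonal threshold), the simulated
accommodation limit — the smallest multiple whose breach probability by 90
years exceeds $10^{-3}$ (`find_threshold_multiple()`) — lands at 11–12
fold, and roughly 0.5–1% of clones at the 17-fold (12%/yr) scenario breach
by 50 years. Two published-scale claims are not reproduced by this
reconstruction and are left visibly failing in the acceptance tests rather
than absorbed by tolerance: the 19-fold scenario yields ~1% (not ~5%) at 50
years, and a decade of complete fission inhibition
(`intervention_comparison()`, mode `"zero"`, the default; mode
`"baseline"` reduces the rate to homeostatic instead) trims rather than
collapses the risk, because in this model breaches are short local bursts
that a distant pause cannot undo — and inhibition starting at mutation
acquisition can only time-shift a memoryless growth process. Interventions
are implemented exactly as time-rescaled Gillespie exposure, so both modes
are exact, and replicate counts auto-scale so the smallest reported
probability rests on at least 20 expected events, with Wilson intervals
throughout.

## Amplicon mutation calling

`build_noise_profile()` records, per amplicon position and alternate base,
the mean and SD of the alternate-read fraction across samples; zero-depth
entries are flagged and excluded. A candidate call requires the MAF to
exceed 4x the mean noise, or to exceed the mean by more than 3.29 SD — the
centring makes 3.29 correspond to the stated two-sided $P \le 0.001$; both
inequalities are strict, and boundary cases are tested. Confirmation
requires presence in every serial-section sample of the same patch and
absence from all wild-type samples; corrected MAFs subtract the mean noise
and are floored at zero, never exceeding the raw MAF. Codon 12/13
alternates for the activating-mutation screen are generated from the
glycine codons programmatically (the 12 missense single-base changes), and
calling demands >1000 reads in both gene amplicons and at least one mimic
control, MAF > 0.1% with >= 10 mutant reads in both, and mimic signal within
noise (<= mean + 1.96 SD, the one-sided 0.025 quantile; the mimic-side rule
is our operationalization and is configurable). Clone sizes follow from
corrected MAFs as `ploidy_factor * maf * total_crypts` (ploidy factor 1 for
X-linked male samples; an optional multiplicative stromal correction is
exposed but defaults to 1, since no published rule exists).

Calibration caveat, characterized rather than hidden: with beta-binomial
cross-sample noise, the 3.29-SD rule inherits the beta right tail. At
moderate overdispersion (SD ~ 0.15x mean at amplicon-typical depth) the
per-position false-positive rate is below 0.2%, consistent with the design
level; at heavy overdispersion (SD ~ 0.4x mean, shallow depth) it rises
toward ~0.5%. The serial-section confirmation step is what keeps final
calls clean in either regime.

`infer_kras_fission()` closes the loop from called clone sizes to a fission
rate by simulation-based (ABC-style) inference under the same pure-birth,
uniform-timing model, with a detection floor at the MAF sensitivity limit
(default 24 crypts, i.e. 0.12% MAF in a 10^4-crypt section at ploidy 2);
candidate rates are weighted by a Gaussian kernel on the RMS distance
between observed and simulated log-size quantiles, with the bandwidth set
to the first quartile of the distances.

## Problem sizes, reproducibility, and limitations

The packaged test suite runs reduced problem sizes (tens of patients,
$10^4$–$10^5$ simulation replicates, 12 spatial maps) chosen so the whole
suite completes in under two minutes while every stochastic assertion keeps
at least 3-sigma headroom; `scripts/acceptance.R` re-runs the analysis-scale
versions (120 patients, 20 maps x 200 draws, $10^5$–$10^6$ lesion
replicates, >= 10-20 seeded replicates per estimate) in a few minutes.
Every generator and estimator takes an explicit integer seed and is
bit-reproducible given it; pipeline artifacts carry seed and parameter-hash
sidecars, and rerunning a stage with the same seed reproduces identical
file hashes.

What the generator does not emulate — and what passing tests therefore do
not establish about clinical material: staining and detection error in
clone scoring, section-boundary fragmentation of patches, non-uniform age
structure of real cohorts (ages are uniform over the configured range, as
no density is published), spatial correlation of mutations, image-derived
segmentation noise in crypt areas beyond log-normal scatter, and
mechanical crypt-crypt interactions beyond the diffusion idealization. The
outlier-exclusion rule used on real cohorts is exposed as a config flag
(z-score on average patch size, default off) but no claim depends on it.
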