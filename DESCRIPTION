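Package: cryptdyn
Title: Clonal Dynamics, Fission-Fusion Rates and Crypt Diffusion in Human Colonic Epithelium
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic-process analysis of clonal expansion in human colonic
    epithelium. Provides a synthetic-cohort generator with ground-truth event
    logs; intracrypt Moran dynamics and the fixed-clone accumulation ratio;
    pure-birth (Yule) inference of crypt fission rates from age-stratified
    patch-size distributions; classification of branched crypt forms (FUFIs)
    and proportionality-based crypt fusion rate estimation; a point-source
    crypt-diffusion model with trajectory-ensemble inference of the diffusion
    coefficient from spatial stromal-fraction profiles; forward simulation of
    the fission-rate threshold beyond which new crypts can no longer be
    accommodated (lesion formation); and amplicon mutation-calling filters
    with clone-size estimation from mutant allele frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
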