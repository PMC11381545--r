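Package: microflux
Title: Longitudinal Microbial Flux Analysis of Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models the temporal turnover ("microbial flux") of gut microbial
    species in longitudinal shotgun-metagenomic cohorts. From species-by-sample
    abundance tables the package calls presence/absence with a gamma-distribution
    detection threshold, estimates per-species inflow (absence-to-presence) and
    outflow (presence-to-absence) transition probabilities with a two-state
    Markov chain, classifies persistent (PCS) and transient (TCS) colonizing
    species, computes Kaplan-Meier species-retention curves, aggregated PCS/TCS
    Z-scores and consecutive-visit dynamics, destabilization statistics (Jaccard
    similarity, stratification), enrichment and overlap tests, and
    random-intercept mixed-model associations with host phenotypes. A synthetic
    cohort generator with known ground-truth colonization dynamics makes every
    stage testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    survival,
    lme4,
    lmerTest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
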