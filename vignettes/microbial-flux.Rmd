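---
title: "Modeling microbial flux in longitudinal metagenomic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microbial flux in longitudinal metagenomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microflux)
```

## The problem

Cross-sectional gut-microbiome surveys cannot distinguish a species that has
colonized a host for years from one sampled mid-transit. With repeated visits
per subject, occupancy itself becomes observable: each species traces a
presence/absence path over a subject's visits, and the statistics of those
paths separate persistent from transient colonizers. `microflux` implements
that analysis end to end, together with a synthetic-cohort generator that
makes each stage verifiable against known ground truth.

## Detection: when is a species "present"?

Calling absence from a shotgun profile is a detection-limit question, not a
biological one. We pool every nonzero abundance in the cohort, transform to
log2 of the per-million scale, and fit a gamma distribution by maximum
likelihood (`fitdistrplus`). The presence threshold is the fitted
distribution's quantile at `percentile` (default 0.01): a species is present
in a sample iff its log2 per-million abundance strictly exceeds it.

Choices worth stating:

* **Pooled, global fit.** One detection model for the whole cohort, not one
  per species — per-species fits would be data-starved, and the detection
  limit is a property of the assay, not the organism.
* **Gamma support.** Log2 values ≤ 0 (abundance ≤ 1 per million) lie outside
  the gamma support and are excluded from the fit. Such abundances can never
  exceed a positive threshold, so exclusion only makes calling conservative.
* **Strict inequality.** A value exactly at the threshold is absent. The
  boundary case is measure-zero in practice; strictness keeps the rule
  unambiguous.
* **Guard rails.** Fewer than 100 pooled positive values, or a degenerate
  (constant) pool, is an error rather than a silent bad fit.

The fit itself is verified against the closed-form gamma quantile: on 10^5
draws from gamma(shape 2, rate 1) the fitted 1% threshold lands within 2%
relative error (see `tests/testthat/test-detection.R` and the acceptance
script).

## The two-state Markov chain

For each species we pool, across all subjects, the transitions between
*adjacent observed visits* (a skipped visit index does not break adjacency —
real cohorts have missing visits, and the pair of visits actually observed is
still a consecutive observation of the same host). The four counts
(absent→absent, absent→present, present→absent, present→present) sum, for
every species, to the total number of pairs — an invariant asserted on every
run. Row normalization gives the maximum-likelihood transition probabilities:
`inflow` (absence→presence) and `outflow` (presence→absence).

Species never present, or always present, carry no information about a
two-state chain and are excluded. A species whose pairs never start from one
of the states has that row's probability left `NA` — flagged, never imputed,
so downstream consumers see exactly what was estimable.

Classification uses strict thresholds: PCS when inflow > 0.3 and
outflow < 0.3, TCS when outflow > 0.3 and inflow < 0.3, everything else
(including `NA` rows) unclassified. The 0.3/0.3 defaults are exposed as
parameters.

## Retention as survival

Colonization episodes are survival records: the clock starts at the first
observed presence, loss (the first subsequent absence) is the event, and an
episode still running at the subject's last visit is right-censored. Time is
measured in visit intervals (about three months in a quarterly cohort) — the
only clock the design observes. The product-limit estimator comes from
`survival::survfit`.

Two conventions are explicit toggles rather than silent choices:

* **Episodes.** Default `episodes = "first"`: a re-colonization of the same
  host is not an independent record (within-subject pseudo-replication);
  `"all"` keeps every episode.
* **Left entry.** Default counts episodes already present at visit 1 from
  visit 1; `require_absence_before = TRUE` demands an observed absence first.

A species first seen at a subject's final visit has no interval at risk and
yields no record (a zero-length record would carry no information and break
the duration ≥ 1 invariant). One further property worth knowing: adding a
censored record with a late exit time *raises* earlier survival estimates
slightly (it enters the risk sets), it never adds steps.

## Aggregated scores and destabilization

Abundances are standardized per species over **all** cohort samples, zeros
included, with the n−1 standard-deviation denominator: z_ij = (A_ij − μ_i)/σ_i.
Zero-variance species are dropped with a warning. The class score
Z(j) = Σ_i z_ij / √n sums over *all* class members, detected or not (their
zeros are informative and standardized); under iid-normal z this is standard
normal for every class size n, which the tests check by Kolmogorov–Smirnov at
n ∈ {5, 50, 500}.

Consecutive-visit dynamics then give, per subject-pair, μ = (Z_t + Z_t+1)/2
and Δ = Z_t+1 − Z_t. Pairs with μ_TCS > 2 define TCS-enriched host states,
μ_TCS < −2 TCS-depleted ones (strict, monotone in the cutoffs). Community
turnover is measured by the Jaccard similarity of adjacent presence sets, and
the enriched-vs-depleted comparison is a one-sided test (enriched less
similar); both the Wilcoxon rank-sum and Student's t versions are
implemented because both appear in practice — the Wilcoxon is the default.
Richness dynamics default to species richness from the presence matrix; gene
richness is used when a gene count table is supplied (the two differ, and
which one is in play is the caller's explicit choice).

## Associations

* **Co-abundance**: pairwise Spearman among PCS ∪ TCS species,
  Benjamini–Hochberg adjusted, signed edges below the adjusted-p cutoff.
* **Function enrichment**: per binary annotation, a univariate regression of
  the species' inflow (or outflow) score on the annotation; with a binary
  predictor the coefficient is exactly the annotated-minus-unannotated mean
  difference, which the tests assert. Enriched = adjusted p < 10⁻³ and
  coefficient > 0. Annotations present in no or all species have no contrast
  and are skipped.
* **Differential abundance**: per-species two-sided Wilcoxon between groups,
  split by direction of the median (tie-broken by mean) shift.
* **Overlap enrichment**: the 2×2 hit × class table over the universe, with
  a Pearson chi-square (no continuity correction) and the exact
  hypergeometric upper tail P(X ≥ k). The hypergeometric is validated against
  exhaustive enumeration of all hit sets on universes up to 15.
* **Phenotype models**: Y = Z_PCS·β_PCS + Z_TCS·β_TCS + u_subject + ε with a
  subject random intercept (`lme4`, Satterthwaite p-values via `lmerTest`).
  When every subject is observed once the random intercept is unidentifiable
  and the model falls back to OLS with a warning; when the between-subject
  variance estimate is at the zero boundary the mixed fit *is* the OLS fit,
  a reduction the tests verify to 10⁻⁶. Per-species models
  Y = A_i·β_i + u + ε are screened by the explained variance of the fixed
  effect, var(fixed predictions) / (var(fixed) + var(random intercept) +
  var(residual)) — the marginal-R² style decomposition, stated here
  explicitly so results are reproducible — with a 10% retention threshold.

## The synthetic cohort

The generator is test scaffolding with teeth: it encodes a *possible*
generative process, not a claim about any real cohort.

* Occupancy: per-species two-state chain; the initial state is drawn from
  the chain's stationary distribution π = inflow/(inflow + outflow) (π := 0
  for the degenerate both-zero chain, recorded in the truth table). Starting
  at stationarity keeps prevalence time-homogeneous, so transition-frequency
  recovery tests are well posed.
* Abundance-when-present: log-normal per species — a simple heavy-tailed
  positive model consistent with a log-scale detection fit. Default meanlog
  drawn once from N(0, 1.5), sdlog 1.
* Sequencing noise: multinomial read sampling at `read_depth` (default 10⁷),
  optionally at marker-gene level with the species mass split uniformly over
  its markers (default 100), which gives the <10%-markers rule its
  semantics.
* Phenotypes: Y = Z_PCS·β_PCS + Z_TCS·β_TCS + u_subject + ε, the generative
  mirror of the association model.
* Case/control: occupancy at the stationary prevalence; designated species
  get an abundance fold-change and/or an occupancy increase in cases. In the
  power tests a "strong" effect is both knobs at once (fold-change 2³ with
  +0.4 occupancy) — a bloom of transient colonizers shifts how often they are
  present, not just how much of them there is; a pure abundance shift on a
  rarely-present species is nearly invisible to a rank test and is exactly
  the regime the calibration test covers instead.
* Reproducibility: one master seed expands into fixed per-stage substreams,
  so identical configs are bit-identical, stage by stage.

What the generator does **not** emulate: strain structure, phylogenetic
correlation, ecological interactions (any PCS–TCS anticorrelation in real
data is emergent, not mechanistic here), time-varying transition
probabilities, and compositional coupling beyond closure. Passing recovery
tests therefore demonstrates correctness of the estimators under the stated
model, not robustness to everything real data can do.

Default dimensions are a wellness-style cohort: 86 subjects × 4 visits × 300
species. Recovery tests run at 150 subjects × 6 visits × 200 species with
inflow/outflow uniform on (0.05, 0.95), where the noiseless mean absolute
error of both probabilities is below 0.03 and, through multinomial noise at
10⁶ reads plus gamma detection, below 0.08 with rank correlation above 0.9 —
sizes chosen so the full suite and the acceptance script each run in well
under a minute on one CPU.

## Known limitations

* The chain is first-order and time-homogeneous; seasonal or diet-driven
  inhomogeneity is out of scope.
* The pooled detection threshold treats the assay, not the species, as the
  limiting factor; systematically under-detected taxa will have inflated
  outflow.
* Transition pooling across subjects reports one cohort-level inflow/outflow
  per species; between-host heterogeneity in colonization dynamics is not
  modeled.
* Relative abundances are compositional: a strong enrichment in a few
  species induces genuine (not artifactual, but not ecological) depletion
  calls elsewhere, visible in the case/control simulations.
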