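---
title: "Strain sharing and transmission inference: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain sharing and transmission inference: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When two hosts carry highly similar lineages of the same gut bacterial
species, it is tempting to read that as host-to-host transmission. But two
hosts can also acquire the same strain independently from a shared
environment, or carry related strains because their communities were shaped
by similar diets and seasons. `strainshare` implements the strain-comparison
machinery, the dyad-level sharing statistics, a cumulative filter cascade
that upgrades raw sharing events to putative transmission events, and the
enrichment and covariate analyses needed to probe these alternatives — plus
a forward simulator that generates cohorts with known transmission ground
truth so every stage can be validated.

## Strain comparison from allele profiles

The atomic input is an *allele profile*: for one sample and one species,
the counts of A, C, G and T at every covered genome position (0-based,
scaffolds concatenated in sidecar order). From profiles we compute:

* **Presence.** A species is present in a sample when at least `min_breadth`
  (default 0.25) of its genome is covered at `min_depth` (default 5) or
  more. The 25%/5x defaults retain rare, low-abundance strains while
  controlling false positives. Species failing *joint* presence in a pair
  are excluded from every numerator and denominator downstream. Whether the
  breadth fraction should be measured at 1x or at the presence depth is
  genuinely ambiguous in the profiling literature; we measure it at
  `min_depth` (the stricter reading) and expose both knobs.

* **Allele detection.** At one site, a base is a detected allele when it has
  at least `min_count = 2` reads and at least `min_freq = 5%` of the site's
  depth. Upstream profilers use an error-aware null model for this call;
  fixed thresholds are simpler, deterministic, and adequate at the error
  rates the simulator emulates (0.1% per read at 20x).

* **popANI and conANI.** Comparison is restricted to sites with depth at
  least `min_depth` in *both* samples. A site is a *population* (popANI)
  substitution only when the two samples share no detected allele, major or
  minor — the microdiversity-aware rule; it is a *consensus* (conANI)
  substitution when the majority bases differ. Consensus ties are broken
  alphabetically (A < C < G < T) for determinism. popANI is therefore never
  below conANI: disjointness of allele sets implies differing consensus
  (the consensus base always passes detection at the default thresholds).
  A comparison with no comparable sites is flagged non-evaluable and can
  never count as sharing.

* **Sharing.** Two samples share a strain when popANI is at least
  `ani_threshold = 0.99999`. The threshold is exact: one substitution in
  50,000 compared sites (popANI 0.99998) is not sharing; zero is.

## Dyad networks and categories

A dyad's *sharing rate* is shared strains over jointly present species.
Dyads with no jointly present species have an undefined rate and are
excluded from category statistics with a warning. Field-study dyads are
categorised by the windows used in the observational design: longitudinal
self-pairs 120–150 days apart; hosts whose lifespans never intersect;
contemporaneous hosts of different social groups sampled less than 150 days
apart; same-group close partners sampled at most 4 days apart. Category
contrasts run through two routes: all pairwise Welch t-tests with
Benjamini–Hochberg adjustment over the family of category pairs (Welch
because category variances have no reason to be equal), and one-way Tukey
HSD.

Downsampling robustness re-runs the Tukey comparison on datasets reduced to
one sampling unit per host. Taken literally, "one random sample per
individual" would delete every longitudinal self-pair and make that
category untestable under downsampling, which is not what the analysis is
for; we therefore treat a host's longitudinal pair as one selectable unit,
so the longitudinal category survives while no host ever contributes two
independent units.

The marker-gene alternative (`phylo_share`) flags pairs whose normalised
phylogenetic distance is at or below 0.1. "Normalised distance ≤ 0.1" and
"the 10th percentile of pairwise distances" are different readings of the
same convention; we implement max-normalisation as the default and the
species-specific quantile as an explicit mode, asserting neither as
canonical. Both are invariant to global rescaling of the distance matrix.

## The transmission-filter cascade

Raw strain sharing is upgraded to putative transmission through cumulative
criteria: tier 1 requires the strain to have been absent from the recipient
before the transplant; tier 2 additionally requires the strain to be unique
to one donor pre-transplant; tier 3 additionally unique to one recipient
post-transplant. Tier sets are nested by construction. Uniqueness is at the
strain level — divergent conspecific strains elsewhere do not disqualify an
event — and uses the same global popANI threshold as dyad sharing.

Three operational choices deserve note. "Shared prior to transplant" is
evaluated as donor versus recipient-pre (matching the criterion's intent of
"previously absent from recipient" relative to the putative source), with
recipient-pre versus post available as an alternative mode. Donor
uniqueness is evaluated against the other donors by default, with an
`all_pre` mode that also scans recipients' pre-transplant samples.
Mismatched pairs run through the identical cascade with the mismatched
donor treated as the putative source, so the matched/mismatched contrast is
computed under identical criteria. At each tier, a dyad's rate uses as its
denominator the jointly present species that survive that tier's cumulative
filters, so numerator and denominator shrink together.

## Enrichment and covariates

Family composition differences between event groups use Fisher's exact
test (exact for 2x2; seeded Monte Carlo with 1e5 draws for larger tables),
followed by per-family log2 odds ratios with a Haldane–Anscombe +0.5
correction on zero cells and Woolf confidence intervals. Trait enrichment
in a filtered event subset is tested by drawing subsets of the observed
size from the full event list without replacement; the p-value is the raw
proportion of draws at least as extreme as the observation (one-sided in
the direction of the observed deviation by default, with a two-sided
absolute-deviation mode). The attainable floor is 1/`n_perm`; no +1
smoothing is applied, so the reported value is exactly the proportion of
permutations. Unknown-trait events are excluded from the observed and
permuted sets alike, with a message.

Dyad covariates are Bray–Curtis dietary dissimilarity (Jaccard on
presence/absence as an alternative — both conventions circulate and we
default to the compositional one), circular month distance (bounded by 6),
and rainfall summed by the two samples' collection months (mean as an
alternative mode; the additive default is declared, not derived). Each
covariate is related to the sharing rate by ordinary least squares with a
two-sided t-based p on n − 2 degrees of freedom.

## The forward simulator

The simulator emulates two designs: a transplant cohort (five donors
sampled once, eight recipients sampled immediately before and 15–30 days
after a single-donor transplant) and an observational cohort of sample
dyads (20 never-overlapped, 23 different-group, 26 close-partner and 22
longitudinal pairs by default, matching the field design; the study's own
description of these counts is internally inconsistent between 20/23 and
23/20, and we follow the sampling-protocol description).

Per species, `n_haplotypes` haplotypes each carry `divergence = 10` private
substitutions at disjoint sites of a 10,000-site genome, so any two
haplotypes differ at 20 or more sites and always fall below the 99.999%
sharing threshold, while transmitted copies are exact (mutation rate 0 by
default) and sit at it. Species prevalence is geometric across hosts,
producing the rare-versus-widespread contrast the tier filters exploit.
Sequencing draws Poisson depth (mean 20 per site, lognormal per
sample-species abundance multiplier with sdlog 0.5 so the presence filter
has real work to do) and misreads each read with probability 0.001.

In the transplant design, recipients' pre-transplant strains survive
depletion with probability 0.2 (an antibiotic-conditioning analogue),
designated-donor strains engraft with probability 0.8, and recipients
independently acquire a designated environmental haplotype per species with
probability 0.05 — the transplant parameters used throughout validation.
In the social design, each dyad's two hosts carry disjoint personal strain
pools; a shared environment offers the environmental haplotype per species
with probability `social_env_rate`, and it is acquired *jointly* with
probability `env_base` plus weighted contributions of diet similarity,
seasonal proximity and rainfall. Longitudinal second samples retain strains
with probability `persistence`; close partners exchange strains with
probability `social_transmission_prob`. Every strain instance carries
exactly one ground-truth origin label (transmitted, pre-existing, or
environmental), so precision of the cascade can be scored directly.

What the simulator does *not* emulate: read-level artefacts (mapping bias,
chimeras), strain recombination, within-species gene content variation,
compositionality of relative abundances, and database incompleteness.
Passing tests therefore demonstrate the correctness and calibration of the
inference machinery under the generative model, not performance on real
metagenomes.

## Validation experiments and problem sizes

The test suite validates each stage at sizes chosen to keep the whole run
desk-scale:

* popANI/conANI agree exactly with a brute-force site enumeration on 1,000
  random toy profile pairs of up to 50 sites.
* On a default transplant cohort (80 species, 10 kb genomes), tier sets are
  nested, the matched-versus-mismatched sharing contrast is non-decreasing
  from tier 0 to tier 3, and with environmental acquisition switched off
  and strictly per-host strain pools, every matched tier-1 event is a true
  transmission.
* Permutation p-values are calibrated under the null (500 datasets of 200
  events; type-I error at the 5% level inside its binomial confidence
  band) and agree with the exact hypergeometric tail within three Monte
  Carlo standard errors at 10,000 permutations.
* BH, Welch, Tukey HSD and OLS agree with independent closed forms to
  1e-10.
* The covariate-recovery experiment uses a controlled single-covariate
  configuration — diet coupling only (`diet_effect = 0.85`, season and
  rainfall couplings 0, `env_base = 0.05`, `social_env_rate = 0.35`,
  `base_carriage = 0.15`), 20 different-group dyads and 2 kb genomes so
  one hundred replicates stay fast. The fitted diet slope is positive in
  at least 95 of 100 replicates; setting the diet coupling to zero leaves
  sign recovery at chance.
* With full within-host persistence, longitudinal self-dyads attain the
  highest mean sharing rate among the four categories.

## Numerical choices and degenerate inputs

Consensus ties break alphabetically; non-evaluable comparisons are flagged
and never shared; dyads with undefined rates are excluded listwise from
category tests (and logged); categories with fewer than two rates leave
their pairs flagged not-computable rather than dropped; an all-zero
distance matrix flags every pair as sharing, with a warning; zero cells in
odds-ratio tables are Haldane-corrected rather than propagating infinities;
every stochastic operation takes an explicit seed and restores the caller's
RNG stream.

One validation finding deserves emphasis. The recipient-uniqueness filter
(tier 3) removes strains detected in more than one recipient
post-transplant to guard against recipient-to-recipient exchange. When two
recipients share a designated donor — unavoidable with eight recipients
and five donors — both engraft the same donor strains, and tier 3 then
removes *true* transmission events from matched pairs (at one validation
seed, every matched sharing event removed at tier 3 was a ground-truth
transmission, most via such sibling recipients). Consequently the
matched-versus-mismatched contrast, monotone through tiers 0–2 in every
cohort we simulate, can tick down at the tier-2-to-3 step in a minority of
cohorts even though the *precision* of surviving events never decreases.
The last filter trades recall for precision; on small cohorts the rate
contrast is a noisy summary of that trade.

## Known limitations

The per-read error model attributes misreads to the site's majority allele,
which is adequate at 0.1% error but would misstate minor-allele noise at
much higher error rates. Fixed allele-detection thresholds, rather than a
depth-aware null model, slightly over-call minor alleles at very high
depth. The social simulator generates dyads independently rather than as a
connected population, which matches the dyad-level analyses here but cannot
represent network-level confounding. None of these affect the contracts the
tests assert.
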