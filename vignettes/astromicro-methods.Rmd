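---
title: "Methods: longitudinal crew-microbiome analysis with astromicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal crew-microbiome analysis with astromicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`astromicro` analyses longitudinal 16S OTU tables from small spaceflight
cohorts: a few subjects sampled at labelled sessions before (L-240..L-60),
during (FD7..FD360) and after (R+0..R+180) a mission, alongside spacecraft
surface swabs, negative controls, and a left-censored plasma cytokine
panel. This vignette records the models the package implements, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the methodology was genuinely
open.

## Filtering, contaminants, and prevalence rules

OTU support filtering keeps exactly the OTUs with at least `min_reads = 4`
reads in at least `min_samples = 4` samples; the rule is idempotent and
never touches the sample set. Contaminant removal drops any OTU with
`min_reads = 5` or more reads in *any single* negative-control sample
(PCR or extraction-kit); the rule is deliberately per-control-sample, not
summed across controls, reading "in either control" literally. Control
columns leave the table afterwards. Running with no controls requires an
explicit opt-out, because silently skipping decontamination is the kind of
mistake that surfaces two figures later.

Depth correction is total-sum scaling (relative abundance). Rarefying
counts is out of scope; every downstream procedure here is defined on
proportions or on presence/absence.

The preflight core microbiome of a body site contains the taxa (OTU or
genus level; genus sums counts over member OTUs, with unclassified genera
keyed by family plus "(uncl.)") present with >= 4 reads in >= 75% of the
site's preflight samples. Both thresholds are arguments. For ISS-surface
residents the published rule conjoins two clauses that are redundant if
read literally ("detected at every relative time point" and "not zero for
two or more consecutive time points"), so the package computes both
readings — `qualifies_strict` (nonzero at every relative timepoint) and
`qualifies_relaxed` (no run of >= 2 consecutive zero timepoints) — reports
both flags, and defaults summaries to strict. Strict residents are a subset
of relaxed residents by construction.

## Diversity, distances, ordination, PERMANOVA

Shannon diversity is -sum p_i ln p_i in nats (the natural-log convention of
the underlying vegan tooling), invariant under count rescaling. Rarefied
richness is the closed-form expectation E[S_n] = sum_i [1 - C(N-N_i,n)/C(N,n)],
evaluated through `vegan::rarefy` (log-space binomials); the rarefaction
depth defaults to the minimum library size of the compared samples and is
recorded in the output, since the choice is a run parameter, not a constant.

Bray-Curtis comes in the weighted flavor sum|a_i-b_i| / sum(a_i+b_i) on
relative abundances and the unweighted flavor (A + B - 2J)/(A + B) on the
presence pattern of the filtered counts (count > 0, not a read threshold).
PCoA double-centers -D^2/2 and eigendecomposes; negative eigenvalues (usual
for Bray-Curtis) are reported but coordinates are returned only on positive
axes, and each axis is flipped so its largest-magnitude loading is positive,
making ordinations reproducible across platforms. PERMANOVA is the
single-factor distance decomposition (`vegan::adonis2`); p-values are
permutation-count-exact, p = (1 + #\{F* >= F\})/(1 + n_perm), so the
smallest attainable p is 1/(n_perm+1). With strata, labels permute within
strata only — the conventional reading of "stratifying by body site" — via
`permute::how(blocks = )`.

## Mission-stage inference

Contrasts against the preflight baseline use a random-intercept linear
mixed model, `value ~ level + (1 | subject)`, fit by REML (lme4), with Wald
normal tests. Satterthwaite-style degrees-of-freedom machinery is
deliberately not reproduced; the package's guarantees are framed as
parameter recovery (the acceptance suite checks 95% CI coverage of a
planted effect within 93-97% over 500 simulations) rather than p-value
equality with any particular tool. Singular fits fall back to fixed-effects
OLS and the record says so. In balanced designs the fixed-effect estimates
coincide with OLS group differences regardless.

Distance-based stage designs use only within-astronaut pairs — distances
between different astronauts are excluded — and classify each pair as
within- or between-stage for a chosen comparison (preflight-inflight or
preflight-postflight). These observations are pseudo-replicated (each
sample participates in many pairs); the mixed-model-on-distances design is
reproduced as the field uses it rather than replaced by a permutation
framework, and this caveat travels with the output. Distance-to-baseline
trajectories report, per astronaut and timepoint, the mean distance from
that timepoint's samples to all of the astronaut's preflight samples, with
the within-preflight mean as baseline.

Inter-subject convergence is tested by comparing inter-astronaut distances
among preflight samples against inflight (or postflight) samples with a
Welch t-test. Attribution ranks genera by reduction in the coefficient of
variation of relative abundance across subjects, CV_pre - CV_in, computed
on per-subject mean abundance within each stage: pooling a subject's
replicates first avoids conflating within-subject with between-subject
variance (whether the original analysis used per-sample or per-subject
abundances is unstated; the per-subject reading is the variance-correct
one). Genera with zero stage mean have undefined CV and are flagged and
excluded from the positive-reduction total; the cumulative fraction over
positive reductions is nondecreasing and ends at 1.

The differential-abundance screen is plumbing, not a reimplementation of
published DA methods: subject-centered log relative abundance (floored at
half the minimum nonzero value per OTU), a stage contrast tested by
permuting stage labels within subject, and BH at FDR 0.10. An externally
produced candidate list bypasses it verbatim. OTUs absent from every
compared sample are dropped with a warning rather than an error, because
site subsets of a globally filtered table legitimately contain such rows.

## Cytokine models

Each analyte carries a transform: identity, log (the default), or
reciprocal-censored. The reciprocal maps concentration c to 1/c, turning a
left-censoring bound L (value known only to be below the detection limit)
into right-censoring at 1/L, which a right-censored lognormal regression
(`survival::survreg`, normal errors on the log scale, upper-tail survival
terms for censored observations) absorbs; the design is additive in subject
and session with Wald tests of FD7, FD180, R+0 and R+180 against L-60.
With no censored values the ML solution coincides with OLS on the logs to
numerical tolerance, and the censored log-likelihood at the MLE always
dominates the OLS parameters — both are tested. Analytes with more than
50% censored records (configurable) are excluded with a reason; no
published number exists for "too many censored observations", so the
threshold is explicit. BH correction is applied once across the full
analyte x session grid (19 analytes x 4 sessions = 76 tests in the
reference design) and the realized p threshold is reported alongside the
q-values, since different rounding conventions for that threshold are a
known source of discrepancies between a Methods section and its Results.

## The Somers' D association screen

The centrepiece. Relative abundance is discretized so that only >= 2-fold
changes register: Y = the nearest integer to log2(RA) for RA > 0 (exact
half-levels round away from zero — a measure-zero case for real data, but
synthetic data can hit dyadic boundaries); for RA = 0, Y is one level below
the OTU's minimum positive level *within the analysis subset* (the five
blood-matched sessions and the screened subjects), the narrower reading of
"the lowest level". Session pairs are formed within subject only, over the
sessions where both a stool level and an uncensored cytokine value exist;
censored cytokine values have unknown X and drop the session from pairing.

Pooled over subjects, D = (C - Q) / T, with C and Q the concordant and
discordant counts among pairs and T the number of pairs untied on Y; pairs
tied on the cytokine but not on Y stay in the denominator. The standard
error is a delete-one-subject jackknife, SE^2 = (g-1)/g * sum_i (D_(i) -
Dbar)^2 over the g subjects contributing untied pairs; the resampling
method behind the original analysis is unnamed, and the delete-one-cluster
jackknife is the standard estimator that respects within-subject pairing.
p-values are two-sided normal on D/SE, matching the z-based inference of
the original tooling. Two caveats are deliberate: SE below numerical zero
(all leave-one-out replicates equal, e.g. perfect concordance) marks the
combination degenerate with the p suppressed; and with as few as five
contributing subjects the normal reference is mildly anti-conservative —
the package's calibration checks therefore run the null screen on a
nine-subject cohort, where the flagged fraction sits at the nominal FDR.
A t reference with g-1 degrees of freedom would calibrate at g = 5 but
cannot produce the small p-values the FDR-1% screen requires, so it was
rejected.

Combinations failing to support at least 10 valid comparisons are excluded
before any p-value is computed; "comparisons" is read as subject-session
observations with RA > 0 and uncensored cytokine (the `comparison_unit =
"pairs"` reading is exposed as an option). BH at FDR 0.01 runs across the
computed p-values only, mirroring a screen in which only part of the full
candidate x analyte grid is evaluable. D < 0 is a negative association
between cytokine concentration and OTU abundance.

## The synthetic cohort generator

Counts are Dirichlet-multinomial: per sample, a Dirichlet draw around the
subject's generative composition (concentration `concentration`, default
50; smaller is more overdispersed) feeds a multinomial at a lognormal
library size (median ~20k reads, sdlog 0.5 — the real distribution is
unpublished, so both are configurable). The generative composition is a
softmax of site baseline (heavy-tailed gamma weights, evenness controlled
by `base_shape`) plus subject-specific log intercepts (SD
`subject_effect_sd`, default 1, winsorized at +/-2 SD so one subject cannot
swallow the composition through a single taxon; per-taxon overrides model
taxa with unusually strong personal signatures), plus per-sample
"day-to-day" fluctuations (SD `temporal_sd` in log2 units, default 0.5),
plus planted stage fold changes. Inter-subject convergence multiplies the
subject intercepts of designated taxa by `convergence_factor` < 1 on
inflight samples. ISS-surface samples mix a surface-resident profile with
the concurrent crew's mean skin composition (weight 0.3), giving the
skin-surface similarity analyses signal. Negative controls contain the
planted contaminant taxa at >= 5 reads plus sub-threshold noise, so the
contaminant rule recovers the planted set exactly. Cytokine log
concentrations are analyte baseline + subject intercept + planted session
effects + coupling terms + noise, where a coupling adds strength x (centered
generative log stool abundance of the coupled taxon); acting on the
generative abundance rather than realized counts avoids circularity while
keeping the concordance recoverable. Values under the detection limit are
clamped and flagged censored.

What the generator does not emulate: sequence-level artifacts (chimeras,
primer bias), taxonomic misassignment, real rank-abundance shapes beyond
the gamma family, date-fuzzy matching of stool to blood sessions (synthetic
stool is matched to sessions by exact label; a date-tolerance matcher is
not implemented), and hormone/virus time series. Passing tests therefore
demonstrate that the machinery recovers structure it can represent, not
that real data contain such structure.

A compositional lesson from building the convergence scenarios: because
relative abundances are closed, converging taxa that carry appreciable mass
necessarily converge everything else through the denominator, and the CV of
five subjects is both capped at 2 and noisy, so ranked background
reductions (an order-statistics effect — the null generator's mean
reduction is zero) can swamp a planted signal. The attribution check
therefore plants strong personal signatures (subject SD 2) on five
low-abundance genera against a quiet, broadly shared background
(subject SD 0.1, day-to-day SD 0.05 log2, ~1e5-read libraries) in a
nine-subject cohort. The end-to-end association scenario couples a cytokine
(strength -1.5, noise SD 0.2) to an abundant OTU that itself changes ~5-fold
inflight, with an R+180 stool collection included so all five blood sessions
pair — emulating approximate-time matching of stool to the late blood draw.

## Problem sizes and numerical choices

The test suite runs cohorts of 30-100 taxa, 5-9 subjects and 10-11
sessions; calibration and power checks use 100-500 simulations (null
PERMANOVA: 200 runs x 199 permutations; mixed-model coverage: 500 fits;
end-to-end recovery: 100 full pipeline runs), sizes chosen so the whole
suite documents the statistical properties at Monte-Carlo error a reader
can reason about. Numerical guards worth knowing: jackknife z-scores are
floored at p = 1e-300 before FDR so underflow cannot produce an illegal
p = 0; PCoA treats eigenvalues below 1e-10 of the spectrum as zero;
discretization ties at exact half-levels round away from zero; permutation
p-values are count-exact, never zero. Seeds are explicit arguments
everywhere randomness occurs, and identical seeds reproduce cohorts
byte-for-byte.

## Known limitations

Multi-factor PERMANOVA, UniFrac-style phylogenetic metrics, Chao1/ACE,
mixture-model decontamination, rarefaction-based normalization, Somers' D
confidence intervals via variance-stabilizing transforms, and time-lagged
associations are all out of scope. The distance-design mixed models inherit
the pseudo-replication of their field-standard formulation. The jackknife
normal p-values should be read cautiously below ~7 subjects, as discussed
above.
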