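---
title: "corestab: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corestab: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

corestab analyses longitudinal gut-microbiome cohorts sampled across three
life stages — Infants (I), Adults (A) and Elders (E) — for four questions:
which taxa form a prevalence-defined core; how fast an individual's taxon
set drifts over time; how stable each individual's community is in the sense
of Taylor's power law; and how robustly the community's functional capacity
withstands taxonomic perturbation. This vignette documents the models, the
conventions chosen where the field's usage is ambiguous, and the limits of
what a green test establishes. All empirical numbers cited here are computed
by the package's own test suite or acceptance script, never transcribed from
elsewhere.

## Data model

The universal input is an `abundance_table`: a taxa-by-samples matrix of
relative abundances (columns sum to 1, enforced to 1e-9 with repair-and-warn
above 1e-6) joined to per-sample metadata (sample id, individual id, age
group, collection day, subject age in years). Collection days are re-based
per individual so the first sample is day 0; the age group must be constant
within an individual. Presence is **always** "abundance strictly greater
than the detection threshold", 1e-4 by default. The strict inequality is a
convention fixed once and used identically by prevalence, cores and every
Jaccard computation; "at least" thresholds on *prevalence* are inclusive
(`>=`), mirroring the phrase "in at least 80% of samples".

Results are serialized as TSV with 10 significant digits — enough that
write → read → write round trips are byte-identical — plus a JSON manifest
(config, seed, versions) from which `rerun_from_manifest()` reproduces a
pipeline run bit-exactly.

## The synthetic cohort generator

The generator stands in for the real sequencing data so every downstream
stage is testable. Its defaults are the emulated study design:

* 10 individuals per age group (ages drawn uniformly in 2–5, 27–44,
  69–81 years), a target of 8 samples each;
* sampling intervals of 75 ± 25 days (floored at 1), giving follow-ups of
  roughly 360–750 days;
* 60 genus-level taxa whose design means follow a geometric rank-abundance
  ladder from 0.15 down to 1e-3 (before closure), with a per-individual
  lognormal effect (sd 0.5 on the log10 scale) reflecting the strong
  inter-individual variation typical of gut cohorts;
* temporal fluctuations obeying Taylor's law `sigma^2 = V * mu^(2*beta)`
  with `V = 0.3`, `beta = 0.75` (midway between the Poisson class
  `beta = 1/2` and the exponential class `beta = 1`);
* a core/transient prevalence structure: the top 40% of taxa by design mean
  are "core" with presence probability 0.95 in every group; the rest are
  transient with baseline 0.45 and an additive per-group trend of +0.1 per
  age step, so expected prevalence is ordered I < A < E and core size grows
  with age.

Three design choices deserve explanation.

**Fluctuation law.** A zero-truncated normal with target sd
`sqrt(V) * mu^beta` sounds natural but is unusable at `V = 0.3`: the target
sd exceeds the mean for all but the dominant taxa (`sigma/mu =
0.55 * mu^(-1/4)`), so truncation removes 25–40% of the mass and the
realized draws have neither the designed mean nor the designed sd. The
default is therefore a gamma draw with exactly the designed first two
moments on positive support (`fluctuation = "truncnorm"` is retained for
comparison).

**Detectability floor.** "Present" draws are floored at 3 times the
detection threshold, and absence is an explicit Bernoulli event. Without
the floor, the heavy fluctuation law sends many draws of a *present* taxon
below the detection limit, and no taxon — however abundant — could reach
90%+ prevalence; with it, realized prevalence equals the configured presence
probability, which is what the core/transient structure and the real
100%-prevalence cores require. The floor's distortion of the designed
moments is a few percent for core-ranked taxa.

**Noiseless mode.** A diagnostic mode for estimator oracles: each taxon's
trajectory is `mu ± sigma * sqrt((n-1)/n)` alternating over an even number
of time points, so the sample mean and (n−1)-denominator sd equal `mu` and
`sigma` *exactly* and the Taylor estimator must return the designed
parameters to machine precision. Because a symmetric two-point fluctuation
needs `mu > sigma`, this mode lifts the mean ladder to [0.1, 0.5] and skips
compositional closure; it is a measurement of the estimator, not a
realistic community.

What the generator does *not* emulate: temporal autocorrelation (draws are
independent across time points), sequencing/count noise, taxonomic
nomenclature, and genuine ecological interactions between taxa. A green
test on synthetic data therefore establishes algorithmic correctness and
designed-signal recovery, not biological validity on real cohorts.

## Core microbiota

Per-taxon prevalence within a group is the fraction of that group's
*samples* (pooled; individuals with more samples weigh more — a documented
consequence of the per-sample reading) whose abundance exceeds the
detection limit. Cores at thresholds 1.0/0.8/0.5 are nested by
construction, and the three group cores at a common threshold are
partitioned into the seven membership regions (I-only, …, I∩A∩E), which are
pairwise disjoint and exhaustive — both properties are asserted on 50
random cohorts in the acceptance suite.

## Temporal similarity

Within-individual Jaccard similarity is computed for every unordered sample
pair of the same individual (never across individuals), indexed by the day
gap, and binned into half-open 60-day bins `[60k, 60(k+1))` whose
representative gap is the midpoint. The bin sd uses the n−1 denominator and
is reported missing for single-pair bins. Two empty presence sets are
defined as Jaccard 1 with a warning (identical emptiness), never silently
dropped.

The Jaccard core index (JCI) of a sample against a fixed reference core C
(the 50%-prevalence core of one age group) is
`|C ∩ S| / (|C| + |S| − |C ∩ S|)` with S the sample's presence set — i.e.
exactly the Jaccard similarity of the two sets, a property the tests verify
on 1,000 random set pairs. JCI trajectories use the subject's age *at
collection* (the alternative, age at enrollment, is not distinguishable in
the data model and was not chosen).

## Taylor stability

For each individual with at least 2 time points, each taxon detected at
least once contributes its temporal mean `mu` and sample sd `sigma`
(zeros included; never-detected taxa dropped; constant taxa excluded from
the regression with a logged count since `log 0` is undefined). The fit is
OLS of `log10 sigma` on `log10 mu`: the slope is `beta` and the intercept
`a` gives `V = 10^(2a)`, so `sigma^2 = V * mu^(2*beta)` and V is the
variance a hypothetical dominant taxon (`mu ~ 1`) would attain — the
natural instability amplitude. Regressing sd rather than variance keeps
`beta` on the ½–1 Poisson–exponential scale. Two-time-point fits are
accepted but flagged `low_confidence`.

Fits are standardized per axis to the Adult reference group — the amplitude
axis is `log10 V`, since V is multiplicative — so reference individuals
have mean 0 and sd 1; standard errors are scaled by the same reference sds.
The "healthy window" at level p is the circle of radius
`r = sqrt(-2 ln(1 - p))` (1.5096 at 68%, 2.7971 at 98%) that contains
probability p of a standard bivariate normal; the boundary counts as
inside. Classification is invariant to affine rescaling of the raw
parameters, which the tests assert.

### Why stochastic parameter recovery at 8 time points is biased

The acceptance suite demands that cohorts designed with `V = 0.3,
beta = 0.75` be recovered within a mean absolute slope error of 0.05 and a
median relative V error of 25%. The noiseless oracle meets the exact
(1e-6) criterion, but the stochastic criterion fails, and the failure is
structural, not a bug:

* For any n non-negative numbers, the sample sd is at most `sqrt(n)` times
  the sample mean. At n = 8 the observable moment pairs are confined to
  `log10(sigma_hat) <= log10(mu_hat) + log10(2.83)` — a hard slope-1
  barrier in exactly the plane the regression is fit in.
* The designed law at `V = 0.3` demands `sigma/mu = 0.55 * mu^(-1/4)`,
  which crosses that barrier at `mu ~ 1.3e-3` and runs within a factor ~2
  of it over most of a 60-taxon composition (closure forces a mean
  abundance of 1/60).
* Moment estimates from 8 draws of such high-CV laws are dominated by the
  largest draw, making the errors of `log mu_hat` and `log sigma_hat` large
  and almost perfectly correlated; squeezed against the barrier, the OLS
  slope is pulled toward 1 regardless of the generative distribution
  (gamma, lognormal, beta-distributed and mean-reverting variants were all
  measured at mean slope 0.90–0.98), and the V estimate — `10^(2 *
  intercept)` extrapolated to `mu = 1` — inherits the pivot several-fold.

The acceptance test states the criterion verbatim and reports the measured
values (mean |beta error| ≈ 0.37, median relative V error ≈ 12 under the
shipped generator); it is deliberately left failing rather than weakened,
and the criterion's tolerances should be read as applying to the noiseless
oracle and to low-CV regimes such as the Poisson count check (means 5–500,
where CV ≤ 0.45 and the recovered slope is 0.497 ± 0.03).

## Taxa-function robustness

A community's functional profile divides each taxon's abundance by its 16S
(rrn) copy number, renormalizes, projects through the taxa × gene-family
copy-number matrix, and renormalizes the function vector. Perturbations are
taxon knockouts: taxa are removed in uniformly random order until the
cumulative removed relative abundance first reaches the target magnitude
(final taxon may overshoot), survivors renormalized; the magnitude grid is
0.05–0.75 in steps of 0.05 with 20 replicates each. A knockout that would
empty the community (a dominant taxon drawn last) is redrawn — once inside
`perturb()` per its contract, up to 20 times at the curve level — and a
magnitude no removal order can satisfy is an error.

Each perturbation yields a taxonomic shift `d_T` and a functional shift
`d_F` (Bray–Curtis on the scope-restricted, renormalized profiles; a
perturbed community that lost a scope entirely scores `d_F = 1`; shifts
below 1e-12 are snapped to 0 as floating-point dust). The response is
summarized by the hinge model `d_F = s * max(0, d_T - b)`, fit by grid
search on the offset (step 0.005, ties toward the smaller offset) with the
closed-form non-negative slope: the offset realizes the perturbation size
tolerated before functional shifts appear, the slope the rate at which they
then grow.

Scores are standardized against a null that permutes whole genome rows
(with their rrn values) across taxa — preserving genome content and
community structure, randomizing only the taxa→function assignment — and
refits the hinge on the *same* perturbation events (d_T unchanged):
`attenuation = (mean s_null - s_obs) / sd s_null` (positive: functional
response flatter than random assignment) and `buffering = (b_obs - mean
b_null) / sd b_null` (positive: larger perturbations tolerated). A
degenerate null (sd 0, e.g. fully redundant genomes where every slope is 0)
flags the score undefined rather than producing an infinity. This hinge +
row-shuffle construction is a fully specified stand-in for
published robustness pipelines whose exact curve family and null are not
recoverable; the *sign conventions* are therefore declared, not inferred,
and per-sample scores land in roughly the −2 to +5 range on the default
synthetic cohort. Per-pathway and per-superpathway scores share one set of
perturbation events and one set of null permutations across scopes so they
are comparable within a sample.

## Group statistics

Two-group contrasts (JCI, attenuation, buffering) use the two-sided
Mann–Whitney/Wilcoxon rank-sum test: the exact tie-free null distribution
when both groups have at most 12 observations (folded two-sided p,
`min(1, 2*min(P(U<=u), P(U>=u)))`), otherwise the normal approximation with
tie correction and continuity correction; the switch is logged.
Benjamini–Hochberg step-up adjustment is available and off by default for
the JCI contrasts (the adjustment family there is a reporting choice, not a
stated one). The significance convention is p ≤ 0.05. The exact path is
verified against brute-force enumeration over all group assignments up to
7 + 7, and the null type-I error is calibrated empirically (0.044 at
α = 0.05 over 2,000 simulated pairs).

## Numerical and degenerate-input choices

* Detection threshold comparisons are strict (`>`); prevalence thresholds
  inclusive (`>=`).
* Jaccard of two empty sets is 1 with a warning.
* Hinge ties break toward the smaller offset; the slope is clamped at 0.
* All randomness flows from one master seed through named sub-streams
  (cohort, genome, perturb, null, per-sample robustness), so every stage is
  bit-reproducible and independently re-runnable.
* Serialized numbers use 10 significant digits; round trips are
  byte-stable.

## Known limitations

* The generator's independence across time points means Jaccard decay
  curves are flat in expectation beyond the presence/absence turnover the
  prevalence structure creates; real cohorts show gap-dependent decay.
* Robustness scores depend on the declared hinge/null construction;
  absolute values are not comparable to other robustness software, only
  contrasts within a run.
* Stochastic Taylor parameter recovery at few time points is biased toward
  slope 1 (see above); V and beta from 8-sample series should be read as
  comparative, not calibrated, estimates — which is also how the healthy
  window uses them (standardized to a reference group).
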