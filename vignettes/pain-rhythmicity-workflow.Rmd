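---
title: "Phenotyping pain rhythmicity and its molecular correlates: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping pain rhythmicity and its molecular correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Chronic low back pain (CLBP) is heterogeneous not only across patients but
within a patient's day. A 7-day ecological momentary assessment (EMA)
diary — three prompts per day at 08:00, 14:00 and 20:00, each answered on
the 11-point numeric rating scale (NRS, integers 0–10) — lets us ask
whether a patient's pain is flat, erratic, or *rhythmic*: systematically
higher in the evening than in the morning. `painrhythm` implements that
phenotyping and the analyses that hang off it: group comparisons of
biopsychosocial covariates, a multinomial logistic regression against the
rhythmic-increasing reference, and a blood-transcriptomic arm (paired
day/night sampling, differential expression, signed coexpression networks,
gene-set enrichment) plus a two-visit replication design built around an
opioid-use-by-time interaction.

Participant-level study data are not redistributable, so the package ships
a seeded synthetic-cohort generator with known ground truth. Every stage of
the pipeline therefore has a *recovery* test (planted signal found) and a
*calibration* test (null configuration gives uniform p-values) rather than
a fixture-comparison test.

# The phenotyping rules

For each participant, diary entries are assigned to the nearest scheduled
slot and retained only within ±60 minutes (`tolerance_min`, the
registered analysis window). Day 1 is the participant's first diary date;
exactly 7 scheduled days are considered.

1. **Variability split.** Each day with ≥2 of its 3 slots present
   contributes a within-day sample SD (denominator *n*−1; with 3
   observations per day the unbiased scale matters). The participant's
   variability metric is the unweighted mean of these daily SDs, and the
   cohort is split at its 50th percentile (linear interpolation): at or
   below the median → low variability. The phrase "daily pain-score SD"
   could also be read as one SD pooled over all 21 scores; both are
   implemented (`variability_method`), and mean-of-daily-SDs is the
   default because the whole construct — like the 12-hour change rule —
   concerns within-day structure.
2. **Constant split.** Low-variability participants are split at the
   median of their mean pain intensity, computed *within the
   low-variability subset* (the alternative, the whole-cohort median, is a
   one-line change): at or below → `constant_low`, above →
   `constant_high`.
3. **Rhythm rule.** A day *qualifies as increasing* when both anchor slots
   are present and (s20 − s08)/s08 ≥ 0.30; decreasing when the same ratio
   is ≤ −0.30. The threshold is inclusive (`inclusive = TRUE`) — the
   procedure's detailed description uses "≥30%" even where a summary says
   ">30%" — and both the threshold and the ≥4-day requirement are exposed
   (`rel_threshold`, `min_days`). A morning score of 0 with a positive
   evening score counts as increasing; 0 → 0 is no change. Days missing an
   anchor cannot qualify but stay in the 7-day denominator (a conservative
   reading of "≥4 of 7 days"). High-variability participants with ≥4
   increasing days are `rhythmic_up`, with ≥4 decreasing days
   `rhythmic_down`, otherwise `mixed`.
4. Ties at either median go to the *low* group; this makes the labels
   deterministic and independent of participant order. Participants with
   no SD-evaluable day are `unclassifiable`. Rhythmic-decreasing
   participants are flagged for downstream exclusion
   (`exclude_rhythmic_down`), mirroring the study cohort where only two
   such participants existed.

The same classifier runs unchanged on the mood and fatigue scales.

# The synthetic cohort

`cohort_config()` defines four archetypes plus the rare decreasing one,
with the study's group sizes (17/14/10/2/19) as the default mix. Within a
day the latent slot mean is

```
mu(slot) = baseline * (1 + slope * f(slot)) + day_shift + midday_excursion
```

where `f` is the fraction of the 08:00→20:00 interval elapsed. Growth is
*multiplicative* (evening = morning × (1 + slope)) because the rhythm rule
is relative; the rhythmic-increasing default slope of 1.0 doubles pain by
evening, comfortably above the 30% rule even after integer rounding.
Scores are Gaussian-noised, rounded half-away-from-zero (NRS is an integer
scale; round-half-even would bias the 0.5 ties), and clipped to 0–10.
Missingness is slot-wise independent Bernoulli — the simplest mechanism
that exercises the evaluable-day logic.

The mixed archetype needs high within-day variability *without* a
systematic morning-to-evening trend; pure slot noise cannot deliver that
(symmetric noise around a flat baseline sends roughly one mixed
participant in ten over the ≥4/7 increasing-day rule). It therefore gets a
per-day midday excursion with random sign (`midday_excursion_sd`, default
3 NRS units): large 14:00 departures with matching 08:00/20:00 anchors,
i.e. unpredictable days rather than trending ones. Mood and fatigue are
noisy monotone functions of the latent pain signal plus a
participant-level disposition, putting the cross-scale rank correlations
of participant means near the moderate 0.5–0.7 range reported for such
cohorts.

The Gaussian-then-round noise model is a stand-in, not an inference about
real diaries: real EMA noise is likely skewed, serially correlated and
missing-not-at-random. Passing recovery tests therefore show that the
*rules are implemented correctly and are recoverable under their own
assumptions*, not that real cohorts would classify this cleanly.

Counts are negative binomial with Var = μ + αμ² (matching the downstream
model, so recovery tests are self-consistent), a log-normal relative
abundance profile, per-sample library sizes, gene-specific multiplicative
batch/sex/night effects, and one planted module whose genes share a latent
factor; the factor's participant-level score is shifted down by
`module_effect` in rhythmic-increasing participants, so the planted
eigengene is negatively associated with that phenotype. No isoform
structure, no count outliers, no correlated gene–gene noise beyond the
planted module: real RNA-seq is messier in all three ways.

# Statistical components

**Multinomial regression.** `fit_multinomial_or()` fits a maximum-
likelihood multinomial logit (reference: rhythmic-increasing) and reports
OR = e^β with Wald 95% CIs e^(β ± 1.96·se). Quasi-complete separation —
e.g. a medication used by nobody in the reference group — is detected two
ways: a refit at a larger iteration budget whose coefficients keep
growing, and a zero cell in the cross-tab of any binary design column with
(level vs reference), which makes the MLE infinite regardless of where the
optimizer stalls. Flagged ORs are reported as the bounded sentinel
e^(±15), with the flag; no penalized correction is applied by default
because the uncorrected behavior is itself informative (the analysis
deliberately mirrors it). Firth-style fixes can be layered on by the user.

**Exact contingency tests.** `fisher_exact()` uses the exact
Freeman–Halton rule for r×c tables within an enumeration budget (total ≤
500 or both dimensions ≤ 5) and a seeded Monte-Carlo p-value beyond it.
The test suite checks the exact path against a from-scratch enumeration of
all margin-preserving tables.

**Normalization.** `tmm_factors()` returns both the TMM composition
factor and the *effective relative library scaling* (library size ×
factor, geometric mean 1); downstream transforms divide by the effective
library size. `log_cpm()` is exactly log2((count + 0.5)/eff_lib · 1e6) — a
monotone variance-flattening working scale for filtering and networks. It
is not a variance-stabilizing transform in the model-based sense; that is
a documented, deliberate simplification.

**Nonspecific filtering** ranks transcripts by MAD of the transformed
values (the scale is configurable; MAD on raw counts is dominated by
abundance) and keeps the top 30%, ties broken by transcript id so the
retained set is deterministic.

**Outlier triage** scores each sample by (a) its summed mean-absolute
distance to the other samples, (b) the Kolmogorov–Smirnov statistic of its
value distribution against the pooled rest, and (c) Hoeffding's D between
its MA-coordinates against a row-median pseudo-reference. A sample is
removed if flagged before *and* after normalization, or by ≥2 metrics
after. The flagging fence is Q3 + 3·IQR: with three correlated metrics and
the 2-of-3 clause, the ordinary 1.5 fence removes samples from roughly a
third of perfectly homogeneous simulated cohorts, while the far-out fence
removes essentially none and still exceeds a grossly shifted sample's
score several-fold.

**Batch adjustment** is a light median log-ratio centering (per gene, each
batch's median is moved onto the grand median on the log2(count + 0.5)
scale, then re-rounded). It removes multiplicative batch shifts — which is
all the network stage needs, and the differential-expression models carry
batch as a covariate anyway — but it is *not* an empirical-Bayes
location/scale adjustment; dispersion differences between batches survive
it.

**Differential expression** goes through edgeR: TMM offsets, per-gene
dispersion with trended/common shrinkage, GLM fits and likelihood-ratio
tests, Bonferroni control (`adjust = "BH"` available). Candidate gene-set
DE corrects over the candidate subset only. The replication arm's
`interaction_de()` fits the two-visit design
`~ age + sex + RIN + smoker + resolved + time + opioids + time:opioids`
with DESeq2 and ranks genes by the interaction's signed Wald statistic —
positive means expression lingered or rose with time in opioid users.
Wald (not LRT) is the ranking default because a signed statistic is what
the enrichment stage consumes. The chronicity odds ratio uses exactly
OR = e^β, CI = e^(β ± 1.96·sem) from a logistic fit adjusted for sex, age
and smoking.

# The coexpression stack

Networks are *signed*: a_ij = ((1 + cor_ij)/2)^β, so anticorrelated
transcripts get adjacency near 0. The soft threshold β is the smallest
power whose connectivity distribution fits a scale-free form with signed
R² ≥ 0.80 (log-log regression over 10 connectivity bins, sign taken from
the slope), argmax otherwise. Topological overlap is
TOM_ij = (l_ij + a_ij)/(min(k_i, k_j) + 1 − a_ij) with shared-neighbor
sums l and connectivities k; 1 − TOM feeds average-linkage clustering.

Tree cutting is a simplified adaptive procedure, not a port of the
dynamic hybrid algorithm (whose many tuning constants are not published):
candidate cut heights (midpoints between merge heights) are scored by how
many clusters of at least `min_size` they produce, the highest such cut
wins, undersized clusters become grey, and a retained cluster must also be
internally tighter than both the cut height and 95% of the cohort-wide
mean dissimilarity (core scatter) — the latter guard keeps the whole tree
from masquerading as one module. A static cut at the 0.99 height quantile
is available as a fallback.

Module eigengenes are first principal components of the standardized
member profiles (unit norm, sign-anchored to the module mean profile).
Merging is iterative: while any two eigengenes correlate at |r| ≥ 0.30,
merge the most correlated pair and recompute. The 0.30 threshold is the
study's own — far more aggressive than the common 0.75 convention — and is
implemented as quoted, with the threshold and the |r|-vs-signed-r choice
both configurable. Module–trait association fits a logistic GLM of
(phenotype == rhythmic-increasing) on each eigengene, or a multinomial GLM
with that reference for the multilevel version. Day and night networks are
built from their own sample sets with no shared state.

# Enrichment

Over-representation uses the hypergeometric upper tail with term-size
filters (10–500 after intersection with the background) and
Benjamini–Hochberg adjustment. The g:SCS correction of the original
pathway tool depends on the live GO graph and is not reproduced; this is a
documented divergence. Ranked-list enrichment is the classic running sum:
hit increments ∝ |stat|^weight (weight 1 by default), uniform miss
decrements, ES = the extremum (earliest position wins on |ES| ties, to
1e-10). The permutation null permutes gene labels: when C(n, k) placements
fit the permutation budget they are enumerated *exactly* (small-case
p-values then equal brute-force enumeration); otherwise seeded Monte-Carlo
with p = (1 + #extreme)/(n_perm + 1), one-sided in the observed sign.
The leading edge is the hit genes at or before (after, for negative ES)
the extremum.

# Numerical conventions and degenerate inputs

- All generators take a mandatory seed; the pipeline derives per-stage
  seeds from one global seed through named substreams (`stage_seed`), so
  stages rerun independently and reproducibly.
- Medians/percentiles use linear interpolation; median ties classify low.
- NRS rounding is half-away-from-zero; counts re-rounded after batch
  centering are clipped at 0.
- Constant inputs are flagged, not silently propagated: constant
  transcripts fail `signed_adjacency`, constant eigengenes are flagged in
  `module_trait`, zero rank variance is flagged in `spearman_cor`, and a
  day value of 0 is an error for percent change.
- All-zero transcripts are dropped (and reported) before GLM fitting;
  non-full-rank designs error with the offending columns named.

# Problem sizes

The packaged analyses and checks run at deliberately scaled sizes chosen
to exercise every code path on a single CPU in minutes: 62–160
participants per diary cohort, 1,500–2,000 transcripts (≈450–600 after the
30% MAD filter) for the expression arm, 60–120 samples per network, and a
97-participant two-visit replication cohort at 1,000 genes. The stages are
size-agnostic; nothing in the implementation assumes these dimensions.

# Known limitations

- The diary noise model is a stand-in (see above); classifier recovery
  rates on synthetic cohorts are upper bounds for real data.
- The batch adjustment and the log-CPM transform are simplified stand-ins
  for empirical-Bayes batch correction and variance-stabilizing
  transforms, respectively.
- The tree cut is a simplified adaptive procedure; on real-scale data the
  module count will differ from the original tooling's.
- g:SCS multiplicity correction and fgsea's multilevel p refinement are
  not reproduced; BH/Bonferroni and plain permutation p-values are used.
- The replication generator plants a clean interaction in one set;
  correlated gene sets and confounded designs are not simulated.
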