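# painrhythm

Phenotyping of chronic low back pain (CLBP) by within-day pain
rhythmicity, with the downstream biopsychosocial and blood-transcriptomic
analyses that such a phenotyping enables. The package is aimed at pain
researchers and biostatisticians who want to (a) classify 7-day,
3-prompts-per-day ecological momentary assessment (EMA) diaries into
interpretable rhythmicity phenotypes and (b) carry those phenotypes
through group statistics, RNA-seq differential expression, coexpression
networks, and gene-set enrichment — all runnable offline against a seeded
synthetic cohort with known ground truth.

## The classification at the core

Participants answer a 0–10 numeric rating scale (NRS) at 08:00, 14:00 and
20:00 for 7 days; entries within ±1 h of a prompt are kept. With s08 and
s20 the anchor scores of a day:

- **variability split** — each day with ≥2 slots contributes a within-day
  sample SD; participants at or below the cohort median of the mean daily
  SD are *low variability*;
- **constant-low / constant-high** — the low-variability group is split at
  the median of mean pain intensity;
- **rhythmic↑ / rhythmic↓** — a high-variability participant is rhythmic
  increasing if (s20 − s08)/s08 ≥ 0.30 on ≥4 of the 7 scheduled days
  (decreasing: ≤ −0.30), and **mixed** otherwise.

Downstream, group contrasts are expressed as multinomial logistic
regression odds ratios OR = e^β with 95% CI e^(β ± 1.96·se) against the
rhythmic-increasing reference (with explicit detection of quasi-complete
separation, e.g. zero opioid users in the reference group); categorical
tables use exact Freeman–Halton tests; the transcriptomic arm uses TMM
normalization, a top-30% MAD filter, negative-binomial GLMs with
Bonferroni control, signed coexpression networks
(a_ij = ((1 + cor_ij)/2)^β, topological overlap, eigengene merging at
|r| ≥ 0.30) and running-sum gene-set enrichment with a gene-permutation
null. The methods vignette
(`vignettes/pain-rhythmicity-workflow.Rmd`) documents every rule,
parameter and design choice.

## Worked example

```r
library(painrhythm)

# a study-sized synthetic diary cohort (17/14/10/2/19 archetype mix)
cfg    <- cohort_config(seed = 2019)
sim    <- gen_diaries(cfg)
labels <- phenotype_cohort(sim$diary, scale = "pain")
table(labels$label)
#> constant_high  constant_low         mixed rhythmic_down   rhythmic_up
#>            15            16            20             1            10

# the antidepressant-use table reconstructed from published counts
fisher_exact(antidepressant_table())$p
#> [1] 0.01602901

# covariates linked to phenotype; opioid use is absent in the rhythmic
# group, which quasi-separates the regression and is flagged
cov <- gen_covariates(sim$truth, covariate_config(seed = 2020))
d   <- merge(labels, cov[, setdiff(names(cov), "phenotype")],
             by = "participant_id")
d$phenotype <- d$label
d   <- d[!d$excluded, ]
ors <- fit_multinomial_or(d, c("age", "promis_depression", "opioid_use"))
subset(ors, term == "opioid_use")
#>           level       term beta    se     or  ci_lo  ci_hi         p separation
#> 3 constant_high opioid_use 12.8 0.443 353785 148458 843092 7.34e-183       TRUE
#> 6  constant_low opioid_use 12.4 0.425 242112 105273 556823 4.01e-187       TRUE
#> 9         mixed opioid_use 11.7 0.435 117759  50229 276082 6.55e-159       TRUE
```

The `table()` call shows the recovered phenotype mix (ground truth is in
`sim$truth`); the exact test reproduces the published p = 0.016 for
antidepressant use across the four phenotypes; and the opioid contrast
illustrates the separation behavior — every OR is reported as a bounded
sentinel with `separation = TRUE` because no rhythmic-increasing
participant uses opioids.

## The analysis workflow

Numbered drivers under `analysis/` run the full study sequence and write
their tables under `results/` (each regenerates its inputs from seeded
generators, so they can be run independently, in order):

| script | what it does |
|---|---|
| `01_simulate_cohort.R` | synthesize diaries, covariates, paired day/night counts, replication cohort |
| `02_phenotype_diaries.R` | classify the cohort; compare to ground truth; mood/fatigue reuse |
| `03_cohort_statistics.R` | multinomial ORs, Fisher exact tests, Kruskal–Wallis, percent change, 2^−ΔΔCt |
| `04_preprocess_expression.R` | TMM, log-CPM, MAD filter, outlier triage, batch centering |
| `05_differential_expression.R` | NB-GLM contrasts vs the rhythmic group, candidate-set DE |
| `06_coexpression_network.R` | day/night signed networks, modules, module–trait GLMs |
| `07_replication.R` | chronicity OR, opioid×time interaction, ranked-list enrichment |

`run_pipeline()` orchestrates the same stages from one YAML config (see
`inst/extdata/demo_config.yaml` for a minute-scale demonstration run).

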