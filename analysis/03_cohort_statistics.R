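# Biopsychosocial group statistics: multinomial logistic regression odds
# ratios against the rhythmic-increasing reference, exact contingency
# tests (including the published antidepressant table), rank tests, and
# the qPCR fold-change helper.

source("analysis/00_settings.R")

sim <- gen_diaries(diary_config())
labels <- phenotype_cohort(sim$diary)
cov <- gen_covariates(sim$truth, covar_config())

d <- merge(labels[, c("participant_id", "label", "excluded")],
           cov[, setdiff(names(cov), "phenotype")], by = "participant_id")
d <- d[!d$excluded & d$label != "unclassifiable", ]
d$phenotype <- d$label

ors <- fit_multinomial_or(
  d, covariates = c("age", "sex", "promis_depression",
                    "promis_sleep_disturbance", "promis_pain_interference",
                    "promis_physical_function", "pcs6", "n_pain_meds",
                    "opioid_use"))
write_tsv(ors, "03_or_table.tsv")
sep <- ors[ors$term == "opioid_use", ]
message("opioid-use contrasts flagged for separation: ",
        sum(sep$separation), " of ", nrow(sep),
        " (no opioid users in the reference group)")

# exact tests on medication-use tables
opioid_tab <- table(d$phenotype, d$opioid_use)
message(sprintf("opioid-use Fisher exact p = %.4f",
                fisher_exact(opioid_tab)$p))
antidep_tab <- table(d$phenotype, d$antidepressant_use)
message(sprintf("antidepressant-use Fisher exact p = %.4f (synthetic)",
                fisher_exact(antidep_tab)$p))

# the table reconstructed from the published counts/percentages
pub <- antidepressant_table()
message(sprintf("published antidepressant table: p = %.3f; constant-low %%
  = %.1f", fisher_exact(pub)$p, 100 * pub["constant_low", "yes"] /
                  sum(pub["constant_low", ])))

# continuous covariates across phenotypes
for (v in c("age", "promis_depression", "pcs6")) {
  k <- group_compare(d[[v]], d$phenotype, mode = "kruskal")
  message(sprintf("Kruskal-Wallis %-18s H = %5.2f, p = %.3f", v,
                  k$statistic, k$p))
}

# worked percent-change and ddCt examples (day/night blood measures)
message(sprintf("pct_change(4.0, 5.0) = %+.1f%%", pct_change(4, 5)))
message(sprintf("2^-ddCt fold change for ddCt = -2: %.1f",
                ddct_fold_change(3, 5, 5, 5)))
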