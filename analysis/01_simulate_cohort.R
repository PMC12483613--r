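# Synthesize the study cohorts: 7-day EMA diaries for the archetype mix,
# phenotype-linked covariates, paired day/night transcript counts with a
# planted coexpression module, and the two-visit replication dataset.

source("analysis/00_settings.R")

sim <- gen_diaries(diary_config())
message(sprintf("diaries: %d entries from %d participants (%d scales)",
                nrow(sim$diary), nrow(sim$truth),
                length(unique(sim$diary$scale))))
write_tsv(sim$truth, "01_ground_truth.tsv")

cov <- gen_covariates(sim$truth, covar_config())
message(sprintf("covariates: opioid use %.0f%% overall, %.0f%% in the
  rhythmic-increasing archetype",
                100 * mean(cov$opioid_use),
                100 * mean(cov$opioid_use[cov$phenotype == "rhythmic_up"])))
write_tsv(cov, "01_covariates.tsv")

expr <- gen_counts(sim$truth, expr_config())
message(sprintf("counts: %d transcripts x %d samples per time point; %d
  planted module genes", nrow(expr$counts_day), ncol(expr$counts_day),
                length(expr$truth$module_genes)))

repl <- gen_replication(repl_config())
message(sprintf("replication: %d participants x 2 visits, %d genes, %d
  gene sets", nrow(repl$design) / 2, nrow(repl$counts),
                length(repl$gene_sets)))
message("synthesis is seed-reproducible; downstream scripts regenerate it")
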