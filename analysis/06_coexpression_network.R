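# Signed coexpression networks built independently for the day and night
# samples: soft-threshold pick, TOM clustering, eigengenes, merging at the
# 0.30 correlation threshold, and module-phenotype association.

source("analysis/00_settings.R")

sim <- gen_diaries(diary_config())
labels <- phenotype_cohort(sim$diary)
expr <- gen_counts(sim$truth, expr_config())
lab <- setNames(labels$label, labels$participant_id)

analyse <- function(counts, samples, tag) {
  lc <- log_cpm(counts, tmm_factors(counts))
  filt <- mad_filter(lc, keep_fraction = 0.30)
  adj <- batch_adjust(counts[rownames(filt), ], samples$batch)
  x <- log_cpm(adj, tmm_factors(adj))
  nw <- build_network(x, min_size = 15, merge_threshold = 0.30)
  n_mod <- length(setdiff(unique(nw$labels), "grey"))
  message(sprintf("[%s] power = %d, %d modules (plus grey, %d transcripts)",
                  tag, nw$power, n_mod, sum(nw$labels == "grey")))
  pl <- nw$labels[intersect(expr$truth$module_genes, names(nw$labels))]
  pl <- pl[pl != "grey"]
  message(sprintf("[%s] planted-module capture: %.0f%% in '%s'", tag,
                  100 * max(table(pl)) / length(expr$truth$module_genes),
                  names(which.max(table(pl)))))
  ph <- unname(lab[samples$participant_id])
  keep <- ph %in% c("rhythmic_up", "constant_low", "constant_high",
                    "mixed")
  mt <- module_trait(nw$eigengenes[keep, , drop = FALSE], ph[keep],
                     mode = "binary")
  write_tsv(mt, sprintf("06_module_trait_%s.tsv", tag))
  sig <- mt[!mt$degenerate & mt$p < 0.05, ]
  for (i in seq_len(nrow(sig))) {
    message(sprintf("[%s] module %s: beta = %+.2f, p = %.4f (%s with the
  rhythmic-increasing phenotype)", tag, sig$module[i], sig$beta[i],
                    sig$p[i],
                    ifelse(sig$beta[i] < 0, "negatively associated",
                           "positively associated")))
  }
  invisible(nw)
}

analyse(expr$counts_day, expr$samples[expr$samples$time == "day", ], "day")
analyse(expr$counts_night, expr$samples[expr$samples$time == "night", ],
        "night")
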