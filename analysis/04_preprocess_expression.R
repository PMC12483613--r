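# Count-matrix triage: TMM factors, log-CPM, top-30% MAD filter, the
# three-metric outlier rule, and batch centering — day and night matrices
# handled separately.

source("analysis/00_settings.R")

sim <- gen_diaries(diary_config())
expr <- gen_counts(sim$truth, expr_config())

prep <- function(counts, samples, tag) {
  fac <- tmm_factors(counts)
  write_tsv(fac, sprintf("04_tmm_factors_%s.tsv", tag))
  lc <- log_cpm(counts, fac)
  out <- outlier_flag(log2(counts + 0.5), lc)
  message(sprintf("[%s] outliers removed: %d of %d", tag,
                  sum(out$verdict), nrow(out)))
  filt <- mad_filter(lc, keep_fraction = 0.30)
  message(sprintf("[%s] MAD filter kept %d of %d transcripts", tag,
                  nrow(filt), nrow(lc)))
  adj <- batch_adjust(counts[rownames(filt), ], samples$batch)
  lr <- vapply(rownames(adj)[1:100], function(g) {
    la <- log2(adj[g, ] + 0.5)
    abs(median(la[samples$batch == "b2"]) -
          median(la[samples$batch == "b1"]))
  }, numeric(1))
  message(sprintf("[%s] post-adjustment |batch log-ratio| median: %.3f",
                  tag, median(lr)))
  log_cpm(adj, tmm_factors(adj))
}

day_samples <- expr$samples[expr$samples$time == "day", ]
night_samples <- expr$samples[expr$samples$time == "night", ]
lc_day <- prep(expr$counts_day, day_samples, "day")
lc_night <- prep(expr$counts_night, night_samples, "night")
message("transformed matrices ready: ", nrow(lc_day), " transcripts x ",
        ncol(lc_day), " samples per time point")
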