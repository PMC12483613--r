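# Two-visit replication cohort: chronicity odds ratio for opioid use, the
# opioid-by-time interaction model per gene, and ranked-list enrichment of
# the designated degranulation-style gene set.

source("analysis/00_settings.R")

repl <- gen_replication(repl_config())

des <- repl$design[repl$design$visit == "baseline", ]
des$chronic <- !des$resolved
or <- logistic_or(des, outcome = "chronic", exposure = "opioids",
                  covariates = c("sex", "age", "smoker"))
message(sprintf("chronicity OR for opioid use: %.2f (95%% CI %.2f-%.2f),
  p = %.3g", or$or, or$ci_lo, or$ci_hi, or$p))

ide <- interaction_de(repl$counts, repl$design)
write_tsv(ide$table[order(-abs(ide$table$stat)), ][1:50, ],
          "07_interaction_top50.tsv")
n_pos <- sum(ide$table$stat > 0 &
               ide$table$gene %in% repl$truth$target_set)
message(sprintf("planted set: %d of %d genes with a positive interaction
  (expression lingers/rises with time in opioid users)", n_pos,
                length(repl$truth$target_set)))

gs <- gsea(ide$ranked, repl$gene_sets, n_perm = 2000,
           seed = stage_seed(SEED, "gsea"))
write_tsv(gs[order(gs$p), setdiff(names(gs), "leading_edge")],
          "07_gsea.tsv")
target <- gs[gs$set == "DEGRANULATION_SYNTH", ]
message(sprintf("designated set enrichment: ES = %+.2f, p = %.2g
  (leading edge %d genes)", target$es, target$p,
                length(strsplit(target$leading_edge, ";")[[1]])))
top3 <- strsplit(target$leading_edge, ";")[[1]][1:3]
message("top-ranking leading-edge genes: ", paste(top3, collapse = ", "))
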