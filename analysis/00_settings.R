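# Shared settings for the analysis scripts. Every script regenerates the
# data it needs from these seeded configurations (generation is cheap and
# byte-reproducible), so no large intermediates are stored in the
# repository.

library(painrhythm)

SEED <- 20190107L          # cohort recruitment started the week of 2019-01-07
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

# Main cohort: study-sized archetype mix (17/14/10/2/19).
diary_config <- function() cohort_config(seed = stage_seed(SEED, "diaries"))

covar_config <- function() covariate_config(seed = stage_seed(SEED, "covar"))

# Paired day/night counts with one planted module tied to the rhythmic
# phenotype. 1,500 transcripts keeps the network stage minutes-fast while
# leaving ~450 transcripts after the 30% MAD filter.
expr_config <- function() counts_config(
  seed = stage_seed(SEED, "counts"), n_transcripts = 1500,
  planted_module_size = 50, module_effect = 1.2)

# Two-visit replication cohort with the planted opioid-by-time set.
repl_config <- function() replication_config(
  seed = stage_seed(SEED, "replication"), n_users = 45, n_nonusers = 52,
  n_genes = 1000, set_size = 50, interaction_lfc = 0.8, n_decoy_sets = 10)

write_tsv <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
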