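# Generators: seeded determinism, noiseless limits, validation, and the
# null/shift behavior of the covariate generator.

test_that("diary generation is seeded-deterministic and NRS-valid", {
  cfg <- cohort_config(seed = 101, n_per_phenotype = c(
    constant_low = 3, rhythmic_up = 3, mixed = 3))
  a <- gen_diaries(cfg)
  b <- gen_diaries(cfg)
  expect_identical(a, b)
  expect_true(all(a$diary$score %in% 0:10))
  expect_true(all(a$diary$scale %in% c("pain", "mood", "fatigue")))
  expect_setequal(unique(a$truth$phenotype),
                  c("constant_low", "rhythmic_up", "mixed"))
})

test_that("noiseless constant archetype emits exactly the baseline", {
  cfg <- cohort_config(seed = 5, n_per_phenotype = c(constant_low = 2),
                       missing_rate = 0)
  cfg$archetypes$constant_low$baseline_mean <- 3
  cfg$archetypes$constant_low$day_noise_sd <- 0
  cfg$archetypes$constant_low$within_day_noise_sd <- 0
  sim <- gen_diaries(cfg)
  pain <- sim$diary[sim$diary$scale == "pain", ]
  expect_true(all(pain$score == 3))
  expect_equal(nrow(pain), 2 * 7 * 3)
})

test_that("invalid cohort config errors name the offending field", {
  cfg <- cohort_config(seed = 1)
  cfg$missing_rate <- 1.5
  expect_error(gen_diaries(cfg), "missing_rate")
  cfg2 <- cohort_config(seed = 1)
  cfg2$archetypes$mixed$within_day_noise_sd <- -1
  expect_error(gen_diaries(cfg2), "within_day_noise_sd")
})

test_that("covariates: rhythmic group never uses opioids; null t-scores", {
  truth <- data.frame(
    participant_id = sprintf("P%03d", 1:300),
    phenotype = rep(c("rhythmic_up", "mixed", "constant_low"), each = 100))
  vc <- covariate_config(seed = 7, promis_shifts = list(),
                         pcs6_shifts = c())
  cov <- gen_covariates(truth, vc)
  expect_false(any(cov$opioid_use[cov$phenotype == "rhythmic_up"]))
  expect_true(any(cov$opioid_use[cov$phenotype != "rhythmic_up"]))
  # zero-shift configuration: pooled t-score mean near 50
  n <- nrow(cov)
  expect_lt(abs(mean(cov$promis_depression) - 50), 3 * 10 / sqrt(n))
})

test_that("configured depression shift is recovered from group means", {
  truth <- data.frame(
    participant_id = sprintf("P%03d", 1:400),
    phenotype = rep(c("constant_high", "mixed"), each = 200))
  vc <- covariate_config(
    seed = 11, promis_shifts = list(constant_high = c(depression = 8)),
    pcs6_shifts = c())
  cov <- gen_covariates(truth, vc)
  diff <- mean(cov$promis_depression[cov$phenotype == "constant_high"]) -
    mean(cov$promis_depression[cov$phenotype == "mixed"])
  se <- 10 * sqrt(2 / 200)
  expect_lt(abs(diff - 8), 2 * se)
})

test_that("count generation is deterministic and validates module size", {
  truth <- data.frame(participant_id = sprintf("P%03d", 1:6),
                      phenotype = rep(c("rhythmic_up", "mixed"), 3))
  kc <- counts_config(seed = 3, n_transcripts = 50,
                      planted_module_size = 10)
  a <- gen_counts(truth, kc)
  b <- gen_counts(truth, kc)
  expect_identical(a$counts_day, b$counts_day)
  expect_identical(a$counts_night, b$counts_night)
  expect_true(all(a$counts_day >= 0))
  expect_true(all(a$counts_day == floor(a$counts_day)))
  expect_error(counts_config(seed = 1, n_transcripts = 5,
                             planted_module_size = 10),
               "planted_module_size")
})

test_that("null counts give calibrated planted-eigengene association", {
  # module_effect = 0, no batch effect: the logistic GLM p of phenotype on
  # the planted-gene eigengene should be uniform across simulations
  reps <- 200
  pvals <- numeric(reps)
  for (i in seq_len(reps)) {
    truth <- data.frame(participant_id = sprintf("P%02d", 1:30),
                        phenotype = rep(c("rhythmic_up", "mixed"),
                                        each = 15))
    kc <- counts_config(seed = 5000 + i, n_transcripts = 60,
                        planted_module_size = 15, module_effect = 0,
                        batch_effect_sd = 0)
    sim <- gen_counts(truth, kc)
    lc <- log_cpm(sim$counts_day, tmm_factors(sim$counts_day))
    eg <- eigengenes(lc, ifelse(rownames(lc) %in% sim$truth$module_genes,
                                "M1", "grey"))
    samp <- sim$samples[sim$samples$time == "day", ]
    mt <- module_trait(eg$eigengenes, samp$phenotype, mode = "binary")
    pvals[i] <- mt$p[1]
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("replication generator is deterministic and validates sizes", {
  rc <- replication_config(seed = 13, n_users = 5, n_nonusers = 5,
                           n_genes = 40, set_size = 8, n_decoy_sets = 2)
  a <- gen_replication(rc)
  b <- gen_replication(rc)
  expect_identical(a$design, b$design)
  expect_identical(a$counts, b$counts)
  expect_equal(nrow(a$design), 2 * 10)
  expect_error(replication_config(seed = 1, n_users = 2, n_nonusers = 2),
               "covariate")
  expect_error(replication_config(seed = 1, set_size = 50, n_genes = 10),
               "set_size")
})

test_that("replication chronicity odds ratio is recovered at inflated n", {
  hits <- 0; reps <- 50
  for (i in seq_len(reps)) {
    rc <- replication_config(seed = 2000 + i, n_users = 200,
                             n_nonusers = 200, n_genes = 5, set_size = 2,
                             n_decoy_sets = 0)
    sim <- gen_replication(rc)
    des <- sim$design[sim$design$visit == "baseline", ]
    des$chronic <- !des$resolved
    r <- logistic_or(des, "chronic", "opioids", c("sex", "age", "smoker"))
    hits <- hits + (abs(r$beta - log(2.6)) <= 2 * r$se)
  }
  expect_gte(hits / reps, 0.9)
})
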