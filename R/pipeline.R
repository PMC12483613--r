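# End-to-end orchestration: synthesize -> phenotype -> cohort statistics ->
# expression preprocessing -> differential expression -> coexpression
# networks -> replication, from one configuration with a global seed and a
# machine-readable run report.

#' Default pipeline configuration
#'
#' Every stage draws its seed from the global seed via a named substream
#' ([stage_seed()]), so stages can be rerun independently and the whole run
#' is reproducible from `seed` alone. Stage toggles must be
#' dependency-closed: a stage cannot run if a stage it needs is off.
#'
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed).
#' @param stages named logical vector of stage toggles.
#' @param cohort,covariates,counts,replication,network per-stage parameter
#'   overrides (lists merged over the defaults).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, out_dir = tempfile("painrhythm_run_"),
                       stages = c(simulate = TRUE, phenotype = TRUE,
                                  cohort_stats = TRUE, preprocess = TRUE,
                                  de = TRUE, network = TRUE,
                                  replication = TRUE),
                       cohort = list(), covariates = list(),
                       counts = list(), replication = list(),
                       network = list()) {
  check_number(seed, "seed", integer = TRUE)
  structure(list(seed = seed, out_dir = out_dir, stages = stages,
                 cohort = cohort, covariates = covariates, counts = counts,
                 replication = replication, network = network),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with at least a `seed` field.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed", call. = FALSE)
  stages <- run_config(1)$stages
  if (!is.null(y$stages)) {
    for (nm in names(y$stages)) stages[[nm]] <- isTRUE(y$stages[[nm]])
  }
  run_config(seed = y$seed,
             out_dir = if (is.null(y$out_dir))
               tempfile("painrhythm_run_") else y$out_dir,
             stages = stages,
             cohort = if (is.null(y$cohort)) list() else y$cohort,
             covariates = if (is.null(y$covariates)) list() else
               y$covariates,
             counts = if (is.null(y$counts)) list() else y$counts,
             replication = if (is.null(y$replication)) list() else
               y$replication,
             network = if (is.null(y$network)) list() else y$network)
}

stage_deps <- function() {
  list(simulate = character(0),
       phenotype = "simulate",
       cohort_stats = c("simulate", "phenotype"),
       preprocess = c("simulate", "phenotype"),
       de = "preprocess",
       network = "preprocess",
       replication = "simulate")
}

merge_args <- function(defaults, overrides) {
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

#' Run the pipeline
#'
#' Stages run in dependency order; a stage failure halts its dependents
#' with a clear message while independent stages still run. All outputs are
#' written under the configured run directory, and a JSON run report echoes
#' every effective parameter, per-stage status and wall-clock seconds.
#'
#' @param config a `run_config` or the path to a YAML config file.
#' @return the run report (list), invisibly written to
#'   `run_report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  deps <- stage_deps()
  on <- names(config$stages)[unlist(config$stages)]
  for (st in on) {
    off_deps <- setdiff(deps[[st]], on)
    if (length(off_deps)) {
      stop("stage '", st, "' is enabled but depends on disabled stage(s): ",
           paste(off_deps, collapse = ", "), call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env(parent = emptyenv())
  report <- list(seed = config$seed, out_dir = config$out_dir,
                 stages = list())
  failed <- character(0)

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    blocked <- intersect(deps[[name]], failed)
    if (length(blocked)) {
      report$stages[[name]] <<- list(
        status = "blocked",
        message = paste("upstream stage failed:",
                        paste(blocked, collapse = ", ")))
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      outputs <- fun()
      list(status = "ok", outputs = outputs)
    }, error = function(e) list(status = "failed",
                                message = conditionMessage(e)))
    res$seconds <- round(proc.time()[["elapsed"]] - t0, 2)
    report$stages[[name]] <<- res
    if (res$status == "failed") failed <<- c(failed, name)
    invisible(NULL)
  }

  run_stage("simulate", function() {
    cc <- do.call(cohort_config, merge_args(
      list(seed = stage_seed(config$seed, "simulate")), config$cohort))
    sim <- gen_diaries(cc)
    state$diary <- sim$diary; state$truth <- sim$truth
    vc <- do.call(covariate_config, merge_args(
      list(seed = stage_seed(config$seed, "covariates")),
      config$covariates))
    state$covariates <- gen_covariates(sim$truth, vc)
    kc <- do.call(counts_config, merge_args(
      list(seed = stage_seed(config$seed, "counts")), config$counts))
    state$expr <- gen_counts(sim$truth, kc)
    rc <- do.call(replication_config, merge_args(
      list(seed = stage_seed(config$seed, "replication")),
      config$replication))
    state$repl <- gen_replication(rc)
    paths <- file.path(config$out_dir,
                       c("diary.csv", "truth.csv", "covariates.csv"))
    utils::write.csv(sim$diary, paths[1], row.names = FALSE)
    utils::write.csv(sim$truth, paths[2], row.names = FALSE)
    utils::write.csv(state$covariates, paths[3], row.names = FALSE)
    write_gmt(state$repl$gene_sets,
              file.path(config$out_dir, "replication_sets.gmt"))
    c(paths, file.path(config$out_dir, "replication_sets.gmt"))
  })

  run_stage("phenotype", function() {
    state$labels <- phenotype_cohort(state$diary, scale = "pain")
    path <- file.path(config$out_dir, "phenotypes.csv")
    utils::write.csv(state$labels, path, row.names = FALSE)
    path
  })

  run_stage("cohort_stats", function() {
    cov <- merge(state$labels[, c("participant_id", "label", "excluded")],
                 state$covariates[, setdiff(names(state$covariates),
                                            "phenotype")],
                 by = "participant_id")
    cov <- cov[!cov$excluded & cov$label != "unclassifiable", ]
    cov$phenotype <- cov$label
    ors <- fit_multinomial_or(
      cov, c("age", "sex", "promis_depression", "promis_sleep_disturbance",
             "promis_pain_interference", "promis_physical_function",
             "pcs6", "n_pain_meds", "opioid_use"))
    opioid_tab <- table(cov$phenotype, cov$opioid_use)
    fish <- fisher_exact(opioid_tab,
                         seed = stage_seed(config$seed, "fisher"))
    kw <- group_compare(cov$age, cov$phenotype, mode = "kruskal")
    path <- file.path(config$out_dir, "or_table.tsv")
    utils::write.table(ors, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    state$or_table <- ors
    state$opioid_fisher_p <- fish$p
    state$age_kw_p <- kw$p
    path
  })

  run_stage("preprocess", function() {
    lab <- stats::setNames(state$labels$label,
                           state$labels$participant_id)
    sim <- state$expr
    sim$samples$phenotype_hat <-
      unname(lab[sim$samples$participant_id])
    prep_one <- function(counts, samp) {
      fac <- tmm_factors(counts)
      lc <- log_cpm(counts, fac)
      filt <- mad_filter(lc, keep_fraction = 0.30)
      adj <- batch_adjust(counts[rownames(filt), , drop = FALSE],
                          samp$batch)
      list(log_cpm = log_cpm(adj, tmm_factors(adj)),
           counts = adj, factors = fac)
    }
    day_idx <- sim$samples$time == "day"
    state$prep_day <- prep_one(sim$counts_day,
                               sim$samples[day_idx, ])
    state$prep_night <- prep_one(sim$counts_night,
                                 sim$samples[!day_idx, ])
    path <- file.path(config$out_dir, "tmm_factors_day.tsv")
    utils::write.table(state$prep_day$factors, path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    path
  })

  run_stage("de", function() {
    sim <- state$expr
    samp <- sim$samples[sim$samples$time == "day", ]
    lab <- stats::setNames(state$labels$label, state$labels$participant_id)
    samp$phenotype_hat <- unname(lab[samp$participant_id])
    keep <- samp$phenotype_hat %in% c("rhythmic_up", "constant_low",
                                      "constant_high", "mixed")
    samp <- samp[keep, ]
    samp$rhythmic <- factor(samp$phenotype_hat == "rhythmic_up",
                            levels = c(FALSE, TRUE))
    counts <- sim$counts_day[, keep, drop = FALSE]
    fit <- fit_nb_glm(counts, samp, ~ batch + sex + rhythmic)
    de <- contrast_de(fit, "rhythmicTRUE")
    path <- file.path(config$out_dir, "de_rhythmic_vs_rest.tsv")
    utils::write.table(de, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    state$de <- de
    path
  })

  run_stage("network", function() {
    nw_args <- merge_args(list(min_size = 15, merge_threshold = 0.30,
                               beta = NULL), config$network)
    lab <- stats::setNames(state$labels$label, state$labels$participant_id)
    build_one <- function(prep, samp) {
      nw <- build_network(prep$log_cpm, beta = nw_args$beta,
                          min_size = nw_args$min_size,
                          merge_threshold = nw_args$merge_threshold)
      ph <- unname(lab[samp$participant_id])
      assoc <- if (!is.null(nw$eigengenes)) {
        keep <- ph %in% c("rhythmic_up", "constant_low", "constant_high",
                          "mixed")
        module_trait(nw$eigengenes[keep, , drop = FALSE], ph[keep],
                     mode = "binary")
      } else NULL
      list(network = nw, assoc = assoc)
    }
    sim <- state$expr
    day_idx <- sim$samples$time == "day"
    state$net_day <- build_one(state$prep_day, sim$samples[day_idx, ])
    state$net_night <- build_one(state$prep_night,
                                 sim$samples[!day_idx, ])
    path <- file.path(config$out_dir, "module_trait_day.tsv")
    if (!is.null(state$net_day$assoc)) {
      utils::write.table(state$net_day$assoc, path, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    path
  })

  run_stage("replication", function() {
    repl <- state$repl
    des <- repl$design[repl$design$visit == "baseline", ]
    des$chronic <- !des$resolved
    or <- logistic_or(des, outcome = "chronic", exposure = "opioids",
                      covariates = c("sex", "age", "smoker"))
    ide <- interaction_de(repl$counts, repl$design)
    gs <- gsea(ide$ranked, repl$gene_sets, n_perm = 2000,
               seed = stage_seed(config$seed, "gsea"))
    path <- file.path(config$out_dir, "replication_gsea.tsv")
    utils::write.table(gs, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    state$repl_or <- or
    state$repl_gsea <- gs
    path
  })

  report$parameters <- config[c("cohort", "covariates", "counts",
                                "replication", "network")]
  report$stage_toggles <- as.list(config$stages)
  jsonlite::write_json(report,
                       file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(report)
}
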