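# Synthetic paired day/night count matrices and a two-visit replication
# cohort, with negative-binomial noise, batch/sex/time effects, and planted
# signal (a coexpression module tied to the rhythmic phenotype; an
# opioid-by-time interaction in a designated gene set).

#' Configuration for paired day/night count generation
#'
#' Counts follow a negative binomial with mean-dispersion parameterization
#' (Var = mu + alpha * mu^2), matching the downstream differential
#' expression model. A planted module of `planted_module_size` genes shares
#' a per-sample latent factor; that factor's participant-level score is
#' shifted down by `module_effect` (latent SD units) in rhythmic increasing
#' participants, so the planted eigengene is negatively associated with the
#' rhythmic phenotype at the default.
#'
#' @param seed integer seed.
#' @param n_transcripts number of transcripts simulated.
#' @param planted_module_size number of genes in the planted module.
#' @param module_effect downward shift of the latent module factor in
#'   rhythmic increasing participants (0 disables the planted association).
#' @param batch_effect_sd,sex_effect_sd,time_effect_sd SDs (natural-log
#'   scale) of gene-specific multiplicative batch/sex/night effects.
#' @param nb_dispersion NB dispersion alpha (>= 0; 0 gives Poisson).
#' @param lib_size_range range the per-sample library size is drawn from.
#' @return list of class `counts_config`.
#' @export
counts_config <- function(seed,
                          n_transcripts = 2000,
                          planted_module_size = 50,
                          module_effect = 1.0,
                          batch_effect_sd = 0.3,
                          sex_effect_sd = 0.2,
                          time_effect_sd = 0.2,
                          nb_dispersion = 0.1,
                          lib_size_range = c(2e5, 6e5)) {
  check_number(seed, "seed", integer = TRUE)
  check_number(n_transcripts, "n_transcripts", min = 1, integer = TRUE)
  check_number(planted_module_size, "planted_module_size", min = 0,
               integer = TRUE)
  if (planted_module_size > n_transcripts) {
    stop("config field 'planted_module_size' must be <= n_transcripts",
         call. = FALSE)
  }
  check_number(module_effect, "module_effect")
  check_number(batch_effect_sd, "batch_effect_sd", min = 0)
  check_number(sex_effect_sd, "sex_effect_sd", min = 0)
  check_number(time_effect_sd, "time_effect_sd", min = 0)
  check_number(nb_dispersion, "nb_dispersion", min = 0)
  stopifnot(length(lib_size_range) == 2, all(lib_size_range > 0))
  structure(as.list(environment()), class = "counts_config")
}

rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Generate paired day/night transcript counts with a planted module
#'
#' @param truth ground-truth data.frame (participant_id, phenotype); needs
#'   per-participant sex, drawn here if absent.
#' @param config a [counts_config()].
#' @return list with `counts_day`, `counts_night` (transcripts x samples
#'   integer matrices), `samples` (sample sheet: sample_id, participant_id,
#'   time, batch, sex, phenotype) and `truth` (adds `module_genes`).
#' @export
gen_counts <- function(truth, config) {
  stopifnot(inherits(config, "counts_config"))
  if (!is.data.frame(truth) || nrow(truth) == 0) {
    stop("truth must be a nonempty data.frame", call. = FALSE)
  }
  set.seed(config$seed)
  n_p <- nrow(truth)
  g <- config$n_transcripts
  gene_ids <- sprintf("TX%05d", seq_len(g))
  module_genes <- gene_ids[seq_len(config$planted_module_size)]

  # relative abundance profile shared by all samples
  abundance <- exp(stats::rnorm(g, 0, 1.5))
  abundance <- abundance / sum(abundance)

  batch <- sample(rep(c("b1", "b2"), length.out = n_p))
  sex <- if ("sex" %in% names(truth)) truth$sex else
    ifelse(stats::runif(n_p) < 0.5, "female", "male")

  batch_coef <- stats::rnorm(g, 0, config$batch_effect_sd)
  sex_coef <- stats::rnorm(g, 0, config$sex_effect_sd)
  time_coef <- stats::rnorm(g, 0, config$time_effect_sd)
  loading <- numeric(g)
  loading[seq_len(config$planted_module_size)] <-
    stats::runif(config$planted_module_size, 0.7, 1.3)

  z_participant <- stats::rnorm(n_p, 0, 1) -
    config$module_effect * (truth$phenotype == "rhythmic_up")

  make_matrix <- function(night) {
    m <- matrix(0L, g, n_p, dimnames = list(gene_ids, NULL))
    for (j in seq_len(n_p)) {
      lib <- stats::runif(1, config$lib_size_range[1],
                          config$lib_size_range[2])
      z <- z_participant[j] + stats::rnorm(1, 0, 0.3)
      eta <- batch_coef * (batch[j] == "b2") +
        sex_coef * (sex[j] == "female") +
        time_coef * night +
        loading * z
      mu <- lib * abundance * exp(eta)
      m[, j] <- rnbinom_mu(g, mu, config$nb_dispersion)
    }
    storage.mode(m) <- "integer"
    m
  }
  counts_day <- make_matrix(FALSE)
  counts_night <- make_matrix(TRUE)
  colnames(counts_day) <- paste0(truth$participant_id, "_day")
  colnames(counts_night) <- paste0(truth$participant_id, "_night")

  samples <- data.frame(
    sample_id = c(colnames(counts_day), colnames(counts_night)),
    participant_id = rep(truth$participant_id, 2),
    time = rep(c("day", "night"), each = n_p),
    batch = rep(batch, 2),
    sex = rep(sex, 2),
    phenotype = rep(truth$phenotype, 2),
    stringsAsFactors = FALSE)

  truth$module_score <- z_participant
  list(counts_day = counts_day, counts_night = counts_night,
       samples = samples,
       truth = list(participants = truth, module_genes = module_genes))
}

#' Configuration for the two-visit replication cohort
#'
#' Defaults mirror the replication study conditions: 45 opioid users and 52
#' nonusers sampled at a baseline and a 3-month follow-up visit, a
#' designated "degranulation" gene set with a positive opioid-by-time
#' expression interaction, and a chronicity outcome generated with odds
#' ratio `chronicity_or` for opioid use.
#'
#' @param seed integer seed.
#' @param n_users,n_nonusers participants per opioid-use group.
#' @param n_genes number of genes.
#' @param set_size size of the designated interaction gene set.
#' @param interaction_lfc natural-log fold change per visit added to
#'   designated genes in opioid users at follow-up (0 disables the signal).
#' @param chronicity_or generating odds ratio of chronic pain for opioid use.
#' @param nb_dispersion NB dispersion.
#' @param n_decoy_sets number of random same-scale decoy gene sets emitted.
#' @return list of class `replication_config`.
#' @export
replication_config <- function(seed,
                               n_users = 45,
                               n_nonusers = 52,
                               n_genes = 2000,
                               set_size = 50,
                               interaction_lfc = 0.8,
                               chronicity_or = 2.6,
                               nb_dispersion = 0.1,
                               n_decoy_sets = 20) {
  check_number(seed, "seed", integer = TRUE)
  check_number(n_users, "n_users", min = 1, integer = TRUE)
  check_number(n_nonusers, "n_nonusers", min = 1, integer = TRUE)
  if (n_users + n_nonusers <= 5) {
    stop("config fields 'n_users'+'n_nonusers' must exceed the covariate",
         " count (5)", call. = FALSE)
  }
  check_number(n_genes, "n_genes", min = 1, integer = TRUE)
  check_number(set_size, "set_size", min = 1, integer = TRUE)
  if (set_size > n_genes) {
    stop("config field 'set_size' must be <= n_genes", call. = FALSE)
  }
  check_number(interaction_lfc, "interaction_lfc")
  check_number(chronicity_or, "chronicity_or", min = 0)
  check_number(nb_dispersion, "nb_dispersion", min = 0)
  check_number(n_decoy_sets, "n_decoy_sets", min = 0, integer = TRUE)
  structure(as.list(environment()), class = "replication_config")
}

#' Generate the two-visit replication dataset
#'
#' Per-gene trajectories have a participant random effect and a common time
#' effect; designated genes additionally gain `interaction_lfc` in opioid
#' users at follow-up (a positive opioid-by-time interaction: expression
#' lingers or rises with time in users). The chronicity outcome is drawn
#' from a logistic model with the configured odds ratio for opioid use plus
#' weak age/smoking effects.
#'
#' @param config a [replication_config()].
#' @return list with `counts` (genes x samples), `design` (per-sample:
#'   participant, visit, opioids, age, sex, smoker, RIN, resolved),
#'   `gene_sets` (designated set first, then decoys) and `truth`.
#' @export
gen_replication <- function(config) {
  stopifnot(inherits(config, "replication_config"))
  set.seed(config$seed)
  n <- config$n_users + config$n_nonusers
  g <- config$n_genes
  gene_ids <- sprintf("G%05d", seq_len(g))
  target <- gene_ids[seq_len(config$set_size)]

  opioids <- rep(c(TRUE, FALSE), c(config$n_users, config$n_nonusers))
  age <- pmin(pmax(round_half_away(stats::rnorm(n, 45, 13)), 18), 80)
  sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
  smoker <- stats::runif(n) < 0.25
  rin <- pmin(pmax(stats::rnorm(n, 8.5, 0.7), 7.5), 10)

  lp <- -0.45 + log(config$chronicity_or) * opioids +
    0.01 * (age - 45) + 0.2 * smoker
  chronic <- stats::runif(n) < stats::plogis(lp)

  abundance <- exp(stats::rnorm(g, 0, 1.5))
  abundance <- abundance / sum(abundance)
  time_coef <- stats::rnorm(g, 0, 0.15)
  inter <- numeric(g)
  inter[seq_len(config$set_size)] <- config$interaction_lfc
  part_eff <- matrix(stats::rnorm(n * 1, 0, 0.25), n, 1)

  pid <- sprintf("R%03d", seq_len(n))
  counts <- matrix(0L, g, 2 * n, dimnames = list(gene_ids, NULL))
  design <- vector("list", 2 * n)
  k <- 0L
  for (visit in c("baseline", "followup")) {
    t1 <- visit == "followup"
    for (j in seq_len(n)) {
      k <- k + 1L
      lib <- stats::runif(1, 2e5, 6e5)
      eta <- part_eff[j, 1] + time_coef * t1 + inter * (t1 & opioids[j])
      counts[, k] <- rnbinom_mu(g, lib * abundance * exp(eta),
                                config$nb_dispersion)
      design[[k]] <- data.frame(
        sample_id = paste0(pid[j], "_", visit),
        participant_id = pid[j], visit = visit,
        opioids = opioids[j], age = age[j], sex = sex[j],
        smoker = smoker[j], RIN = rin[j], resolved = !chronic[j],
        stringsAsFactors = FALSE)
    }
  }
  design <- do.call(rbind, design)
  storage.mode(counts) <- "integer"
  colnames(counts) <- design$sample_id

  gene_sets <- list(DEGRANULATION_SYNTH = target)
  if (config$n_decoy_sets > 0) {
    for (i in seq_len(config$n_decoy_sets)) {
      sz <- min(sample(20:80, 1), g)
      gene_sets[[sprintf("DECOY_%02d", i)]] <- sample(gene_ids, sz)
    }
  }
  list(counts = counts, design = design, gene_sets = gene_sets,
       truth = list(target_set = target, chronic = chronic,
                    opioids = opioids))
}
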