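# Negative-binomial GLM differential expression with covariates and
# Bonferroni control; candidate gene-set DE; the replication cohort's
# opioid-by-time interaction model; logistic odds ratio for chronicity.

#' Fit per-transcript negative-binomial GLMs
#'
#' Counts are modelled with edgeR: TMM effective library sizes as offsets,
#' per-gene dispersions (with trend/common fallback) and a GLM on the
#' supplied design. All-zero transcripts are dropped before fitting and
#' recorded in the returned object.
#'
#' @param counts transcripts x samples integer matrix.
#' @param samples data.frame of per-sample covariates (rows match columns
#'   of `counts`).
#' @param design a one-sided formula evaluated in `samples`.
#' @return object of class `nbglm_fit`: edgeR fit, design matrix, dropped
#'   transcript ids.
#' @export
fit_nb_glm <- function(counts, samples, design) {
  stopifnot(is.matrix(counts), nrow(samples) == ncol(counts))
  X <- stats::model.matrix(design, data = samples)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is not full rank; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]
  dge <- edgeR::DGEList(counts = counts)
  dge <- edgeR::calcNormFactors(dge, method = "TMM")
  dge <- edgeR::estimateDisp(dge, X)
  fit <- edgeR::glmFit(dge, X)
  structure(list(fit = fit, design = X, dropped = dropped),
            class = "nbglm_fit")
}

#' Likelihood-ratio differential expression for one contrast
#'
#' @param fitobj an `nbglm_fit`.
#' @param coef coefficient name (or index) of the design matrix to test, or
#'   a numeric contrast vector.
#' @param alpha Bonferroni-adjusted significance threshold.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return data.frame: transcript, log2fc, stat, p, p_adj, sign, de.
#' @export
contrast_de <- function(fitobj, coef, alpha = 0.05,
                        adjust = c("bonferroni", "BH")) {
  stopifnot(inherits(fitobj, "nbglm_fit"))
  adjust <- match.arg(adjust)
  if (is.character(coef) && length(coef) == 1 &&
      !coef %in% colnames(fitobj$design)) {
    stop("unknown coefficient '", coef, "'; design has: ",
         paste(colnames(fitobj$design), collapse = ", "), call. = FALSE)
  }
  lrt <- if (is.numeric(coef) && length(coef) > 1) {
    edgeR::glmLRT(fitobj$fit, contrast = coef)
  } else {
    edgeR::glmLRT(fitobj$fit, coef = coef)
  }
  tab <- lrt$table
  out <- data.frame(transcript = rownames(tab), log2fc = tab$logFC,
                    stat = tab$LR, p = tab$PValue,
                    p_adj = stats::p.adjust(tab$PValue, method = adjust),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$sign <- sign(out$log2fc)
  out$de <- out$p_adj < alpha
  out
}

#' Candidate gene-set differential expression
#'
#' Tests only the transcripts in the union of the supplied gene sets;
#' the multiplicity correction uses the candidate subset size only.
#'
#' @param fitobj an `nbglm_fit`.
#' @param coef coefficient to test (see [contrast_de()]).
#' @param gene_sets named list of transcript id vectors.
#' @param alpha adjusted-p threshold.
#' @return data.frame as in [contrast_de()], restricted to candidates.
#' @export
candidate_de <- function(fitobj, coef, gene_sets, alpha = 0.05) {
  stopifnot(inherits(fitobj, "nbglm_fit"))
  candidates <- unique(unlist(gene_sets))
  present <- intersect(candidates, rownames(fitobj$fit$counts))
  if (length(present) == 0) {
    stop("no candidate transcripts present in the matrix; missing ids: ",
         paste(utils::head(candidates, 10), collapse = ", "),
         if (length(candidates) > 10) ", ..." else "", call. = FALSE)
  }
  full <- contrast_de(fitobj, coef, alpha = alpha)
  out <- full[full$transcript %in% present, ]
  out$p_adj <- pmin(1, out$p * length(present))
  out$de <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Opioid-by-time interaction model for the two-visit replication cohort
#'
#' Fits the replication design
#' `~ age + sex + RIN + smoker + resolved + time + opioids + time:opioids`
#' with DESeq2 and extracts the interaction term's Wald statistic per gene.
#' A positive sign means expression lingered or rose with time in opioid
#' users relative to nonusers. Participants with only one visit are
#' excluded (with a message). Genes are returned ranked from most positive
#' to most negative interaction for enrichment input.
#'
#' @param counts genes x samples integer matrix.
#' @param design per-sample data.frame with columns `participant_id`,
#'   `visit` ("baseline"/"followup"), `opioids`, `age`, `sex`, `smoker`,
#'   `RIN`, `resolved`.
#' @return list: `table` (gene, log2fc, stat, p, p_fdr), `ranked` (named
#'   stat vector, decreasing).
#' @export
interaction_de <- function(counts, design) {
  stopifnot(is.matrix(counts), nrow(design) == ncol(counts))
  visits <- table(design$participant_id)
  singles <- names(visits)[visits < 2]
  if (length(singles)) {
    message("interaction_de: excluding ", length(singles),
            " participant(s) with a single visit: ",
            paste(utils::head(singles, 5), collapse = ", "))
    keep <- !design$participant_id %in% singles
    design <- design[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  cd <- data.frame(
    age = as.numeric(scale(design$age)),
    sex = factor(design$sex),
    RIN = as.numeric(scale(design$RIN)),
    smoker = factor(design$smoker),
    resolved = factor(design$resolved),
    time = factor(design$visit, levels = c("baseline", "followup")),
    opioids = factor(design$opioids, levels = c(FALSE, TRUE)))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = counts, colData = cd,
    design = ~ age + sex + RIN + smoker + resolved + time + opioids +
      time:opioids)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  rn <- DESeq2::resultsNames(dds)
  iname <- grep("^time.*opioids", rn, value = TRUE)
  stopifnot(length(iname) == 1)
  res <- DESeq2::results(dds, name = iname)
  tab <- data.frame(gene = rownames(res), log2fc = res$log2FoldChange,
                    stat = res$stat, p = res$pvalue, p_fdr = res$padj,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[!is.na(tab$stat), ]
  ranked <- stats::setNames(tab$stat, tab$gene)
  ranked <- sort(ranked, decreasing = TRUE)
  list(table = tab, ranked = ranked)
}

#' Logistic odds ratio for a binary outcome on a binary exposure
#'
#' Maximum-likelihood logistic regression; OR = exp(beta) and 95% CI =
#' exp(beta +/- 1.96 se) exactly. Separation is flagged when the
#' coefficient exceeds the guard or the fit does not converge.
#'
#' @param data data.frame.
#' @param outcome,exposure column names of logical/binary variables.
#' @param covariates additional adjustment column names.
#' @param beta_guard separation guard on |beta|.
#' @return one-row data.frame: beta, se, or, ci_lo, ci_hi, p, separation.
#' @export
logistic_or <- function(data, outcome, exposure, covariates = character(0),
                        beta_guard = 15) {
  form <- stats::reformulate(c(exposure, covariates), response = outcome)
  fit <- suppressWarnings(
    stats::glm(form, data = data, family = stats::binomial()))
  co <- summary(fit)$coefficients
  term <- grep(paste0("^", exposure), rownames(co), value = TRUE)[1]
  beta <- co[term, "Estimate"]
  se <- co[term, "Std. Error"]
  data.frame(term = term, beta = beta, se = se, or = exp(beta),
             ci_lo = exp(beta - 1.96 * se), ci_hi = exp(beta + 1.96 * se),
             p = co[term, "Pr(>|z|)"],
             separation = abs(beta) > beta_guard || !fit$converged,
             stringsAsFactors = FALSE, row.names = NULL)
}
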