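# Group-level statistics: multinomial logistic regression odds ratios
# against the rhythmic-increasing reference, exact contingency tests, rank
# tests, correlations, blood-count percent change, and ddCt fold changes.

#' Multinomial logistic regression odds ratios vs a reference phenotype
#'
#' Fits a maximum-likelihood multinomial logit (via `nnet::multinom`) of
#' phenotype on the listed covariates with the rhythmic increasing group as
#' the reference, and reports per-contrast log odds, OR = exp(beta), Wald
#' 95% CIs exp(beta +/- 1.96 se) and p-values. Quasi-complete separation
#' (e.g. a medication used by no one in the reference group) drives a
#' coefficient to infinity; it is detected by refitting with a larger
#' iteration budget and monitoring coefficient divergence, plus a hard
#' |beta| guard. Flagged ORs are reported as the bounded sentinel
#' exp(+/- guard) rather than a meaningless huge number.
#'
#' @param data data.frame with a `phenotype` column and the covariates.
#' @param covariates character vector of covariate column names.
#' @param reference reference phenotype level.
#' @param per_covariate if `TRUE`, fit one model per covariate instead of a
#'   single joint model.
#' @param beta_guard |beta| above which a coefficient is declared separated.
#' @return data.frame (class `or_table`): contrast level, term, beta, se,
#'   or, ci_lo, ci_hi, p, separation.
#' @export
fit_multinomial_or <- function(data, covariates, reference = "rhythmic_up",
                               per_covariate = FALSE, beta_guard = 15) {
  stopifnot(is.data.frame(data), "phenotype" %in% names(data))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  data$phenotype <- stats::relevel(factor(data$phenotype), ref = reference)
  if (nlevels(data$phenotype) < 2) {
    stop("need at least 2 phenotype levels", call. = FALSE)
  }
  if (per_covariate) {
    res <- lapply(covariates, function(cv) {
      fit_multinomial_or(data, cv, reference = reference,
                         per_covariate = FALSE, beta_guard = beta_guard)
    })
    return(do.call(rbind, res))
  }
  # binary covariates as 0/1 so ORs are per-unit
  for (cv in covariates) {
    if (is.logical(data[[cv]])) data[[cv]] <- as.numeric(data[[cv]])
  }
  X <- stats::model.matrix(
    stats::reformulate(covariates), data = data)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is singular; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  form <- stats::reformulate(covariates, response = "phenotype")
  fit1 <- nnet::multinom(form, data = data, trace = FALSE, maxit = 60,
                         reltol = 1e-12)
  fit2 <- nnet::multinom(form, data = data, trace = FALSE, maxit = 400,
                         reltol = 1e-12)
  co1 <- coef_matrix(fit1)
  co <- coef_matrix(fit2)
  se <- se_matrix(fit2)
  diverging <- abs(co) > beta_guard | (abs(co) - abs(co1) > 2 & abs(co) > 5)
  # quasi-complete separation of a binary design column: a zero cell in its
  # cross-tab with (level vs reference) makes that logit MLE infinite even
  # when the optimizer stalls at a finite estimate.
  ref <- levels(data$phenotype)[1]
  for (tm in colnames(co)) {
    xc <- X[, tm]
    if (length(unique(xc)) != 2) next
    for (lv in rownames(co)) {
      idx <- data$phenotype %in% c(ref, lv)
      tt <- table(factor(xc[idx]), data$phenotype[idx] == lv)
      if (any(tt == 0)) diverging[lv, tm] <- TRUE
    }
  }
  levels_out <- rownames(co)
  out <- do.call(rbind, lapply(levels_out, function(lv) {
    data.frame(level = lv, term = colnames(co),
               beta = co[lv, ], se = se[lv, ],
               separation = diverging[lv, ],
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  b_rep <- pmin(pmax(out$beta, -beta_guard), beta_guard)
  b_rep[!out$separation] <- out$beta[!out$separation]
  out$or <- exp(b_rep)
  out$ci_lo <- exp(b_rep - 1.96 * out$se)
  out$ci_hi <- exp(b_rep + 1.96 * out$se)
  out$p <- 2 * stats::pnorm(-abs(out$beta / out$se))
  out <- out[out$term != "(Intercept)",
             c("level", "term", "beta", "se", "or", "ci_lo", "ci_hi", "p",
               "separation")]
  rownames(out) <- NULL
  class(out) <- c("or_table", "data.frame")
  out
}

# nnet::multinom returns a vector for 2-level outcomes; normalize to matrix.
coef_matrix <- function(fit) {
  co <- stats::coef(fit)
  if (!is.matrix(co)) {
    co <- matrix(co, nrow = 1, dimnames = list(fit$lev[2], names(co)))
  }
  co
}

se_matrix <- function(fit) {
  v <- sqrt(diag(stats::vcov(fit)))
  co <- coef_matrix(fit)
  se <- matrix(NA_real_, nrow(co), ncol(co), dimnames = dimnames(co))
  # vcov names look like "level:term" for >2 levels, plain terms for 2
  if (nrow(co) == 1) {
    se[1, ] <- v[colnames(co)]
  } else {
    for (lv in rownames(co)) for (tm in colnames(co)) {
      se[lv, tm] <- v[paste0(lv, ":", tm)]
    }
  }
  se
}

#' Fisher's exact test for r x c contingency tables
#'
#' 2x2 tables use the standard two-sided hypergeometric rule; larger tables
#' use the Freeman-Halton extension (probabilities of all tables with the
#' observed margins that are no more probable than the observed one). When
#' the table exceeds the exact-enumeration budget (total > 500 and both
#' dimensions > 5) a seeded Monte-Carlo p-value is used.
#'
#' @param tab integer matrix of counts (>= 2x2, all cells >= 0).
#' @param B Monte-Carlo replicates for large tables.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list: `p`, `method`.
#' @export
fisher_exact <- function(tab, B = 1e5, seed = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab)) || any(!is.finite(tab))) {
    stop("contingency table must hold non-negative integer counts",
         call. = FALSE)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table must be at least 2x2", call. = FALSE)
  }
  exact_ok <- sum(tab) <= 500 || (nrow(tab) <= 5 && ncol(tab) <= 5)
  if (exact_ok) {
    res <- tryCatch(
      stats::fisher.test(tab, workspace = 2e7),
      error = function(e) NULL)
    if (!is.null(res)) {
      return(list(p = res$p.value, method = "exact"))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  res <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)
  list(p = res$p.value, method = "monte_carlo")
}

#' Compare a continuous variable across phenotype groups
#'
#' `mode = "kruskal"` runs the tie-corrected Kruskal-Wallis test;
#' `mode = "anova_tukey"` runs an ordinary one-way ANOVA with post hoc
#' Tukey HSD pairwise comparisons.
#'
#' @param values numeric vector.
#' @param groups grouping factor/character of the same length.
#' @param mode test flavor.
#' @return list: `statistic`, `p`, and for ANOVA a `pairwise` data.frame of
#'   Tukey-adjusted comparisons.
#' @export
group_compare <- function(values, groups, mode = c("kruskal",
                                                   "anova_tukey")) {
  mode <- match.arg(mode)
  if (!is.factor(groups)) groups <- factor(groups)
  empty <- levels(groups)[tabulate(groups, nlevels(groups)) == 0]
  if (length(empty)) {
    stop("empty group(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (mode == "kruskal") {
    if (length(unique(values)) == 1) {
      return(list(statistic = 0, p = 1, pairwise = NULL))
    }
    k <- stats::kruskal.test(values, groups)
    return(list(statistic = unname(k$statistic), p = k$p.value,
                pairwise = NULL))
  }
  if (any(tabulate(groups) < 2)) {
    stop("ANOVA needs >= 2 values per group", call. = FALSE)
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  list(statistic = sm[["F value"]][1], p = sm[["Pr(>F)"]][1],
       pairwise = pairwise)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average (mid-) ranks; p from the t approximation
#' `t = r * sqrt((n-2)/(1-r^2))`. Zero rank variance (a constant input) is
#' flagged instead of returning a spurious value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: `estimate`, `p`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) {
    stop("need >= 3 complete pairs of equal length", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(estimate = NA_real_, p = NA_real_, n = n,
                degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(estimate = r, p = p, n = n, degenerate = FALSE)
}

#' Percent change from the day to the night measurement
#'
#' @param day_value,night_value numeric vectors; `day_value` must be
#'   nonzero.
#' @return `100 * (night - day) / day`.
#' @export
pct_change <- function(day_value, night_value) {
  if (any(day_value == 0)) {
    stop("percent change undefined for a day value of 0", call. = FALSE)
  }
  100 * (night_value - day_value) / day_value
}

#' Relative qPCR quantification (2^-ddCt fold change)
#'
#' ddCt = (Ct_target,cond - Ct_ref,cond) - (Ct_target,ctrl - Ct_ref,ctrl);
#' the fold change is 2^-ddCt.
#'
#' @param ct_target_cond,ct_ref_cond,ct_target_ctrl,ct_ref_ctrl Ct values.
#' @return fold change(s).
#' @export
ddct_fold_change <- function(ct_target_cond, ct_ref_cond,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_cond, ct_ref_cond,
                            ct_target_ctrl, ct_ref_ctrl))))
  ddct <- (ct_target_cond - ct_ref_cond) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' The published antidepressant-use contingency table
#'
#' Reconstructs the 4 (phenotype) x 2 (antidepressant yes/no) counts from
#' the printed group sizes and percentages: 1 of 10 (rhythmic increasing),
#' 2 of 17 (11.8%, constant-low), 42.1% of 19 (mixed) and 57.1% of 14
#' (constant-high).
#'
#' @return integer matrix with phenotype rows and yes/no columns.
#' @export
antidepressant_table <- function() {
  counts <- rbind(
    rhythmic_up   = c(yes = 1, no = 9),
    constant_low  = c(yes = 2, no = 15),
    mixed         = c(yes = 8, no = 11),
    constant_high = c(yes = 8, no = 6))
  storage.mode(counts) <- "integer"
  counts
}
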