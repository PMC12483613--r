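# Signed weighted coexpression network analysis: soft-threshold selection
# by scale-free fit, signed adjacency, topological overlap, average-linkage
# clustering with an adaptive tree cut, module eigengenes, correlation-based
# merging, and module-phenotype association. Day and night networks are
# built independently from their own sample sets.

#' Pick the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, the signed adjacency is formed and the
#' connectivity distribution is binned; the scale-free fit index is the
#' R-squared of the log10(p(k)) ~ log10(k) regression, signed by the
#' negated slope sign (a proper scale-free fit has a negative slope). The
#' chosen power is the smallest one reaching `rsq_target`, or the argmax
#' when none does.
#'
#' @param expr transcripts x samples numeric matrix (>= 20 transcripts,
#'   >= 8 samples).
#' @param powers candidate integer powers.
#' @param rsq_target target signed R-squared (default 0.80).
#' @param n_breaks connectivity histogram bins.
#' @return list: `power`, `fit_table` (power, rsq_signed, slope, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, rsq_target = 0.80,
                                n_breaks = 10) {
  stopifnot(nrow(expr) >= 20, ncol(expr) >= 8)
  base <- (1 + stats::cor(t(expr))) / 2
  diag(base) <- 0
  rows <- lapply(powers, function(b) {
    k <- rowSums(base^b)
    br <- seq(min(k), max(k), length.out = n_breaks + 1)
    bin <- cut(k, br, include.lowest = TRUE)
    dk <- tapply(k, bin, mean)
    pk <- tabulate(bin, n_breaks) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(ok) < 3) {
      return(data.frame(power = b, rsq_signed = NA_real_,
                        slope = NA_real_, mean_k = mean(k)))
    }
    fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    slope <- stats::coef(fit)[2]
    rsq <- summary(fit)$r.squared
    data.frame(power = b, rsq_signed = -sign(slope) * rsq,
               slope = unname(slope), mean_k = mean(k))
  })
  fit_table <- do.call(rbind, rows)
  hit <- which(!is.na(fit_table$rsq_signed) &
                 fit_table$rsq_signed >= rsq_target)
  power <- if (length(hit)) fit_table$power[min(hit)] else
    fit_table$power[which.max(fit_table$rsq_signed)]
  list(power = power, fit_table = fit_table)
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^beta`, diagonal 1; anti-correlated
#' transcripts get adjacency near 0 (signed network).
#'
#' @param expr transcripts x samples matrix without constant rows.
#' @param beta soft-threshold power (integer >= 1).
#' @return symmetric adjacency matrix in `[0, 1]`.
#' @export
signed_adjacency <- function(expr, beta) {
  check_number(beta, "beta", min = 1)
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant transcript(s): ",
         paste(utils::head(rownames(expr)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  a <- ((1 + stats::cor(t(expr))) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix and dissimilarity
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` where `l_ij` sums
#' the shared-neighbor adjacency products and `k` is the connectivity (row
#' sum minus the diagonal); `TOM_ii = 1`. The dissimilarity is `1 - TOM`.
#'
#' @param adjacency square symmetric matrix with unit diagonal.
#' @return list: `tom`, `dissimilarity`.
#' @export
tom <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-8)) {
    stop("adjacency must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(a) - 1) > 1e-8)) {
    stop("adjacency must have unit diagonal", call. = FALSE)
  }
  k <- rowSums(a) - 1
  L <- a %*% a           # (A^2)_ij includes the u = i and u = j terms (2 a_ij)
  num <- L - a           # = l_ij + a_ij with l_ij = (A^2)_ij - 2 a_ij
  den <- outer(k, k, pmin) + 1 - a
  t_mat <- num / den
  diag(t_mat) <- 1
  t_mat <- pmin(pmax(t_mat, 0), 1)
  list(tom = t_mat, dissimilarity = 1 - t_mat)
}

#' Detect modules by clustering the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering followed by an adaptive branch
#' cut: candidate cut heights (midpoints between consecutive merge heights)
#' are scored by the number of resulting clusters holding at least
#' `min_size` members, and the highest cut achieving the maximum is used.
#' Clusters below `min_size`, or whose mean internal dissimilarity (core
#' scatter) is not below the cut height, are assigned to "grey". A static
#' cut at the 0.99 quantile of merge heights is available as a fallback.
#'
#' @param dissimilarity square dissimilarity matrix (1 - TOM).
#' @param min_size minimum module size.
#' @param method `"adaptive"` (default) or `"static"`.
#' @param cut_height optional fixed cut height.
#' @return named character vector of module labels ("grey" = unassigned;
#'   modules "M1", "M2", ... by decreasing size).
#' @export
detect_modules <- function(dissimilarity, min_size = 20,
                           method = c("adaptive", "static"),
                           cut_height = NULL) {
  method <- match.arg(method)
  d <- as.matrix(dissimilarity)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) < min_size) {
    warning("fewer transcripts than min_size; all grey", call. = FALSE)
    return(stats::setNames(rep("grey", nrow(d)), ids))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  heights <- sort(unique(hc$height))
  if (!is.null(cut_height)) {
    candidates <- cut_height
  } else if (method == "static") {
    candidates <- stats::quantile(hc$height, 0.99, names = FALSE)
  } else {
    h <- c(heights, max(heights) * 1.001)
    candidates <- (h[-1] + h[-length(h)]) / 2
  }
  best <- NULL; best_score <- -1; best_h <- NA
  for (h in candidates) {
    cl <- stats::cutree(hc, h = h)
    score <- sum(table(cl) >= min_size)
    if (score > best_score ||
        (score == best_score && !is.na(best_h) && h > best_h)) {
      best <- cl; best_score <- score; best_h <- h
    }
  }
  labels <- rep("grey", length(ids))
  names(labels) <- ids
  sizes <- table(best)
  keep <- names(sizes)[sizes >= min_size]
  # core-scatter check: a real module is tighter than the cut that made it
  # and clearly tighter than the cohort at large (guards against the whole
  # tree masquerading as one module)
  overall <- mean(d[upper.tri(d)])
  keep <- Filter(function(cl_id) {
    members <- which(best == as.integer(cl_id))
    scatter <- mean(d[members, members][upper.tri(d[members, members])])
    scatter < best_h && scatter < 0.95 * overall
  }, keep)
  if (length(keep)) {
    # deterministic module numbering: by size desc, ties by first member id
    first_member <- vapply(keep, function(cl_id) {
      min(ids[best == as.integer(cl_id)])
    }, character(1))
    ord <- order(-sizes[keep], first_member)
    for (i in seq_along(ord)) {
      cl_id <- keep[ord[i]]
      labels[best == as.integer(cl_id)] <- paste0("M", i)
    }
  } else {
    warning("no cluster reached min_size; all grey", call. = FALSE)
  }
  labels
}

#' Module eigengenes
#'
#' Per module, the first principal component of the standardized member
#' profiles (unit-norm per-sample score vector), sign-anchored to correlate
#' positively with the module's mean standardized profile, with the
#' fraction of variance it explains.
#'
#' @param expr transcripts x samples matrix.
#' @param labels module label per transcript ("grey" ignored).
#' @return list: `eigengenes` (samples x modules matrix, unit columns),
#'   `var_explained` (named vector).
#' @export
eigengenes <- function(expr, labels) {
  stopifnot(nrow(expr) == length(labels))
  mods <- setdiff(unique(labels), "grey")
  mods <- mods[order(mods)]
  if (!length(mods)) stop("no modules to summarize", call. = FALSE)
  eg <- matrix(NA_real_, ncol(expr), length(mods),
               dimnames = list(colnames(expr), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    X <- expr[labels == m, , drop = FALSE]
    if (nrow(X) < 2) stop("module '", m, "' has < 2 transcripts",
                          call. = FALSE)
    Xs <- t(scale(t(X)))
    Xs[!is.finite(Xs)] <- 0
    sv <- svd(Xs)
    v1 <- sv$v[, 1]
    anchor <- colMeans(Xs)
    if (stats::sd(anchor) > 0 && stats::cor(v1, anchor) < 0) v1 <- -v1
    eg[, m] <- v1
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eg, var_explained = ve)
}

#' Iteratively merge modules with correlated eigengenes
#'
#' While any pair of module eigengenes has |Pearson correlation| at or
#' above `threshold`, the most correlated pair is merged and eigengenes are
#' recomputed; terminates when all pairwise correlations are below the
#' threshold or a single module remains.
#'
#' @param expr transcripts x samples matrix.
#' @param labels module labels.
#' @param threshold merge correlation threshold (default 0.30, the study's
#'   aggressive setting; the common convention is ~0.75).
#' @param use_abs compare |r| (default) rather than signed r.
#' @return list: `labels`, `eigengenes`, `var_explained`, `n_merges`.
#' @export
merge_modules <- function(expr, labels, threshold = 0.30, use_abs = TRUE) {
  stopifnot(threshold > 0, threshold < 1)
  n_merges <- 0L
  repeat {
    eg <- eigengenes(expr, labels)
    mods <- colnames(eg$eigengenes)
    if (length(mods) < 2) break
    C <- stats::cor(eg$eigengenes)
    cc <- if (use_abs) abs(C) else C
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] < threshold) break
    from <- mods[max(mx)]; into <- mods[min(mx)]
    labels[labels == from] <- into
    n_merges <- n_merges + 1L
  }
  eg <- eigengenes(expr, labels)
  list(labels = labels, eigengenes = eg$eigengenes,
       var_explained = eg$var_explained, n_merges = n_merges)
}

#' Associate module eigengenes with the pain phenotype
#'
#' Binary mode: logistic GLM of (phenotype == reference) on each eigengene.
#' Multinomial mode: multinomial GLM with the reference level as baseline;
#' one row per module and non-reference level. Constant eigengenes are
#' flagged and not fitted.
#'
#' @param eigengene_matrix samples x modules matrix.
#' @param phenotype per-sample phenotype labels.
#' @param mode `"binary"` or `"multinomial"`.
#' @param reference the phenotype of interest (default rhythmic
#'   increasing).
#' @return data.frame: module, level, beta, se, or, p, degenerate.
#' @export
module_trait <- function(eigengene_matrix, phenotype,
                         mode = c("binary", "multinomial"),
                         reference = "rhythmic_up") {
  mode <- match.arg(mode)
  stopifnot(nrow(eigengene_matrix) == length(phenotype))
  if (length(unique(phenotype)) < 2) {
    stop("phenotype has a single level", call. = FALSE)
  }
  rows <- list()
  for (m in colnames(eigengene_matrix)) {
    me <- eigengene_matrix[, m]
    if (stats::sd(me) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, level = NA_character_, beta = NA_real_, se = NA_real_,
        or = NA_real_, p = NA_real_, degenerate = TRUE,
        stringsAsFactors = FALSE)
      next
    }
    if (mode == "binary") {
      y <- as.numeric(phenotype == reference)
      fit <- suppressWarnings(stats::glm(y ~ me,
                                         family = stats::binomial()))
      co <- summary(fit)$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, level = reference, beta = co["me", "Estimate"],
        se = co["me", "Std. Error"], or = exp(co["me", "Estimate"]),
        p = co["me", "Pr(>|z|)"], degenerate = FALSE,
        stringsAsFactors = FALSE)
    } else {
      ph <- stats::relevel(factor(phenotype), ref = reference)
      df <- data.frame(ph = ph, me = me)
      fit <- nnet::multinom(ph ~ me, data = df, trace = FALSE,
                            reltol = 1e-12)
      co <- coef_matrix(fit)
      se <- se_matrix(fit)
      for (lv in rownames(co)) {
        z <- co[lv, "me"] / se[lv, "me"]
        rows[[length(rows) + 1L]] <- data.frame(
          module = m, level = lv, beta = co[lv, "me"], se = se[lv, "me"],
          or = exp(co[lv, "me"]), p = 2 * stats::pnorm(-abs(z)),
          degenerate = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' End-to-end network construction for one time point
#'
#' Convenience composition: soft-threshold pick (optional fixed power),
#' signed adjacency, TOM, module detection, eigengenes, and merging.
#'
#' @param expr transcripts x samples matrix (transformed scale).
#' @param beta fixed power; `NULL` picks by scale-free fit.
#' @param min_size minimum module size.
#' @param merge_threshold eigengene merge correlation.
#' @return list: `power`, `labels`, `eigengenes`, `var_explained`,
#'   `fit_table`.
#' @export
build_network <- function(expr, beta = NULL, min_size = 20,
                          merge_threshold = 0.30) {
  fit_table <- NULL
  if (is.null(beta)) {
    pk <- pick_soft_threshold(expr)
    beta <- pk$power
    fit_table <- pk$fit_table
  }
  adj <- signed_adjacency(expr, beta)
  tm <- tom(adj)
  labels <- detect_modules(tm$dissimilarity, min_size = min_size)
  if (all(labels == "grey")) {
    return(list(power = beta, labels = labels, eigengenes = NULL,
                var_explained = NULL, fit_table = fit_table))
  }
  merged <- merge_modules(expr, labels, threshold = merge_threshold)
  list(power = beta, labels = merged$labels,
       eigengenes = merged$eigengenes,
       var_explained = merged$var_explained, fit_table = fit_table)
}
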