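# Count-matrix triage and normalization: TMM factors, MAD-based
# nonspecific filtering, three-metric sample-outlier triage, median
# log-ratio batch centering, and the log-CPM transform.

#' TMM normalization factors
#'
#' Trimmed mean of M-values via edgeR (30% M trim, 5% A trim, reference =
#' library whose upper quartile is closest to the mean upper quartile).
#' Returns both the composition-only factor and the *effective* relative
#' library scaling (library size times composition factor, rescaled to
#' geometric mean 1), which is what downstream transforms divide by: a
#' sample whose counts are doubled wholesale has `rel_factor` twice its
#' peers even though its composition factor is 1.
#'
#' @param m transcripts x samples integer count matrix (>= 2 samples).
#' @return data.frame: sample, lib_size, norm_factor, eff_lib_size,
#'   rel_factor (geometric mean 1).
#' @export
tmm_factors <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need >= 2 samples", call. = FALSE)
  zero <- colSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  }
  dge <- edgeR::calcNormFactors(edgeR::DGEList(counts = m), method = "TMM")
  lib <- dge$samples$lib.size
  nf <- dge$samples$norm.factors
  eff <- lib * nf
  data.frame(sample = colnames(m), lib_size = lib, norm_factor = nf,
             eff_lib_size = eff, rel_factor = eff / geometric_mean(eff),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Keep the most variable transcripts by median absolute deviation
#'
#' Rows are ranked by MAD of their (typically log-transformed) values; the
#' top `ceil(keep_fraction * nrow)` are retained, MAD ties broken by row id
#' for determinism. Constant rows (MAD 0) rank last.
#'
#' @param m numeric matrix with unique rownames.
#' @param keep_fraction fraction of rows to keep (default 0.30).
#' @param keep_n optional absolute number of rows, overriding the fraction.
#' @return the filtered matrix (original row order preserved).
#' @export
mad_filter <- function(m, keep_fraction = 0.30, keep_n = NULL) {
  stopifnot(is.matrix(m), !is.null(rownames(m)),
            !anyDuplicated(rownames(m)))
  n_keep <- if (!is.null(keep_n)) keep_n else ceiling(keep_fraction * nrow(m))
  if (nrow(m) < n_keep) stop("fewer rows than requested", call. = FALSE)
  mads <- apply(m, 1, stats::mad)
  ord <- order(-mads, rownames(m))
  keep <- sort(ord[seq_len(n_keep)])
  m[keep, , drop = FALSE]
}

# Hoeffding's D statistic of dependence between two vectors (mid-ranks for
# ties). Vectorized O(n^2); D is 30x the classic integral estimator, as in
# the usual software convention, so independence gives values near 0.
hoeffding_d <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 5, length(y) == n)
  R <- rank(x); S <- rank(y)
  u <- function(v) {
    d <- outer(v, v, "-")          # d[i,j] = v[i] - v[j]
    (d > 0) + 0.5 * (d == 0)
  }
  ux <- u(x); uy <- u(y)
  diag(ux) <- 0; diag(uy) <- 0
  Q <- 1 + rowSums(ux * uy)
  D1 <- sum((Q - 1) * (Q - 2))
  D2 <- sum((R - 1) * (R - 2) * (S - 1) * (S - 2))
  D3 <- sum((R - 2) * (S - 2) * (Q - 1))
  30 * ((n - 2) * (n - 3) * D1 + D2 - 2 * (n - 2) * D3) /
    (n * (n - 1) * (n - 2) * (n - 3) * (n - 4))
}

#' Per-sample outlier scores (distance sum, KS, Hoeffding's D)
#'
#' For each sample: (a) the sum of mean-absolute-difference distances to
#' the other samples; (b) the Kolmogorov-Smirnov statistic between the
#' sample's value distribution and the pooled distribution of the others;
#' (c) Hoeffding's D between the MA-coordinates (mean vs difference) of the
#' sample against the row-median pseudo-reference. A sample is flagged on a
#' metric when its score exceeds Q3 + `fence` * IQR of the cohort's scores;
#' the default far-out fence of 3 keeps homogeneous cohorts essentially
#' free of spurious removals (the three metrics are correlated, so the
#' ordinary 1.5 fence combined with the 2-of-3 removal clause would shed
#' samples from a third of perfectly clean cohorts) while a grossly shifted
#' sample still exceeds it several-fold. Matrices larger than `max_rows`
#' rows are thinned deterministically (evenly spaced rows) for the D
#' statistic.
#'
#' @param m numeric matrix (log-scale values recommended), >= 4 samples.
#' @param max_rows row budget for the Hoeffding statistic.
#' @param fence IQR multiplier of the flagging fence (default 3).
#' @return data.frame: sample, dist_sum, ks, hoeffd and the three flags.
#' @export
outlier_scores <- function(m, max_rows = 1000, fence = 3) {
  stopifnot(is.matrix(m))
  n <- ncol(m)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  D <- as.matrix(stats::dist(t(m), method = "manhattan")) / nrow(m)
  dist_sum <- rowSums(D)
  ks <- vapply(seq_len(n), function(j) {
    unname(suppressWarnings(
      stats::ks.test(m[, j], as.vector(m[, -j]))$statistic))
  }, numeric(1))
  ridx <- if (nrow(m) > max_rows) {
    unique(round(seq(1, nrow(m), length.out = max_rows)))
  } else seq_len(nrow(m))
  ref <- apply(m[ridx, , drop = FALSE], 1, stats::median)
  hoeffd <- vapply(seq_len(n), function(j) {
    x <- m[ridx, j]
    hoeffding_d((x + ref) / 2, x - ref)
  }, numeric(1))
  flag <- function(s) {
    q <- stats::quantile(s, c(0.25, 0.75), names = FALSE)
    s > q[2] + fence * (q[2] - q[1])
  }
  data.frame(sample = colnames(m), dist_sum = dist_sum, ks = ks,
             hoeffd = hoeffd,
             flag_dist = flag(dist_sum), flag_ks = flag(ks),
             flag_hoeffd = flag(hoeffd),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Outlier triage across pre- and post-normalization scores
#'
#' A sample is removed if it was flagged by any metric both before and
#' after normalization, or if at least two metrics flag it after
#' normalization.
#'
#' @param m_before,m_after matrices before/after normalization (same
#'   samples; log scale recommended).
#' @param max_rows,fence see [outlier_scores()].
#' @return data.frame joining both score sets plus the removal `verdict`.
#' @export
outlier_flag <- function(m_before, m_after = m_before, max_rows = 1000,
                         fence = 3) {
  before <- outlier_scores(m_before, max_rows = max_rows, fence = fence)
  after <- outlier_scores(m_after, max_rows = max_rows, fence = fence)
  stopifnot(identical(before$sample, after$sample))
  any_before <- before$flag_dist | before$flag_ks | before$flag_hoeffd
  any_after <- after$flag_dist | after$flag_ks | after$flag_hoeffd
  n_after <- after$flag_dist + after$flag_ks + after$flag_hoeffd
  out <- data.frame(sample = before$sample,
                    before[, -1], after = after[, -1],
                    stringsAsFactors = FALSE)
  out$verdict <- (any_before & any_after) | (n_after >= 2)
  out
}

#' Batch centering by per-gene median log-ratios
#'
#' A light-weight batch adjustment: on the log2(count + 0.5) scale, each
#' batch's per-gene median is shifted onto the per-gene grand median, then
#' values are transformed back and re-rounded to non-negative integers.
#' Singleton batches are passed through with a warning.
#'
#' @param m transcripts x samples integer count matrix.
#' @param batch batch label per sample.
#' @return adjusted integer matrix of the same shape.
#' @export
batch_adjust <- function(m, batch) {
  stopifnot(is.matrix(m), length(batch) == ncol(m))
  batch <- as.character(batch)
  if (length(unique(batch)) < 2) stop("need >= 2 batches", call. = FALSE)
  L <- log2(m + 0.5)
  grand <- apply(L, 1, stats::median)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    if (length(idx) < 2) {
      warning("singleton batch '", b, "' passed through unadjusted",
              call. = FALSE)
      next
    }
    delta <- apply(L[, idx, drop = FALSE], 1, stats::median) - grand
    L[, idx] <- L[, idx] - delta
  }
  out <- round_half_away(2^L - 0.5)
  out[out < 0] <- 0
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(m)
  out
}

#' Log counts-per-million transform
#'
#' `log2((count + prior) / eff_lib_size * 1e6)` with the TMM effective
#' library size per sample; a monotone variance-flattening transform used
#' as the working scale for filtering and network construction.
#'
#' @param m count matrix.
#' @param factors output of [tmm_factors()] (or a numeric vector of
#'   effective library sizes per sample).
#' @param prior prior count added to the numerator (default 0.5).
#' @return transformed real matrix.
#' @export
log_cpm <- function(m, factors = tmm_factors(m), prior = 0.5) {
  eff <- if (is.data.frame(factors)) factors$eff_lib_size else factors
  stopifnot(length(eff) == ncol(m), all(eff > 0))
  log2(sweep(m + prior, 2, eff, "/") * 1e6)
}
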