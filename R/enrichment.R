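# Gene-set analysis: hypergeometric over-representation with term-size
# filters, and running-sum enrichment on a ranked list with a gene-label
# permutation null (exhaustive enumeration for small problems).

#' Read a GMT gene-set file
#'
#' Lines are `name<TAB>description<TAB>member...`. Duplicate members within
#' a set are removed (with a message); lines with fewer than 3 fields raise
#' an error naming the line; sets whose member fields are all empty are
#' dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of member character vectors, with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); descs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop("malformed GMT line ", i, ": expected name, description and at",
           " least one member", call. = FALSE)
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("GMT line ", i, " ('", f[1], "') has no members; dropped",
              call. = FALSE)
      next
    }
    if (anyDuplicated(members)) {
      message("read_gmt: removed ", sum(duplicated(members)),
              " duplicate member(s) in set '", f[1], "'")
      members <- unique(members)
    }
    if (f[1] %in% names(sets)) {
      stop("duplicate set name '", f[1], "' at line ", i, call. = FALSE)
    }
    sets[[f[1]]] <- members
    descs[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of member vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Sets are intersected with the background and filtered to sizes in
#' `[min_size, max_size]`; the upper-tail hypergeometric p-value tests the
#' query/set overlap, with Benjamini-Hochberg adjustment across the tested
#' sets.
#'
#' @param query character vector of genes of interest (subset of
#'   `background`).
#' @param sets named list of gene sets.
#' @param background character vector of all testable genes.
#' @param min_size,max_size term-size filter (defaults 10 and 500).
#' @return data.frame: set, set_size, overlap, p, p_adj.
#' @export
ora <- function(query, sets, background, min_size = 10, max_size = 500) {
  bad <- setdiff(query, background)
  if (length(bad)) {
    stop("query gene(s) not in background: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) ", ..." else "", call. = FALSE)
  }
  query <- unique(query)
  background <- unique(background)
  sets_bg <- lapply(sets, intersect, background)
  sizes <- lengths(sets_bg)
  keep <- sizes >= min_size & sizes <= max_size
  sets_bg <- sets_bg[keep]
  if (!length(sets_bg)) {
    return(data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0),
                      p_adj = numeric(0)))
  }
  N <- length(background); K <- length(query)
  p <- vapply(sets_bg, function(s) {
    ov <- length(intersect(s, query))
    stats::phyper(ov - 1, length(s), N - length(s), K, lower.tail = FALSE)
  }, numeric(1))
  overlap <- vapply(sets_bg, function(s) length(intersect(s, query)),
                    integer(1))
  out <- data.frame(set = names(sets_bg), set_size = lengths(sets_bg),
                    overlap = overlap, p = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), ]
}

# Running-sum enrichment score for hit positions in a ranked stat vector.
# Hit increments are proportional to |stat|^weight, miss decrements
# uniform; the ES is the running sum's extremum (largest absolute
# deviation).
gsea_es <- function(stat_sorted, hit_idx, weight = 1) {
  n <- length(stat_sorted)
  k <- length(hit_idx)
  delta <- rep(-1 / (n - k), n)
  w <- abs(stat_sorted[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, k)
  delta[hit_idx] <- w / sum(w)
  cs <- cumsum(delta)
  # earliest extremum wins when |cs| ties (up to rounding noise)
  i <- which.max(round(abs(cs), 10))
  list(es = cs[i], extremum = i, running = cs)
}

#' Running-sum gene-set enrichment on a ranked list
#'
#' The ranked list is sorted by decreasing statistic; each set's enrichment
#' score (ES) is the extremum of the classic weighted running sum. The
#' permutation p-value compares the observed ES against ESs of random
#' placements of the set's size in the ranking (gene-label permutation),
#' one-sided in the sign of the observed ES. When the number of possible
#' placements is within `n_perm`, all of them are enumerated exactly;
#' otherwise `n_perm` seeded draws give `p = (1 + #extreme) / (n_perm + 1)`.
#' The leading edge contains the hit genes at or before (after, for
#' negative ES) the running-sum extremum.
#'
#' @param stats named numeric vector (gene-level statistics; unique names).
#' @param sets named list of gene sets.
#' @param n_perm permutation budget (default 10000).
#' @param seed optional seed for the Monte-Carlo path.
#' @param weight hit-increment exponent on |stat| (default 1; 0 = classic
#'   Kolmogorov-Smirnov-style unweighted).
#' @param min_overlap sets overlapping the ranking in fewer genes are
#'   skipped with a message (default 2).
#' @return data.frame: set, size, es, nes, p, n_perm_used, exhaustive,
#'   leading_edge (semicolon-joined).
#' @export
gsea <- function(stats, sets, n_perm = 10000, seed = NULL, weight = 1,
                 min_overlap = 2) {
  if (is.null(names(stats)) || anyDuplicated(names(stats))) {
    stop("stats must be uniquely named by gene", call. = FALSE)
  }
  ord <- order(stats, names(stats), decreasing = TRUE)
  s <- stats[ord]
  genes <- names(s)
  n <- length(s)
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); ledges <- list()
  for (nm in names(sets)) {
    hits <- which(genes %in% sets[[nm]])
    k <- length(hits)
    if (k < min_overlap || k >= n) {
      message("gsea: skipping set '", nm, "' (overlap ", k, ")")
      next
    }
    obs <- gsea_es(s, hits, weight)
    total <- choose(n, k)
    exhaustive <- is.finite(total) && total <= n_perm
    perm_es <- if (exhaustive) {
      apply(utils::combn(n, k), 2, function(idx) gsea_es(s, idx, weight)$es)
    } else {
      vapply(seq_len(n_perm), function(i) {
        gsea_es(s, sort(sample.int(n, k)), weight)$es
      }, numeric(1))
    }
    # tolerance so placements tying the observed ES (up to rounding) count
    extreme <- if (obs$es >= 0) perm_es >= obs$es - 1e-12 else
      perm_es <= obs$es + 1e-12
    p <- if (exhaustive) mean(extreme) else
      (1 + sum(extreme)) / (n_perm + 1)
    same_sign <- perm_es[sign(perm_es) == sign(obs$es)]
    nes <- if (length(same_sign)) obs$es / mean(abs(same_sign)) else NA_real_
    ledge <- if (obs$es >= 0) genes[hits[hits <= obs$extremum]] else
      genes[hits[hits >= obs$extremum]]
    rows[[nm]] <- data.frame(
      set = nm, size = k, es = obs$es, nes = nes, p = p,
      n_perm_used = if (exhaustive) total else n_perm,
      exhaustive = exhaustive,
      leading_edge = paste(ledge, collapse = ";"),
      stringsAsFactors = FALSE)
    ledges[[nm]] <- ledge
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "leading_edges") <- ledges
  out
}
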