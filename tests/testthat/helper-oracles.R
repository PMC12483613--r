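# Independent brute-force oracles used to verify the implementations, plus
# small fixture builders. These deliberately avoid the package's code paths.

# Freeman-Halton / Fisher exact p by exhaustive enumeration of all tables
# with the observed margins (sum of probabilities no larger than the
# observed one, with the customary 1e-7 relative slack).
enum_fisher_p <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab)
  r <- length(rs); c <- length(cs)
  log_prob <- function(m) sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(m)) - sum(lfactorial(m))
  obs <- log_prob(tab)
  total <- 0
  rec <- function(m, i, crem) {
    if (i == r) {
      m[r, ] <- crem
      lp <- log_prob(m)
      if (lp <= obs + 1e-7) total <<- total + exp(lp)
      return(invisible())
    }
    fill <- function(m, j, rowrem, crem) {
      if (j == c) {
        if (rowrem <= crem[c]) {
          m[i, c] <- rowrem
          crem[c] <- crem[c] - rowrem
          rec(m, i + 1, crem)
        }
        return(invisible())
      }
      later <- sum(crem[(j + 1):c])
      lo <- max(0, rowrem - later)
      hi <- min(rowrem, crem[j])
      if (lo > hi) return(invisible())
      for (v in lo:hi) {
        m[i, j] <- v
        cc <- crem; cc[j] <- cc[j] - v
        fill(m, j + 1, rowrem - v, cc)
      }
    }
    fill(m, 1, rs[i], crem)
  }
  rec(matrix(0, r, c), 1, cs)
  total
}

# Scalar triple-loop topological overlap.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- numeric(n)
  for (i in 1:n) k[i] <- sum(a[i, -i])
  out <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { out[i, j] <- 1; next }
    l <- 0
    for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    out[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

# Mid-ranks computed from scratch, then the Pearson formula by hand.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    out <- numeric(length(v))
    for (i in seq_along(v)) {
      out[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    out
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hypergeometric upper tail by direct summation of choose() terms.
oracle_hyper_upper <- function(overlap, set_size, bg_size, query_size) {
  i <- overlap:min(set_size, query_size)
  sum(choose(set_size, i) * choose(bg_size - set_size, query_size - i)) /
    choose(bg_size, query_size)
}

# Running-sum ES written independently (explicit loop over ranks).
oracle_es <- function(stat_sorted, hit_idx, weight = 1) {
  n <- length(stat_sorted); k <- length(hit_idx)
  w <- abs(stat_sorted[hit_idx])^weight
  if (sum(w) == 0) w <- rep(1, k)
  nr <- sum(w)
  run <- 0; best <- 0
  wi <- 1
  hit_set <- logical(n); hit_set[hit_idx] <- TRUE
  w_by_pos <- numeric(n); w_by_pos[hit_idx] <- w
  for (i in 1:n) {
    run <- run + if (hit_set[i]) w_by_pos[i] / nr else -1 / (n - k)
    if (abs(run) > abs(best) + 1e-10) best <- run
  }
  best
}

# Exhaustive permutation p over all placements of k hits among n ranks.
oracle_gsea_p <- function(stat_sorted, hit_idx, weight = 1) {
  n <- length(stat_sorted); k <- length(hit_idx)
  obs <- oracle_es(stat_sorted, hit_idx, weight)
  all_es <- apply(utils::combn(n, k), 2, function(idx)
    oracle_es(stat_sorted, idx, weight))
  if (obs >= 0) mean(all_es >= obs - 1e-12) else mean(all_es <= obs + 1e-12)
}

# Straight-line reimplementation of the phenotyping rules from raw grids.
oracle_phenotype <- function(grids, thr = 0.3, min_days = 4) {
  sdv <- function(v) sqrt(sum((v - mean(v))^2) / (length(v) - 1))
  med <- function(v) {
    v <- sort(v); n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  vars <- c(); means <- c(); labs <- c()
  for (pid in names(grids)) {
    g <- grids[[pid]]
    dsds <- c()
    for (d in seq_len(nrow(g))) {
      v <- g[d, !is.na(g[d, ])]
      if (length(v) >= 2) dsds <- c(dsds, sdv(v))
    }
    if (!length(dsds)) { labs[pid] <- "unclassifiable"; next }
    vars[pid] <- mean(dsds)
    means[pid] <- mean(g[!is.na(g)])
  }
  cl <- names(vars)
  vmed <- med(vars)
  low <- cl[vars[cl] <= vmed]
  high <- setdiff(cl, low)
  imed <- med(means[low])
  for (pid in low) {
    labs[pid] <- if (means[pid] <= imed) "constant_low" else "constant_high"
  }
  for (pid in high) {
    g <- grids[[pid]]; ninc <- 0; ndec <- 0
    for (d in seq_len(nrow(g))) {
      a <- g[d, 1]; b <- g[d, ncol(g)]
      if (is.na(a) || is.na(b)) next
      if (a == 0) {
        if (b > 0) ninc <- ninc + 1
      } else {
        rel <- (b - a) / a
        if (rel >= thr) ninc <- ninc + 1
        if (rel <= -thr) ndec <- ndec + 1
      }
    }
    labs[pid] <- if (ninc >= min_days) "rhythmic_up"
                 else if (ndec >= min_days) "rhythmic_down" else "mixed"
  }
  labs
}

# Long diary rows (exact prompt times) from a list of 7x3 grids.
grids_to_diary <- function(grids, scale = "pain",
                           start = as.POSIXct("2019-01-07 00:00:00",
                                              tz = "UTC")) {
  slot_hours <- c(8, 14, 20)
  rows <- list()
  for (pid in names(grids)) {
    g <- grids[[pid]]
    for (d in seq_len(nrow(g))) for (s in 1:3) {
      if (is.na(g[d, s])) next
      ts <- start + (d - 1) * 86400 + slot_hours[s] * 3600
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = pid,
        timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
        scale = scale, score = g[d, s], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random integer grid with missingness; guarantees >= 1 evaluable day and
# an entry on day 1 (so the grid's day indexing is unambiguous).
random_grid <- function(missing_rate = 0.15) {
  repeat {
    g <- matrix(sample(0:10, 21, replace = TRUE), 7, 3)
    g[matrix(stats::runif(21) < missing_rate, 7, 3)] <- NA
    if (any(rowSums(!is.na(g)) >= 2) && !all(is.na(g[1, ]))) return(g)
  }
}
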