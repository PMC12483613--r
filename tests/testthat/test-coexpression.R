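# Signed adjacency, TOM, module detection, eigengenes, merging and
# module-trait association.

# two tight planted blocks plus background noise genes
blocky_expr <- function(n_block = 25, n_noise = 30, n_samples = 20,
                        seed = 1, within = 0.9) {
  set.seed(seed)
  z1 <- rnorm(n_samples); z2 <- rnorm(n_samples)
  lam <- sqrt(within)
  g1 <- t(sapply(1:n_block, function(i)
    lam * z1 + sqrt(1 - within) * rnorm(n_samples)))
  g2 <- t(sapply(1:n_block, function(i)
    lam * z2 + sqrt(1 - within) * rnorm(n_samples)))
  noise <- matrix(rnorm(n_noise * n_samples), n_noise)
  m <- rbind(g1, g2, noise)
  rownames(m) <- sprintf("T%03d", seq_len(nrow(m)))
  m
}

test_that("signed adjacency endpoints and contract", {
  m <- blocky_expr(seed = 2)
  a <- signed_adjacency(m, 12)
  expect_true(isSymmetric(a))
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(unname(diag(a)), rep(1, nrow(a)))
  x <- rbind(a1 = 1:10, a2 = 1:10, a3 = 10:1)
  aa <- signed_adjacency(x + matrix(rnorm(30, 0, 1e-9), 3), 12)
  expect_equal(aa[1, 2], 1, tolerance = 1e-5)   # cor  1 -> 1
  expect_equal(aa[1, 3], 0, tolerance = 1e-5)   # cor -1 -> 0
  expect_error(signed_adjacency(rbind(const = rep(1, 10), b = 1:10), 6),
               "const")
  # cor 0 at beta 12 gives 0.5^12
  set.seed(3)
  big <- matrix(rnorm(2 * 5000), 2)
  a0 <- signed_adjacency(big, 12)
  expect_equal(a0[1, 2], 0.5^12, tolerance = 0.5^12)
})

test_that("TOM matches the scalar oracle and its bounds", {
  set.seed(4)
  for (i in 1:25) {
    n <- sample(5:12, 1)
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    got <- tom(a)
    expect_equal(got$tom, oracle_tom(a), tolerance = 1e-12)
    expect_true(all(got$tom >= 0 & got$tom <= 1))
    expect_true(isSymmetric(got$tom))
    expect_true(all(got$dissimilarity >= 0 & got$dissimilarity <= 1))
  }
  expect_error(tom(matrix(c(1, 0.5, 0.2, 1), 2)), "symmetric")
})

test_that("a scale-free construction reaches the R-squared target and the
          smallest qualifying power is chosen", {
  set.seed(1)
  n_samp <- 40
  # module sizes follow a discrete power law n(s) ~ s^-2, so connectivity
  # is approximately scale-free
  sizes <- rep(c(2, 3, 4, 5, 6, 8, 10, 14, 20, 30, 45),
               times = c(60, 30, 16, 10, 8, 5, 3, 2, 1, 1, 1))
  rows <- lapply(sizes, function(s) {
    z <- rnorm(n_samp)
    t(sapply(seq_len(s), function(i)
      sqrt(0.9) * z + sqrt(0.1) * rnorm(n_samp)))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sprintf("T%04d", seq_len(nrow(m)))
  pk <- pick_soft_threshold(m)
  chosen <- pk$fit_table[pk$fit_table$power == pk$power, ]
  expect_gte(chosen$rsq_signed, 0.80)
  earlier <- pk$fit_table[pk$fit_table$power < pk$power, ]
  expect_true(all(earlier$rsq_signed < 0.80, na.rm = TRUE))
})

test_that("soft-threshold fit table is monotone in mean connectivity", {
  m <- blocky_expr(n_block = 30, n_noise = 40, seed = 5)
  pk <- pick_soft_threshold(m, powers = 1:12)
  expect_true(all(diff(pk$fit_table$mean_k) < 0))
  pk2 <- pick_soft_threshold(m, powers = 1:12)
  expect_identical(pk$power, pk2$power)  # deterministic
})

test_that("module detection recovers two planted blocks", {
  m <- blocky_expr(n_block = 25, n_noise = 30, seed = 6)
  a <- signed_adjacency(m, 6)
  d <- tom(a)$dissimilarity
  labels <- detect_modules(d, min_size = 10)
  non_grey <- setdiff(unique(labels), "grey")
  expect_equal(length(non_grey), 2)
  b1 <- labels[1:25]; b2 <- labels[26:50]
  expect_equal(length(unique(b1)), 1)
  expect_equal(length(unique(b2)), 1)
  expect_false(unique(b1) == unique(b2))
  # min_size above every block: everything grey
  expect_warning(all_grey <- detect_modules(d, min_size = 60), "grey")
  expect_true(all(all_grey == "grey"))
})

test_that("module labels are invariant to transcript order", {
  m <- blocky_expr(n_block = 20, n_noise = 20, seed = 7)
  d <- tom(signed_adjacency(m, 6))$dissimilarity
  l1 <- detect_modules(d, min_size = 8)
  set.seed(8); perm <- sample(nrow(m))
  d2 <- d[perm, perm]
  l2 <- detect_modules(d2, min_size = 8)
  expect_identical(l1[names(l2)], l2)
})

test_that("eigengenes: identical, orthogonal and SVD-oracle cases", {
  prof <- sin(1:12)
  m <- rbind(a = prof, b = prof, c = prof)
  eg <- eigengenes(m, rep("M1", 3))
  expect_equal(unname(eg$var_explained["M1"]), 1)
  z <- scale(prof)[, 1]
  expect_equal(abs(cor(eg$eigengenes[, "M1"], z)), 1, tolerance = 1e-10)
  expect_gt(cor(eg$eigengenes[, "M1"], z), 0)  # sign anchored to profile
  # two orthogonal members split the variance evenly (centered first so
  # row standardization preserves orthogonality)
  set.seed(9)
  x <- rnorm(50); y <- rnorm(50)
  x <- x - mean(x); y <- y - mean(y)
  y <- y - x * sum(x * y) / sum(x * x)
  eg2 <- eigengenes(rbind(a = x, b = y), rep("M1", 2))
  expect_equal(unname(eg2$var_explained["M1"]), 0.5, tolerance = 1e-10)
  # random module: matches direct SVD up to sign; unit norm
  m3 <- matrix(rnorm(8 * 15), 8, dimnames = list(paste0("g", 1:8), NULL))
  eg3 <- eigengenes(m3, rep("M1", 8))
  v <- eg3$eigengenes[, 1]
  expect_equal(sum(v^2), 1, tolerance = 1e-10)
  sv <- svd(t(scale(t(m3))))
  expect_equal(abs(cor(v, sv$v[, 1])), 1, tolerance = 1e-10)
})

test_that("merging terminates with all eigengene correlations below the
          threshold", {
  set.seed(10)
  z <- rnorm(30)
  m <- rbind(
    t(sapply(1:10, function(i) z + rnorm(30, 0, 0.3))),
    t(sapply(1:10, function(i) z + rnorm(30, 0, 0.3))),
    t(sapply(1:10, function(i) rnorm(30))))
  rownames(m) <- sprintf("T%02d", 1:30)
  labels <- rep(c("M1", "M2", "M3"), each = 10)
  names(labels) <- rownames(m)
  merged <- merge_modules(m, labels, threshold = 0.30)
  expect_lt(length(unique(merged$labels)), 3)   # the twin modules merged
  if (ncol(merged$eigengenes) > 1) {
    C <- abs(cor(merged$eigengenes))
    expect_true(all(C[upper.tri(C)] < 0.30))
  }
  # below-threshold modules are a fixed point
  set.seed(11)
  m2 <- matrix(rnorm(20 * 40), 20,
               dimnames = list(sprintf("U%02d", 1:20), NULL))
  lab2 <- setNames(rep(c("M1", "M2"), each = 10), rownames(m2))
  eg <- eigengenes(m2, lab2)
  if (abs(cor(eg$eigengenes)[1, 2]) < 0.30) {
    merged2 <- merge_modules(m2, lab2, threshold = 0.30)
    expect_identical(merged2$labels, lab2)
  }
})

test_that("module-trait association: null shuffle is calibrated and a
          constant eigengene is flagged", {
  set.seed(12)
  pvals <- replicate(100, {
    eg <- matrix(rnorm(40), 40, 1, dimnames = list(NULL, "M1"))
    ph <- sample(rep(c("rhythmic_up", "mixed"), each = 20))
    module_trait(eg, ph, mode = "binary")$p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  egc <- matrix(1, 10, 1, dimnames = list(NULL, "M1"))
  mt <- module_trait(egc, rep(c("rhythmic_up", "mixed"), 5))
  expect_true(mt$degenerate[1])
  expect_error(module_trait(matrix(rnorm(10), 10, 1), rep("a", 10)),
               "single level")
})

test_that("multinomial module-trait mode returns one row per level", {
  set.seed(13)
  eg <- matrix(rnorm(60), 60, 2, dimnames = list(NULL, c("M1", "M2")))
  ph <- sample(c("rhythmic_up", "mixed", "constant_low"), 60, TRUE)
  mt <- module_trait(eg, ph, mode = "multinomial")
  expect_equal(nrow(mt), 2 * 2)
  expect_setequal(unique(mt$level), c("mixed", "constant_low"))
})
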