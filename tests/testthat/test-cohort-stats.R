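# Multinomial ORs, exact contingency tests, rank tests, correlations,
# percent change and ddCt fold changes.

test_that("balanced binary covariate gives OR exactly 1", {
  d <- data.frame(phenotype = rep(c("rhythmic_up", "mixed"), each = 30),
                  x = rep(c(0, 1), 30))
  o <- fit_multinomial_or(d, "x")
  expect_lt(abs(o$or - 1), 1e-6)
  expect_false(o$separation)
})

test_that("multinomial betas are recovered within 2 SE most of the time", {
  hits <- 0; reps <- 40
  for (i in seq_len(reps)) {
    set.seed(300 + i)
    n <- 150
    x <- stats::rnorm(n)
    lp <- 0.8 * x           # log-odds of "mixed" vs reference
    ph <- ifelse(stats::runif(n) < stats::plogis(lp), "mixed",
                 "rhythmic_up")
    if (length(unique(ph)) < 2) next
    o <- fit_multinomial_or(data.frame(phenotype = ph, x = x), "x")
    hits <- hits + (abs(o$beta - 0.8) <= 2 * o$se)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("opioid-style quasi-separation raises the flag", {
  set.seed(2)
  d <- data.frame(
    phenotype = rep(c("rhythmic_up", "mixed", "constant_high"), each = 20),
    op = c(rep(FALSE, 20), stats::runif(40) < 0.45))
  o <- fit_multinomial_or(d, "op")
  expect_true(all(o$separation))
  expect_true(all(is.finite(o$or)))
})

test_that("inverting a binary covariate inverts the OR", {
  set.seed(5)
  d <- data.frame(phenotype = rep(c("rhythmic_up", "mixed"), each = 25),
                  x = stats::runif(50) < 0.5)
  a <- fit_multinomial_or(d, "x")
  d$x <- !d$x
  b <- fit_multinomial_or(d, "x")
  expect_equal(a$or * b$or, 1, tolerance = 1e-5)
})

test_that("singular designs error naming the collinear column", {
  d <- data.frame(phenotype = rep(c("rhythmic_up", "mixed"), each = 10),
                  x = 1:20, y = 2 * (1:20))
  expect_error(fit_multinomial_or(d, c("x", "y")), "y")
})

test_that("fisher_exact handles balance, validation and the r x c case", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1.0)
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisher_exact(matrix(1:3, 3, 1)), "2x2")
  # row/column permutation invariance
  set.seed(8)
  tab <- matrix(rpois(12, 4), 3, 4)
  p1 <- fisher_exact(tab)$p
  p2 <- fisher_exact(tab[c(2, 3, 1), c(4, 1, 3, 2)])$p
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("fisher_exact matches exhaustive enumeration on small tables", {
  set.seed(31)
  done <- 0
  while (done < 40) {
    tab <- matrix(rpois(6, 3), 2, 3)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    done <- done + 1
    expect_equal(fisher_exact(tab)$p, enum_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("group comparisons handle degeneracy and match identities", {
  g <- rep(c("a", "b"), each = 5)
  r <- group_compare(rep(3, 10), g, mode = "kruskal")
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  expect_error(group_compare(1:5, factor(rep("a", 5),
                                         levels = c("a", "b"))), "b")
  # two-group ANOVA F equals squared pooled t
  set.seed(4)
  x <- stats::rnorm(10)
  a <- group_compare(x, g, mode = "anova_tukey")
  t2 <- stats::t.test(x ~ g, var.equal = TRUE)$statistic^2
  expect_equal(a$statistic, unname(t2), tolerance = 1e-10)
  expect_equal(nrow(a$pairwise), 1)
})

test_that("kruskal statistic matches the rank-formula oracle", {
  set.seed(10)
  for (i in 1:20) {
    x <- sample(1:8, 30, replace = TRUE)  # plenty of ties
    g <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
    if (any(table(g) == 0)) next
    r <- group_compare(x, g, mode = "kruskal")
    n <- length(x); rk <- rank(x)
    h <- (12 / (n * (n + 1))) *
      sum(tapply(rk, g, function(v) length(v) * (mean(v) - (n + 1) / 2)^2))
    ties <- table(rk)
    h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
    expect_equal(r$statistic, h, tolerance = 1e-10)
  }
})

test_that("spearman handles monotone, reversed and tied inputs", {
  x <- 1:10
  expect_equal(spearman_cor(x, x^3)$estimate, 1)
  expect_equal(spearman_cor(x, rev(x))$estimate, -1)
  expect_true(spearman_cor(rep(1, 5), 1:5)$degenerate)
  set.seed(12)
  for (i in 1:30) {
    a <- sample(1:6, 15, replace = TRUE)
    b <- sample(1:6, 15, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(spearman_cor(a, b)$estimate, oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("percent change and ddCt fold change follow their formulas", {
  expect_equal(pct_change(4, 5), 25)
  expect_equal(pct_change(6, 6), 0)
  expect_error(pct_change(0, 5), "undefined")
  set.seed(3)
  d <- stats::runif(20, 1, 9); n <- stats::runif(20, 1, 9)
  expect_equal(pct_change(d, n), 100 * (n - d) / d)
  expect_equal(ddct_fold_change(5, 5, 7, 7), 1)
  expect_equal(ddct_fold_change(6, 5, 5, 5), 0.5)
  expect_equal(ddct_fold_change(3, 5, 5, 5), 4)
})
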