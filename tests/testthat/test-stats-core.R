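# Statistical primitives against brute-force and reference oracles.

test_that("exact Mann-Whitney matches full enumeration on small groups", {
  expect_equal(mw_test(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  set.seed(101)
  for (i in 1:40) {
    n <- sample(2:7, 1); m <- sample(2:7, 1)
    x <- rnorm(n); y <- rnorm(m)
    for (alt in c("two.sided", "greater", "less")) {
      expect_equal(mw_test(x, y, alternative = alt)$p_value,
                   enumerate_mw_p(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("exact Mann-Whitney agrees with the reference implementation", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(sample(3:20, 1)); y <- rnorm(sample(3:20, 1))
    expect_equal(mw_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("tied or large samples use the corrected normal approximation", {
  res <- mw_test(rep(5, 4), rep(5, 4))
  expect_equal(res$p_value, 1)
  expect_identical(res$method, "approx")
  set.seed(8)
  for (i in 1:15) {
    x <- sample(1:6, 30, replace = TRUE)
    y <- sample(2:7, 35, replace = TRUE)
    expect_equal(mw_test(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
                 tolerance = 1e-10)
  }
  expect_warning(mw_test(c(1, 1, 2), c(1, 3, 4), exact = TRUE), "ties")
  expect_error(mw_test(numeric(0), 1), "non-empty")
  expect_error(mw_test(c(1, NA), c(2, 3)), "missing")
})

test_that("BH adjustment matches the sort-based oracle and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1), 1)
  set.seed(21)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p & q <= 1))
    # re-adjusting never shrinks a q-value
    expect_true(all(bh_adjust(q) >= q - 1e-12))
  }
  # flat adjusted vectors (step-up minimum at the last element) are fixed
  # points of the adjustment
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("spearman_rho handles ties, missing pairs and degeneracy", {
  expect_equal(spearman_rho(1:3, 3:1), -1)
  expect_equal(spearman_rho(1:4, c(2, 4, 6, 8)), 1)
  expect_equal(spearman_rho(c(1, 1, 2), c(1, 2, 3)),
               spearman_oracle(c(1, 1, 2), c(1, 2, 3)))
  set.seed(31)
  for (i in 1:50) {
    x <- sample(1:8, 20, replace = TRUE)
    y <- rnorm(20)
    x[sample(20, 4)] <- NA
    expect_equal(spearman_rho(x, y), spearman_oracle(x, y), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y),
                 suppressWarnings(
                   stats::cor(x, y, method = "spearman",
                              use = "pairwise.complete.obs")),
                 tolerance = 1e-12)
  }
  expect_true(is.na(spearman_rho(c(1, 2, NA), c(NA, 1, 2))))  # < 3 pairs
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))            # constant
})

test_that("fisher_exact_p matches enumeration and the reference", {
  expect_equal(fisher_exact_p(matrix(c(5, 0, 0, 5), 2, 2)), 1 / 252)
  expect_equal(fisher_exact_p(matrix(c(1, 1, 1, 1), 2, 2)), 5 / 6)
  expect_equal(fisher_exact_p(matrix(c(0, 3, 0, 4), 2, 2)), 1)  # zero margin
  set.seed(41)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 6), 2, 2)
    expect_equal(fisher_exact_p(tab, "greater"),
                 hyper_tail_oracle(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    for (alt in c("greater", "less", "two.sided")) {
      expect_equal(fisher_exact_p(tab, alt),
                   stats::fisher.test(tab, alternative = alt)$p.value,
                   tolerance = 1e-9)
    }
  }
  expect_error(fisher_exact_p(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})

test_that("binomial_test_p is exact under all alternatives", {
  expect_identical(binomial_test_p(9, 10, 0.5), 22 / 1024)
  expect_equal(binomial_test_p(10, 10, 0.5, "greater"), 0.5^10)
  expect_equal(binomial_test_p(5, 10, 0.5), 1)
  set.seed(51)
  for (i in 1:50) {
    n <- sample(1:60, 1); k <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    for (alt in c("two.sided", "greater", "less")) {
      ref_alt <- c(two.sided = "two.sided", greater = "greater", less = "less")[alt]
      expect_equal(binomial_test_p(k, n, p0, alt),
                   stats::binom.test(k, n, p0, alternative = ref_alt)$p.value,
                   tolerance = 1e-12)
    }
  }
  # symmetric null: two-sided equals doubled one-sided, capped at 1
  for (k in 0:10) {
    expect_equal(binomial_test_p(k, 10, 0.5),
                 min(1, 2 * min(binomial_test_p(k, 10, 0.5, "greater"),
                                binomial_test_p(k, 10, 0.5, "less"))),
                 tolerance = 1e-12)
  }
  expect_error(binomial_test_p(11, 10), "0 <= k <= n")
})

test_that("hypergeometric ORA reduces to Fisher on the induced table", {
  universe <- paste0("g", 1:10)
  expect_equal(hypergeom_ora(universe[1:5], universe[1:5], universe), 1 / 252)
  set.seed(61)
  for (i in 1:30) {
    universe <- paste0("g", 1:40)
    q <- sample(universe, sample(3:15, 1))
    a <- sample(universe, sample(3:15, 1))
    k <- length(intersect(q, a))
    tab <- matrix(c(k, length(q) - k, length(a) - k,
                    40 - length(q) - length(a) + k), 2)
    expect_equal(hypergeom_ora(q, a, universe, "greater"),
                 fisher_exact_p(tab, "greater"), tolerance = 1e-12)
  }
  expect_error(hypergeom_ora("zz", universe, universe), "contained")
})

test_that("ORA over a named list adds Bonferroni step-down", {
  universe <- paste0("g", 1:30)
  sets <- list(hit = universe[1:8], null = universe[21:28])
  res <- hypergeom_ora(universe[1:8], sets, universe)
  expect_s3_class(res, "tbl_df")
  expect_equal(res$overlap, c(8L, 0L))
  expect_true(all(res$p_holm >= res$p_value))
})
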