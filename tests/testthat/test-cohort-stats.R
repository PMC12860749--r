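test_that("spearman handles perfect monotone links and degenerate input", {
  expect_equal(spearman(c(1, 2, 3), c(10, 20, 30))$estimate, 1.0)
  expect_equal(spearman(c(1, 2, 3), c(30, 20, 10))$estimate, -1.0)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman(c(1, 2), c(1, 2)), "at least 3")
  # pairwise deletion reports the n actually used
  r <- spearman(c(1, 2, 3, NA, 5), c(2, 4, 6, 8, NA))
  expect_identical(r$n, 3L)
})

test_that("rank-sum test matches exact enumeration on small samples", {
  # (1,2,3) vs (101,102,103): most extreme of the 20 assignments -> p = 0.1
  res <- two_group_compare(c(1, 2, 3, 101, 102, 103),
                           rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value,
               oracle_ranksum_p(c(1, 2, 3), c(101, 102, 103)))

  # random unique data, n <= 8 per group: exact path equals enumeration
  set.seed(11)
  for (i in 1:5) {
    a <- sample(seq(1, 100), sample(3:6, 1))
    b <- sample(seq(101, 200), sample(3:6, 1)) + 0.5
    got <- two_group_compare(c(a, b),
                             c(rep("a", length(a)), rep("b", length(b))))
    expect_equal(got$p_value, oracle_ranksum_p(a, b), tolerance = 1e-12)
  }

  # identical values in both groups: symmetric ranks, p = 1
  res1 <- two_group_compare(rep(c(5, 6, 7), 2), rep(c("a", "b"), each = 3))
  expect_equal(res1$p_value, 1)
  expect_error(two_group_compare(1:5, rep("a", 5)), "2 groups")
})

test_that("signed-rank test matches exact enumeration and flags degeneracy", {
  # uniform shift: all signs negative, smallest attainable p at n = 20
  before <- seq(10, 200, by = 10)
  after <- before - 10
  res <- paired_compare(before, after)
  expect_equal(res$p_value, 2 / 2^20)

  set.seed(12)
  for (i in 1:5) {
    b <- runif(8, 0, 100)
    a <- b + rnorm(8, 0, 20)
    got <- paired_compare(b, a)
    expect_equal(got$p_value, oracle_signedrank_p(b, a), tolerance = 1e-12)
  }

  expect_error(paired_compare(1:5, 1:5), "degenerate")
  expect_error(paired_compare(1:4, 1:5), "paired")
})

test_that("Kruskal-Wallis matches the textbook formula and the two-group
           rank-sum equivalence", {
  # 9 untied values in 3 groups: H from the hand formula
  vals <- c(1, 5, 9, 2, 6, 10, 3, 7, 11)
  grp <- rep(c("a", "b", "c"), each = 3)
  got <- kruskal_wallis(vals, grp)
  h <- oracle_kruskal_h(vals, grp)
  expect_equal(unname(got$statistic), h, tolerance = 1e-12)
  expect_equal(got$p_value, 1 - pchisq(h, df = 2), tolerance = 1e-12)

  # two groups: chi-square(1) of H equals the two-sided normal rank-sum p
  # (both on their tie-corrected large-sample paths)
  set.seed(13)
  v <- c(rnorm(15), rnorm(15, 1))
  v[2] <- v[1]                                  # tie forces approx path
  g <- rep(c("a", "b"), each = 15)
  expect_equal(kruskal_wallis(v, g)$p_value,
               two_group_compare(v, g)$p_value, tolerance = 1e-10)

  expect_error(kruskal_wallis(1:6, rep("a", 6)), "2 groups")
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)),
               "identical")
})

test_that("chi-square association matches hand computation", {
  # identical row proportions -> statistic 0
  t0 <- matrix(c(10, 20, 5, 10), 2, byrow = TRUE)
  expect_equal(unname(chi_square_association(t0)$statistic), 0,
               tolerance = 1e-12)
  # perfectly diagonal 2x2
  t1 <- matrix(c(10, 0, 0, 10), 2)
  r1 <- chi_square_association(t1)
  expect_equal(unname(r1$statistic), 20)
  expect_equal(unname(r1$statistic), oracle_chisq(t1))
  # degrees of freedom for a 3x4 table
  set.seed(14)
  t2 <- matrix(rpois(12, 20) + 1, 3, 4)
  r2 <- chi_square_association(t2)
  expect_match(r2$note, "df = 6")
  expect_equal(unname(r2$statistic), oracle_chisq(t2), tolerance = 1e-12)
  expect_error(chi_square_association(matrix(c(0, 0, 3, 4), 2)),
               "zero-margin")
})

test_that("Cohen's kappa matches the closed form", {
  # perfect agreement over >= 2 categories
  a <- rep(c("x", "y", "z"), 10)
  expect_equal(cohens_kappa(a, a)$estimate, 1)

  # confusion matrix (45, 15; 25, 15) by its margins
  ra <- c(rep("p", 60), rep("n", 40))
  rb <- c(rep("p", 45), rep("n", 15), rep("p", 25), rep("n", 15))
  tab <- table(factor(ra, c("n", "p")), factor(rb, c("n", "p")))
  got <- cohens_kappa(ra, rb)
  expect_equal(got$estimate, oracle_kappa(tab), tolerance = 1e-12)
  expect_equal(got$estimate, (0.6 - 0.54) / (1 - 0.54), tolerance = 1e-12)

  # independent ratings drift to zero at large n
  set.seed(15)
  x <- sample(c("a", "b"), 4000, replace = TRUE)
  y <- sample(c("a", "b"), 4000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, y)$estimate), 0.06)

  expect_error(cohens_kappa(rep("a", 5), rep("a", 5)), "degenerate")
  expect_error(cohens_kappa(1:3, 1:4), "equal length")
})

test_that("run_panel plumbing: empty specs, dedup, unknown variables", {
  cohort <- data.frame(x = rnorm(20), y = rnorm(20),
                       g = rep(c("a", "b"), 10))
  empty <- data.frame(var1 = character(), var2 = character(),
                      test = character())
  expect_identical(nrow(run_panel(cohort, empty)), 0L)

  dup <- data.frame(var1 = c("x", "x"), var2 = c("y", "y"),
                    test = "spearman", stringsAsFactors = FALSE)
  expect_warning(res <- run_panel(cohort, dup), "duplicate")
  expect_identical(nrow(res), 1L)
  expect_identical(res$test, "spearman")

  bad <- data.frame(var1 = "x", var2 = "nope", test = "spearman")
  expect_error(run_panel(cohort, bad), "unknown cohort variables")

  mix <- data.frame(var1 = c("x", "x"), var2 = c("y", "g"),
                    test = c("spearman", "wilcoxon_rank_sum"))
  res2 <- run_panel(cohort, mix)
  expect_identical(nrow(res2), 2L)
  expect_true(all(res2$p_value >= 0 & res2$p_value <= 1))
})
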