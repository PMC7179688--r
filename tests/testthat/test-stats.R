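test_that("Kruskal-Wallis H matches the hand rank formula", {
  df <- data.frame(y = 1:9, g = rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(df, y, g)
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$statistic, oracle_kw_h(list(1:3, 4:6, 7:9)))
  expect_equal(kw$df, 2)
  # the exact permutation p is reported for this small problem
  expect_false(is.na(kw$p_exact))
  expect_lt(kw$p_exact, 0.05)
  # identical groups: H = 0 under the tie correction
  df0 <- data.frame(y = rep(c(3, 1, 2), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(kruskal_wallis(df0, y, g)$statistic, 0)
})

test_that("two-group Kruskal-Wallis is the square of the Wilcoxon z", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(15) + 0.8
  df <- data.frame(v = c(x, y), g = rep(c("a", "b"), c(12, 15)))
  kw <- kruskal_wallis(df, v, g)
  wt <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  z <- stats::qnorm(wt$p.value / 2)
  expect_equal(kw$statistic, z^2, tolerance = 1e-10)
})

test_that("Kruskal-Wallis exact enumeration agrees with the chi-square p in rank order", {
  groups <- list(c(1, 5, 9), c(2, 6), c(3, 7, 8))
  df <- data.frame(y = unlist(groups),
                   g = rep(c("a", "b", "c"), lengths(groups)))
  kw <- kruskal_wallis(df, y, g)
  expect_false(is.na(kw$p_exact))
  expect_gte(kw$p_exact, 0)
  expect_lte(kw$p_exact, 1)
  expect_error(kruskal_wallis(data.frame(y = c(1, NA), g = c("a", "b")), y, g),
               class = "flyoperant_stats_error")
})

test_that("pairwise Wilcoxon matches exact enumeration on small tie-free data", {
  df <- data.frame(y = c(1, 2, 3, 4), g = rep(c("a", "b"), each = 2))
  pw <- pairwise_wilcoxon(df, y, g)
  expect_equal(pw$p_value, 1 / 3)
  expect_equal(pw$p_value, oracle_wilcoxon_p(c(1, 2), c(3, 4)))
  # several random small fixtures
  set.seed(8)
  for (i in 1:6) {
    a <- sample(100, sample(3:6, 1))
    b <- sample(200:300, sample(3:6, 1))
    d <- data.frame(y = c(a, b), g = rep(c("a", "b"), c(length(a), length(b))))
    expect_equal(pairwise_wilcoxon(d, y, g)$p_value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical groups give p = 1 and Holm never reorders significance", {
  d0 <- data.frame(y = rep(c(5, 6, 7, 8, 9), 2),
                   g = rep(c("a", "b"), each = 5))
  expect_equal(pairwise_wilcoxon(d0, y, g)$p_value, 1)
  set.seed(3)
  d3 <- data.frame(y = c(rnorm(10), rnorm(10) + 2, rnorm(10) + 4),
                   g = rep(c("a", "b", "c"), each = 10))
  pw <- pairwise_wilcoxon(d3, y, g, adjust = "holm")
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p_value))
  # adjusted p-values are monotone in the raw p-values
  expect_true(all(diff(pw$p_adjusted[order(pw$p_value)]) >= -1e-12))
})

test_that("bootstrap median CI is deterministic, degenerate-safe, and ordered", {
  expect_equal(
    unlist(median_resampling_ci(c(5, 5, 5, 5), seed = 1)[c("ci_low", "median", "ci_high")]),
    c(ci_low = 5, median = 5, ci_high = 5))
  x <- rnorm(50, sd = 2)
  a <- median_resampling_ci(x, seed = 99)
  b <- median_resampling_ci(x, seed = 99)
  expect_identical(a, b)
  expect_lte(a$ci_low, a$median)
  expect_gte(a$ci_high, a$median)
  expect_warning(median_resampling_ci(x, n_resamples = 50, seed = 1),
                 class = "flyoperant_resampling_warning")
  expect_error(median_resampling_ci(5), class = "flyoperant_stats_error")
})

test_that("CI width shrinks with sample size", {
  set.seed(21)
  width <- function(n) {
    w <- replicate(20, {
      ci <- median_resampling_ci(rnorm(n), n_resamples = 2000)
      ci$ci_high - ci$ci_low
    })
    median(w)
  }
  expect_lt(width(200), width(50))
})

test_that("the permutation test matches full enumeration on small fixtures", {
  # full enumeration: 4 of the 20 splits attain |median difference| >= 100
  # ({1,2,3}, {101,102,103}, and the pair {1,2,101} / {3,102,103})
  pt <- two_group_permutation_test(c(1, 2, 3), c(101, 102, 103))
  expect_equal(pt$p_value, 0.2)
  expect_identical(pt$method, "exact")
  expect_equal(pt$p_value,
               oracle_permutation_p(c(1, 2, 3), c(101, 102, 103)))
  # identical multisets: observed statistic is the mode, p = 1
  expect_equal(two_group_permutation_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # Monte Carlo converges to the exact answer
  a <- c(1, 4, 2, 8, 3, 9, 5)
  b <- c(7, 11, 6, 12, 10)
  big <- c(a, 0.5)  # total n = 13 forces the Monte Carlo path
  p_mc <- vapply(c(2000, 20000), function(np)
    two_group_permutation_test(big, b, n_perm = np, seed = 12)$p_value,
    numeric(1))
  p_ex_big <- oracle_permutation_p(big, b)
  expect_lt(abs(p_mc[2] - p_ex_big), 3 * sqrt(p_ex_big * (1 - p_ex_big) / 20000) + 1e-4)
  expect_lt(abs(p_mc[2] - p_ex_big), abs(p_mc[1] - p_ex_big) + 0.02)
  # the enumeration boundary is a total n of 12
  expect_identical(two_group_permutation_test(a, b)$method, "exact")
})

test_that("rank procedures are invariant under monotone transforms", {
  set.seed(14)
  x <- rnorm(9); y <- rnorm(8) + 1; z <- rnorm(7) + 2
  d1 <- data.frame(v = c(x, y, z), g = rep(c("a", "b", "c"), c(9, 8, 7)))
  f <- function(v) exp(v) + v^3 / 10 + v  # strictly increasing
  d2 <- dplyr::mutate(d1, v = f(v))
  expect_equal(kruskal_wallis(d1, v, g)$statistic,
               kruskal_wallis(d2, v, g)$statistic)
  expect_equal(pairwise_wilcoxon(d1, v, g)$p_value,
               pairwise_wilcoxon(d2, v, g)$p_value)
})

test_that("correlation with slope reproduces affine relationships", {
  d <- data.frame(x = c(1, 2, 3, 4, 5))
  d$y <- d$x
  r1 <- correlation_with_slope(d, x, y)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 1)
  d$y <- -2 * d$x + 3
  r2 <- correlation_with_slope(d, x, y)
  expect_equal(r2$r, -1)
  expect_equal(r2$slope, -2)
  expect_equal(r2$intercept, 3)
  expect_error(correlation_with_slope(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               class = "flyoperant_stats_error")
  set.seed(2)
  d3 <- data.frame(x = rnorm(30))
  d3$y <- 0.5 * d3$x + rnorm(30)
  r3 <- correlation_with_slope(d3, x, y)
  expect_equal(sign(r3$r), sign(r3$slope))
  expect_equal(r3$p_value, stats::cor.test(d3$x, d3$y)$p.value, tolerance = 1e-12)
})

test_that("compare_groups bundles omnibus, pairwise and group CIs coherently", {
  set.seed(6)
  d <- data.frame(v = c(rnorm(12), rnorm(12) + 1.5, rnorm(12) + 3),
                  g = rep(c("a", "b", "c"), each = 12))
  cmp <- compare_groups(d, v, g, n_resamples = 2000, seed = 4)
  gs <- cmp$group_summary
  expect_true(all(gs$ci_low <= gs$median & gs$median <= gs$ci_high))
  expect_equal(nrow(cmp$pairwise), 3)
  td <- tidy(cmp)
  expect_true(all(c("median1", "median2") %in% names(td)))
  expect_equal(glance(cmp), cmp$omnibus)
  # significance stars follow the tier thresholds
  expect_identical(p_stars(c(0.2, 0.04, 0.009, 5e-4, 5e-5)),
                   c("n.s.", "*", "**", "***", "****"))
  js <- stats_report(cmp)
  expect_true(jsonlite::validate(js))
})
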