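# Rank-based inference layer: Kruskal-Wallis omnibus, pairwise Wilcoxon
# rank-sum follow-ups with Holm adjustment, bootstrap percentile CIs of
# group medians, two-group permutation tests, correlation with slope.

stats_error <- function(msg) abort(msg, class = "flyoperant_stats_error")

#' Significance stars
#'
#' The conventional tiers: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `n.s.` otherwise.
#'
#' @param p Numeric p-values.
#' @return Character vector of star labels.
#' @export
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "n.s."
  )
}

split_groups <- function(data, value, group) {
  value <- enquo(value); group <- enquo(group)
  v <- dplyr::pull(data, !!value)
  g <- as.character(dplyr::pull(data, !!group))
  keep_all_na <- tapply(v, g, function(x) all(is.na(x)))
  if (any(keep_all_na))
    stats_error(sprintf("group '%s' has no non-missing values",
                        names(keep_all_na)[keep_all_na][1]))
  ok <- !is.na(v)
  split(v[ok], g[ok])
}

# All distinct assignments of n items to groups with the given sizes,
# as an index matrix (one assignment per column; entries are group codes).
label_assignments <- function(sizes) {
  n <- sum(sizes)
  assign_rec <- function(free, sizes_left, labels) {
    if (length(sizes_left) == 1) {
      labels[free] <- length(sizes)
      return(list(labels))
    }
    g <- length(sizes) - length(sizes_left) + 1L
    picks <- combn(free, sizes_left[1], simplify = FALSE)
    out <- list()
    for (p in picks) {
      lab <- labels
      lab[p] <- g
      out <- c(out, assign_rec(setdiff(free, p), sizes_left[-1], lab))
    }
    out
  }
  do.call(cbind, assign_rec(seq_len(n), sizes, integer(n)))
}

kw_statistic <- function(ranks, codes, k) {
  n <- length(ranks)
  rbar <- tapply(ranks, codes, mean)
  ni <- tabulate(codes, k)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(ranks)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

#' Kruskal-Wallis omnibus test
#'
#' Midrank-based H with tie correction and the chi-square approximation
#' (df = k - 1), via [stats::kruskal.test()]. For small problems (total
#' n <= 10) an exact permutation p-value over all distinct group-label
#' assignments is also reported.
#'
#' @param data A data frame.
#' @param value,group Columns holding the response and the group label
#'   (tidy evaluation).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `p_exact` (NA when
#'   not enumerated), `n`, `n_groups`.
#' @export
#' @examples
#' df <- data.frame(y = 1:9, g = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis(df, y, g)
kruskal_wallis <- function(data, value, group) {
  groups <- split_groups(data, {{ value }}, {{ group }})
  if (length(groups) < 2) stats_error("need at least 2 groups")
  kt <- kruskal.test(groups)
  n <- sum(lengths(groups))
  p_exact <- NA_real_
  if (n <= 10) {
    x <- unlist(groups, use.names = FALSE)
    ranks <- rank(x)
    sizes <- lengths(groups)
    k <- length(groups)
    perms <- label_assignments(sizes)
    h_obs <- kw_statistic(ranks, rep(seq_len(k), sizes), k)
    h_perm <- apply(perms, 2, function(codes) kw_statistic(ranks, codes, k))
    p_exact <- mean(h_perm >= h_obs - 1e-12)
  }
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    p_exact = p_exact,
    n = n,
    n_groups = length(groups)
  )
}

#' Pairwise Wilcoxon rank-sum follow-ups
#'
#' Two-sided rank-sum test for every pair of groups: exact enumeration when
#' both groups have at most 8 observations and the pooled data are tie-free,
#' otherwise the normal approximation with continuity correction and
#' tie-corrected variance. Holm adjustment by default (`adjust = "none"`
#' for raw p-values).
#'
#' @inheritParams kruskal_wallis
#' @param adjust Adjustment method for [stats::p.adjust()].
#' @return Tibble, one row per pair: `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (rank-sum W of group1), `p_value`, `p_adjusted`, `stars`.
#' @export
pairwise_wilcoxon <- function(data, value, group, adjust = "holm") {
  groups <- split_groups(data, {{ value }}, {{ group }})
  if (length(groups) < 2) stats_error("need at least 2 groups")
  prs <- combn(names(groups), 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = TRUE))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   n1 = length(a), n2 = length(b),
                   statistic = unname(wt$statistic), p_value = wt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- p.adjust(out$p_value, method = adjust)
  out$stars <- p_stars(out$p_adjusted)
  attr(out, "adjust") <- adjust
  out
}

#' Bootstrap percentile confidence interval of the median
#'
#' Resamples the data with replacement `n_resamples` times and takes the
#' percentile interval of the resample medians. Deterministic given `seed`.
#'
#' @param x Numeric sample (length >= 2; NAs dropped).
#' @param n_resamples Number of resamples.
#' @param level Interval level.
#' @param seed Optional integer seed.
#' @return One-row tibble: `ci_low`, `median`, `ci_high`, `n`,
#'   `n_resamples`, `level`.
#' @export
#' @examples
#' median_resampling_ci(c(5, 5, 5, 5), seed = 1)
median_resampling_ci <- function(x, n_resamples = 10000, level = 0.95,
                                 seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stats_error("need at least 2 observations")
  if (n_resamples < 100)
    warn("fewer than 100 resamples: interval is unstable",
         class = "flyoperant_resampling_warning")
  if (!is.null(seed)) set.seed(seed)
  boots <- boot_median_cpp(x, as.integer(n_resamples))
  alpha <- (1 - level) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  tibble::tibble(ci_low = qs[1], median = median(x), ci_high = qs[2],
                 n = length(x), n_resamples = as.integer(n_resamples),
                 level = level)
}

#' Two-group permutation test
#'
#' Two-sided test of the group-label null: the p-value is the proportion of
#' label permutations whose statistic is at least as extreme (in absolute
#' value) as the observed one. Exact enumeration of all splits when the
#' total n is at most 12, otherwise Monte Carlo with the plus-one
#' correction.
#'
#' @param a,b Numeric samples.
#' @param statistic Function of two samples; default difference of medians.
#' @param n_perm Monte Carlo permutations.
#' @param seed Optional integer seed (Monte Carlo path).
#' @return One-row tibble: `estimate` (observed statistic), `p_value`,
#'   `n_a`, `n_b`, `method` ("exact" or "monte-carlo").
#' @export
#' @examples
#' two_group_permutation_test(c(1, 2, 3), c(101, 102, 103))
two_group_permutation_test <- function(a, b,
                                       statistic = function(x, y)
                                         median(x) - median(y),
                                       n_perm = 10000, seed = NULL) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stats_error("both groups must be non-empty")
  pooled <- c(a, b)
  na <- length(a); n <- length(pooled)
  obs <- statistic(a, b)
  if (n <= 12) {
    splits <- combn(n, na, simplify = FALSE)
    stat <- vapply(splits, function(ix)
      statistic(pooled[ix], pooled[-ix]), numeric(1))
    p <- mean(abs(stat) >= abs(obs) - 1e-12)
    method <- "exact"
  } else {
    if (!is.null(seed)) set.seed(seed)
    stat <- vapply(seq_len(n_perm), function(i) {
      ix <- sample.int(n, na)
      statistic(pooled[ix], pooled[-ix])
    }, numeric(1))
    p <- (1 + sum(abs(stat) >= abs(obs) - 1e-12)) / (n_perm + 1)
    method <- "monte-carlo"
  }
  tibble::tibble(estimate = obs, p_value = p, n_a = na, n_b = length(b),
                 method = method)
}

#' Pearson correlation with least-squares slope
#'
#' @param data A data frame.
#' @param x,y Columns (tidy evaluation).
#' @return One-row tibble: `r`, `slope`, `intercept`, `p_value` (two-sided
#'   t-test of zero slope), `n`.
#' @export
#' @examples
#' correlation_with_slope(data.frame(x = 1:5, y = c(2, 4, 5, 4, 6)), x, y)
correlation_with_slope <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- !is.na(xv) & !is.na(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 3) stats_error("need at least 3 complete observations")
  if (var(xv) == 0) stats_error("`x` has zero variance")
  fit <- lm(yv ~ xv)
  sm <- suppressWarnings(summary(fit))$coefficients
  tibble::tibble(
    r = cor(xv, yv),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = sm[2, 4],
    n = length(xv)
  )
}

#' Full group comparison: omnibus, pairwise follow-ups, median CIs
#'
#' Bundles [kruskal_wallis()], [pairwise_wilcoxon()] and per-group
#' [median_resampling_ci()] into one comparison object.
#'
#' @inheritParams kruskal_wallis
#' @param n_resamples Bootstrap resamples for group median CIs.
#' @param level CI level.
#' @param seed Integer seed for the resampling.
#' @param adjust Adjustment for the pairwise tests.
#' @return A `group_comparison` object (list with `omnibus`, `pairwise`,
#'   `group_summary` tibbles and the resampling parameters). `tidy()` gives
#'   the pairwise table, `glance()` the omnibus row.
#' @export
compare_groups <- function(data, value, group, n_resamples = 10000,
                           level = 0.95, seed = 1L, adjust = "holm") {
  groups <- split_groups(data, {{ value }}, {{ group }})
  omnibus <- kruskal_wallis(data, {{ value }}, {{ group }})
  pairwise <- pairwise_wilcoxon(data, {{ value }}, {{ group }}, adjust = adjust)
  gs <- lapply(names(groups), function(g) {
    ci <- median_resampling_ci(groups[[g]], n_resamples = n_resamples,
                               level = level,
                               seed = seed + match(g, names(groups)))
    dplyr::bind_cols(tibble::tibble(group = g), ci)
  })
  structure(
    list(omnibus = omnibus, pairwise = pairwise,
         group_summary = dplyr::bind_rows(gs),
         n_resamples = as.integer(n_resamples), level = level,
         seed = as.integer(seed)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.3f, df = %d, p = %.4g %s\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value,
              p_stars(x$omnibus$p_value)))
  cat("Group medians (bootstrap CI):\n")
  print(x$group_summary)
  cat("Pairwise Wilcoxon rank-sum (", attr(x$pairwise, "adjust") %||% "holm",
      "-adjusted):\n", sep = "")
  print(x$pairwise)
  invisible(x)
}

#' Tidiers for group comparisons
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the pairwise table with group medians attached;
#'   `glance()`: the omnibus row.
#' @export
#' @method tidy group_comparison
tidy.group_comparison <- function(x, ...) {
  med <- setNames(x$group_summary$median, x$group_summary$group)
  dplyr::mutate(x$pairwise,
                median1 = unname(med[.data$group1]),
                median2 = unname(med[.data$group2]),
                .after = "n2")
}

#' @rdname tidy.group_comparison
#' @export
#' @method glance group_comparison
glance.group_comparison <- function(x, ...) x$omnibus

#' Structured text report of one or more comparisons
#'
#' Serialises comparisons as JSON: per contrast the groups, sample sizes,
#' medians with CIs, raw and adjusted p-values, stars, and the resampling
#' parameters.
#'
#' @param comparisons Named list of `group_comparison` objects (or one).
#' @param path Optional path; when given the JSON is written there.
#' @return JSON string, invisibly when `path` is given.
#' @export
stats_report <- function(comparisons, path = NULL) {
  if (inherits(comparisons, "group_comparison"))
    comparisons <- list(comparison = comparisons)
  blocks <- lapply(comparisons, function(cmp) {
    list(
      omnibus = as.list(cmp$omnibus),
      groups = cmp$group_summary,
      pairwise = cmp$pairwise,
      n_resamples = cmp$n_resamples,
      level = cmp$level,
      seed = cmp$seed
    )
  })
  js <- jsonlite::toJSON(blocks, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
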