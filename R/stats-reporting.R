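# Per-cell statistical comparison layer. The testing scheme: normality is
# screened with the D'Agostino-Pearson omnibus test; two normal groups get a
# Student's t-test (Welch-corrected when an F-test flags unequal variances;
# paired when requested), non-normal pairs get the Mann-Whitney U test; more
# than two groups get one-way ANOVA with Holm-adjusted pairwise t-tests when
# normal, otherwise Kruskal-Wallis with Dunn's post hoc. All tests operate
# on one value per cell; only explicitly distribution-level comparisons
# (e.g. S_MSS distributions, two-sample Kolmogorov-Smirnov) pool
# trajectories.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the sample-size-corrected skewness z (Johnson SU approximation)
#' and kurtosis z (Anscombe-Glynn approximation) into K^2 = z1^2 + z2^2,
#' referred to a chi-squared distribution with 2 df.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` (K^2), `z_skew`, `z_kurt`, `p`; `p` is `NA`
#'   for n < 8.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) return(list(statistic = NA_real_, z_skew = NA_real_,
                         z_kurt = NA_real_, p = NA_real_))
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  if (m2 <= 0) return(list(statistic = NA_real_, z_skew = NA_real_,
                           z_kurt = NA_real_, p = NA_real_))
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2
  # skewness (D'Agostino 1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
  k2 <- z1^2 + z2^2
  list(statistic = k2, z_skew = z1, z_kurt = z2,
       p = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

# Normality verdict used by the router; NA p (tiny n) counts as non-normal,
# routing conservatively to the rank-based tests.
is_normal <- function(x, alpha = 0.05) {
  p <- dagostino_pearson(x)$p
  !is.na(p) && p > alpha
}

#' Select the statistical test for a set of groups
#'
#' Implements the per-cell testing scheme: per-group normality decides
#' between the parametric and rank-based route; the group count decides
#' between two-sample and multi-group machinery.
#'
#' @param groups list of numeric vectors (one value per cell), >= 2 groups
#'   of >= 3 values each.
#' @param paired paired two-group comparison (requires equal lengths).
#' @param alpha_normality significance level of the normality screen.
#' @return list of class `test_descriptor`: `route` (one of `"t"`,
#'   `"welch_t"`, `"paired_t"`, `"mann_whitney"`, `"wilcoxon_paired"`,
#'   `"anova_holm"`, `"kruskal_dunn"`), `normal` (per-group logical),
#'   `normality_p`, `n` per group; or `NULL` (no-test signal) when any group
#'   has fewer than 3 values.
#' @export
select_test <- function(groups, paired = FALSE, alpha_normality = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  n <- vapply(groups, length, 0L)
  if (any(n < 3)) return(NULL)
  if (paired && length(unique(n)) != 1) {
    stop("paired comparison requires equal group sizes")
  }
  norm_p <- vapply(groups, function(g) dagostino_pearson(g)$p, 0)
  normal <- vapply(groups, is_normal, TRUE, alpha = alpha_normality)
  route <- if (length(groups) == 2) {
    if (all(normal)) {
      if (paired) "paired_t" else {
        vt <- stats::var.test(groups[[1]], groups[[2]])
        if (vt$p.value < 0.05) "welch_t" else "t"
      }
    } else {
      if (paired) "wilcoxon_paired" else "mann_whitney"
    }
  } else {
    if (all(normal)) "anova_holm" else "kruskal_dunn"
  }
  structure(list(route = route, normal = normal, normality_p = norm_p, n = n),
            class = "test_descriptor")
}

#' Run the route-selected two-group test
#'
#' Applies the test chosen by [select_test()] to two groups and returns the
#' result with its routing record.
#'
#' @param a,b numeric vectors (one value per cell).
#' @param paired paired design.
#' @param alpha_normality significance level of the normality screen.
#' @return list: `test` (route name), `statistic`, `p`, `descriptor`.
#' @export
run_two_group_test <- function(a, b, paired = FALSE, alpha_normality = 0.05) {
  desc <- select_test(list(a, b), paired = paired,
                      alpha_normality = alpha_normality)
  if (is.null(desc)) return(list(test = "none", statistic = NA_real_,
                                 p = NA_real_, descriptor = NULL))
  res <- switch(desc$route,
    t = stats::t.test(a, b, var.equal = TRUE),
    welch_t = stats::t.test(a, b, var.equal = FALSE),
    paired_t = stats::t.test(a, b, paired = TRUE),
    mann_whitney = stats::wilcox.test(a, b, exact = FALSE),
    wilcoxon_paired = stats::wilcox.test(a, b, paired = TRUE, exact = FALSE))
  list(test = desc$route, statistic = unname(res$statistic),
       p = res$p.value, descriptor = desc)
}

#' Dunn's post-hoc test after Kruskal-Wallis
#'
#' Pairwise z statistics on mean ranks with tie correction; p values
#' adjusted by `p_adjust` (adjusted values never fall below the raw ones).
#'
#' @param values numeric vector.
#' @param groups factor/character of the same length.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return data.frame `group1`, `group2`, `z`, `p`, `p_adjusted`.
#' @export
dunn_test <- function(values, groups, p_adjust = "holm") {
  groups <- as.factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  rk <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(rk, groups, mean)
  ni <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[[i]] + 1 / ni[[j]]))
    z[k] <- (rbar[[i]] - rbar[[j]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

# Multi-group route: omnibus p plus adjusted pairwise table.
run_multi_group_test <- function(groups, alpha_normality = 0.05) {
  desc <- select_test(groups, alpha_normality = alpha_normality)
  if (is.null(desc)) return(list(test = "none", statistic = NA_real_,
                                 p = NA_real_, posthoc = NULL, descriptor = NULL))
  gname <- names(groups) %||% paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(gname, vapply(groups, length, 0L)), levels = gname)
  if (desc$route == "anova_holm") {
    fit <- stats::aov(values ~ fac)
    s <- summary(fit)[[1]]
    ph <- stats::pairwise.t.test(values, fac, p.adjust.method = "holm")
    list(test = "anova_holm", statistic = s$`F value`[1], p = s$`Pr(>F)`[1],
         posthoc = ph$p.value, descriptor = desc)
  } else {
    kw <- stats::kruskal.test(values, fac)
    list(test = "kruskal_dunn", statistic = unname(kw$statistic),
         p = kw$p.value, posthoc = dunn_test(values, fac), descriptor = desc)
  }
}

#' Run the comparison battery over per-cell metrics
#'
#' One comparison per metric across all conditions, with the route selected
#' by [select_test()]. Every result row records the route, per-group n and
#' the normality screen outcome.
#'
#' @param datasets named list of conditions; each a data.frame with one row
#'   per cell and the metric columns.
#' @param metrics character vector of metric column names.
#' @param alpha significance level for the `significant` flag.
#' @param paired paired two-condition design.
#' @return data.frame of class `comparison_results`, one row per metric:
#'   `metric`, `groups`, `test`, `statistic`, `p`, `significant`,
#'   `adjusted` (whether a multiple-comparison-adjusted post hoc is
#'   attached), `normal_groups`, `n`; post-hoc tables in
#'   `attr(, "posthoc")`.
#' @export
run_comparisons <- function(datasets, metrics, alpha = 0.05, paired = FALSE) {
  stopifnot(is.list(datasets), length(datasets) >= 2,
            !is.null(names(datasets)))
  posthoc <- list()
  rows <- lapply(metrics, function(m) {
    groups <- lapply(datasets, function(d) {
      if (!m %in% names(d)) stop("metric '", m, "' missing from a condition")
      v <- d[[m]]
      v[is.finite(v)]
    })
    if (length(groups) == 2) {
      res <- run_two_group_test(groups[[1]], groups[[2]], paired = paired)
      adj <- FALSE
    } else {
      res <- run_multi_group_test(groups)
      if (!is.null(res$posthoc)) posthoc[[m]] <<- res$posthoc
      adj <- !is.null(res$posthoc)
    }
    desc <- res$descriptor
    data.frame(
      metric = m, groups = paste(names(datasets), collapse = " vs "),
      test = res$test, statistic = res$statistic,
      p = res$p,
      significant = !is.na(res$p) && res$p < alpha,
      adjusted = adj,
      normal_groups = if (is.null(desc)) NA_character_ else
        paste(ifelse(desc$normal, "normal", "non-normal"), collapse = "/"),
      n = paste(vapply(groups, length, 0L), collapse = "/"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "posthoc") <- posthoc
  class(out) <- c("comparison_results", "data.frame")
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of pooled distributions
#'
#' The route used for distribution-level metrics such as per-trajectory
#' S_MSS values, where the compared objects are whole distributions rather
#' than per-cell scalars.
#'
#' @param x,y numeric vectors (pooled trajectory-level values).
#' @return data.frame row with `test = "kolmogorov_smirnov"`, `statistic`
#'   (D), `p`, `n`.
#' @export
compare_distributions <- function(x, y) {
  res <- suppressWarnings(stats::ks.test(x, y))
  data.frame(test = "kolmogorov_smirnov", statistic = unname(res$statistic),
             p = res$p.value, n = paste(length(x), length(y), sep = "/"),
             stringsAsFactors = FALSE)
}

#' Write a comparison report
#'
#' Emits the result table as CSV together with a human-readable text
#' summary; each row carries the route and group sizes.
#'
#' @param results `comparison_results` from [run_comparisons()].
#' @param csv_path,txt_path output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_comparison_report <- function(results, csv_path = NULL, txt_path = NULL) {
  written <- character(0)
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(results), csv_path, row.names = FALSE)
    written <- c(written, csv_path)
  }
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(results))) {
      r <- results[i, ]
      cat(sprintf("%s [%s]: %s (n = %s), p = %.4g%s\n",
                  r$metric, r$groups, r$test, r$n, r$p,
                  if (isTRUE(r$significant)) " *" else ""), file = con)
    }
    written <- c(written, txt_path)
  }
  invisible(written)
}
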