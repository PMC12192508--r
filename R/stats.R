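#' Per-group summary statistics
#'
#' Mean, sample standard deviation (n-1 denominator; `NA` for n = 1),
#' variance, median and range per group -- the "mean +/- sd" layer of a
#' cohort comparison.
#'
#' @param values Numeric vector.
#' @param groups Vector of group labels, same length as `values`.
#' @return `data.frame` with columns `group`, `n`, `mean`, `sd`, `variance`,
#'   `median`, `min`, `max`.
#' @export
summarize_groups <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (anyNA(values) || anyNA(groups))
    abort_validation("values and groups must be free of NA")
  split_v <- split(values, factor(groups, levels = unique(groups)))
  if (any(lengths(split_v) == 0))
    abort_validation("empty group")
  out <- data.frame(
    group = names(split_v),
    n = lengths(split_v),
    mean = vapply(split_v, mean, 0),
    sd = vapply(split_v, function(v) if (length(v) > 1) stats::sd(v) else NA_real_, 0),
    variance = vapply(split_v, function(v) if (length(v) > 1) stats::var(v) else NA_real_, 0),
    median = vapply(split_v, stats::median, 0),
    min = vapply(split_v, min, 0),
    max = vapply(split_v, max, 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# shared mode-selection rule: ANOVA (or t) when the central limit theorem
# applies (all n >= 30) or when Shapiro-Wilk on the centered residuals does
# not reject normality at 0.05; otherwise the rank-based test.
.parametric_ok <- function(split_v) {
  if (all(lengths(split_v) >= 30)) return(TRUE)
  resid <- unlist(lapply(split_v, function(v) v - mean(v)), use.names = FALSE)
  if (length(unique(resid)) < 3) return(FALSE)
  n <- length(resid)
  if (n < 3 || n > 5000) return(n >= 3)
  stats::shapiro.test(resid)$p.value > 0.05
}

#' Omnibus multi-group comparison
#'
#' One-way ANOVA where normality or the central limit theorem applies,
#' otherwise Kruskal-Wallis (tie-corrected). `mode = "auto"` concretizes
#' that rule as: ANOVA if every group has n >= 30, else if Shapiro-Wilk on
#' the within-group-centered residuals gives p > 0.05, else Kruskal-Wallis.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 groups, each n >= 2).
#' @param mode `"auto"`, `"anova"` or `"kruskal"`.
#' @return List with `name` (`"ANOVA"` or `"Kruskal-Wallis"`), `statistic`
#'   (F or H), `p`, `df`.
#' @export
omnibus_test <- function(values, groups, mode = c("auto", "anova", "kruskal")) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  split_v <- split(values, groups)
  if (length(split_v) < 2)
    abort_validation("omnibus test needs >= 2 groups")
  if (any(lengths(split_v) < 2))
    abort_validation("omnibus test needs n >= 2 per group")
  if (length(unique(values)) == 1)
    abort_validation("all values constant: omnibus statistic degenerate")
  if (mode == "auto")
    mode <- if (.parametric_ok(split_v)) "anova" else "kruskal"
  if (mode == "anova") {
    ht <- stats::oneway.test(values ~ factor(groups), var.equal = TRUE)
    list(name = "ANOVA", statistic = unname(ht$statistic),
         p = ht$p.value, df = unname(ht$parameter))
  } else {
    ht <- stats::kruskal.test(values, factor(groups))
    list(name = "Kruskal-Wallis", statistic = unname(ht$statistic),
         p = ht$p.value, df = unname(ht$parameter))
  }
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All unordered group pairs, two-sided; Welch t-test or Mann-Whitney U,
#' chosen per pair by the same rule as [omnibus_test()] when
#' `mode = "auto"`. Adjusted p is `min(1, raw p x family size)`.
#'
#' @inheritParams omnibus_test
#' @param mode `"auto"`, `"t"` or `"wilcox"`.
#' @param family_size Number of tests in the Bonferroni family; defaults to
#'   the number of pairs tested here.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with `group_a`, `group_b`, `test`, `statistic`,
#'   `p_raw`, `p_adjusted`, `significant`. Pairs with a group of n < 2 are
#'   skipped with a warning.
#' @export
pairwise_tests <- function(values, groups, mode = c("auto", "t", "wilcox"),
                           family_size = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  groups <- as.character(groups)
  split_v <- split(values, factor(groups, levels = unique(groups)))
  labs <- names(split_v)
  if (length(labs) < 2) abort_validation("pairwise tests need >= 2 groups")
  pairs <- utils::combn(labs, 2)
  rows <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    va <- split_v[[a]]; vb <- split_v[[b]]
    if (length(va) < 2 || length(vb) < 2) {
      warning(sprintf("skipping pair %s vs %s: group with n < 2", a, b))
      next
    }
    use <- mode
    if (use == "auto")
      use <- if (.parametric_ok(list(va, vb))) "t" else "wilcox"
    if (use == "t") {
      ht <- stats::t.test(va, vb)  # Welch, two-sided
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = a, group_b = b, test = "t",
        statistic = unname(ht$statistic), p_raw = ht$p.value)
    } else {
      ht <- suppressWarnings(stats::wilcox.test(va, vb))
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = a, group_b = b, test = "Mann-Whitney U",
        statistic = unname(ht$statistic), p_raw = ht$p.value)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(family_size)) family_size <- nrow(out)
  out$p_adjusted <- pmin(1, out$p_raw * family_size)
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out
}

#' Cohen's d from group moments
#'
#' Standardized mean difference `(mean_a - mean_b) / s` with, by default,
#' the root-mean-square of the two standard deviations as denominator,
#' `s = sqrt((sd_a^2 + sd_b^2) / 2)`. The n-weighted pooled-sd variant
#' (`method = "pooled"`) is also available. Sign convention: group a minus
#' group b (e.g. healthy minus affected).
#'
#' @param mean_a,sd_a,n_a Moments of group a (`sd_a >= 0`, `n_a >= 2`).
#' @param mean_b,sd_b,n_b Moments of group b.
#' @param method `"rms"` (default) or `"pooled"`.
#' @return Cohen's d (unbounded real; antisymmetric under swapping groups).
#' @examples
#' cohens_d(0.60, 0.09, 63, 0.43, 0.24, 26)  # ~0.94
#' @export
cohens_d <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                     method = c("rms", "pooled")) {
  method <- match.arg(method)
  if (sd_a < 0 || sd_b < 0) abort_validation("standard deviations must be >= 0")
  if (n_a < 2 || n_b < 2) abort_validation("Cohen's d needs n >= 2 per group")
  s <- if (method == "rms") sqrt((sd_a^2 + sd_b^2) / 2)
       else sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (s == 0) abort_validation("both standard deviations zero: d undefined")
  (mean_a - mean_b) / s
}

#' @rdname cohens_d
#' @param a,b Numeric sample vectors (alternative interface computing the
#'   moments from data).
#' @export
cohens_d_samples <- function(a, b, method = c("rms", "pooled")) {
  cohens_d(mean(a), stats::sd(a), length(a),
           mean(b), stats::sd(b), length(b), method = method)
}

#' Two-sample variance comparison
#'
#' By default a two-sided F-test of the variance ratio with the larger
#' variance in the numerator (so the reported ratio is >= 1); a
#' Brown-Forsythe Levene test (absolute deviations from group medians,
#' one-way ANOVA) is available as a robust alternative.
#'
#' @param values_a,values_b Numeric vectors (n >= 2 each).
#' @param method `"f"` or `"levene"`.
#' @return List with `method`, `ratio` (larger/smaller variance; `NA` for
#'   Levene), `statistic`, `p`.
#' @export
variance_test <- function(values_a, values_b, method = c("f", "levene")) {
  method <- match.arg(method)
  if (length(values_a) < 2 || length(values_b) < 2)
    abort_validation("variance test needs n >= 2 per group")
  va <- stats::var(values_a); vb <- stats::var(values_b)
  if (method == "f") {
    if (min(va, vb) == 0)
      abort_validation("zero variance in denominator: F ratio undefined")
    if (va >= vb) {
      f <- va / vb; df1 <- length(values_a) - 1; df2 <- length(values_b) - 1
    } else {
      f <- vb / va; df1 <- length(values_b) - 1; df2 <- length(values_a) - 1
    }
    p <- min(1, 2 * stats::pf(f, df1, df2, lower.tail = FALSE))
    list(method = "F", ratio = f, statistic = f, p = p)
  } else {
    z <- c(abs(values_a - stats::median(values_a)),
           abs(values_b - stats::median(values_b)))
    g <- rep(c("a", "b"), c(length(values_a), length(values_b)))
    ht <- stats::oneway.test(z ~ factor(g), var.equal = TRUE)
    list(method = "Levene (Brown-Forsythe)",
         ratio = max(va, vb) / min(va, vb),
         statistic = unname(ht$statistic), p = ht$p.value)
  }
}

#' @rdname variance_test
#' @param var_a,var_b Variances already computed (e.g. from printed group
#'   summaries); returns the larger/smaller ratio only.
#' @export
variance_ratio <- function(var_a, var_b) {
  if (min(var_a, var_b) <= 0)
    abort_validation("variance ratio needs positive variances")
  max(var_a, var_b) / min(var_a, var_b)
}

#' Spearman rank correlation
#'
#' Spearman's rho with midrank tie handling and an asymptotic two-sided p
#' (appropriate at cohort sample sizes).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho` and `p`.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    abort_validation("rank correlation needs equal lengths >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    abort_validation("constant vector: rank correlation undefined")
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ht$estimate), p = ht$p.value)
}

#' Full cohort comparison report
#'
#' Bundles the statistical layer applied to one response variable (e.g.
#' per-sample mean MND) across labelled groups: group summaries, omnibus
#' test, Bonferroni-corrected pairwise tests, Cohen's d effect sizes, and
#' pairwise variance tests.
#'
#' @inheritParams omnibus_test
#' @param effect `"rms"` or `"pooled"` denominator for Cohen's d.
#' @param var_method `"f"` or `"levene"`.
#' @param alpha Significance level for the Bonferroni-adjusted pairwise p.
#' @param reference Optional reference group label; when given, effect
#'   sizes and variance tests compare the reference against every other
#'   group (reference minus other), otherwise all pairs are compared.
#' @return Object of class `comparison_report`: list with `summaries`,
#'   `omnibus`, `pairwise`, `effects`, `variance_tests`, `alpha`.
#' @export
compare_groups <- function(values, groups, mode = "auto", effect = "rms",
                           var_method = "f", alpha = 0.05,
                           reference = NULL) {
  summ <- summarize_groups(values, groups)
  omni <- omnibus_test(values, groups, mode = mode)
  pw_mode <- switch(mode, anova = "t", kruskal = "wilcox", "auto")
  pw <- pairwise_tests(values, groups, mode = pw_mode, alpha = alpha)
  split_v <- split(values, factor(as.character(groups),
                                  levels = unique(as.character(groups))))
  labs <- names(split_v)
  eff_pairs <- if (is.null(reference)) {
    utils::combn(labs, 2)
  } else {
    if (!reference %in% labs)
      abort_validation(sprintf("reference group '%s' not found", reference))
    rbind(reference, setdiff(labs, reference))
  }
  effects <- do.call(rbind, lapply(seq_len(ncol(eff_pairs)), function(j) {
    a <- eff_pairs[1, j]; b <- eff_pairs[2, j]
    data.frame(group_a = a, group_b = b,
               cohens_d = cohens_d_samples(split_v[[a]], split_v[[b]],
                                           method = effect))
  }))
  var_tests <- do.call(rbind, lapply(seq_len(ncol(eff_pairs)), function(j) {
    a <- eff_pairs[1, j]; b <- eff_pairs[2, j]
    vt <- variance_test(split_v[[a]], split_v[[b]], method = var_method)
    data.frame(group_a = a, group_b = b, ratio = vt$ratio,
               statistic = vt$statistic, p = vt$p)
  }))
  structure(list(summaries = summ, omnibus = omni, pairwise = pw,
                 effects = effects, variance_tests = var_tests,
                 alpha = alpha),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  omnibus: %s statistic=%.4g p=%.3g\n",
              x$omnibus$name, x$omnibus$statistic, x$omnibus$p))
  s <- x$summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %s: n=%d, %.3f +/- %.3f\n",
                s$group[i], s$n[i], s$mean[i], s$sd[i]))
  cat(sprintf("  pairwise tests: %d (Bonferroni family %d, alpha %.2f)\n",
              nrow(x$pairwise), nrow(x$pairwise), x$alpha))
  invisible(x)
}

#' Boxplot of MND by group
#'
#' A minimal reproducible visualization of group MND distributions
#' (no publication styling).
#'
#' @param values Numeric vector.
#' @param groups Group labels.
#' @param ylab Axis label.
#' @param ... Passed to [graphics::boxplot()].
#' @return Invisibly, the boxplot stats.
#' @export
plot_group_distributions <- function(values, groups, ylab = "mean MND", ...) {
  invisible(graphics::boxplot(values ~ factor(as.character(groups),
                                              levels = unique(as.character(groups))),
                              ylab = ylab, xlab = "", ...))
}
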