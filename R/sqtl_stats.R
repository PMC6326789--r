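# Statistical layer: construct-vs-construct t-tests with family-wise
# Bonferroni correction, genotype one-way ANOVA and allele-dose tests.

new_test_result <- function(test, statistic, df, p, ...,
                            alpha_adjusted = NULL, degenerate = FALSE) {
  alpha <- if (is.null(alpha_adjusted)) 0.05 else alpha_adjusted
  structure(list(test = test, statistic = statistic, df = df, p = p,
                 alpha_adjusted = alpha_adjusted,
                 significant = is.finite(p) && p < alpha,
                 degenerate = degenerate, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, df = %s, p = %.4g%s\n",
              x$test, x$statistic, paste(signif(x$df, 4), collapse = ","),
              x$p,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.null(x$alpha_adjusted))
    cat(sprintf("  adjusted alpha %.4g; significant: %s\n",
                x$alpha_adjusted, x$significant))
  invisible(x)
}

#' Unpaired t-test between two construct groups
#'
#' Two-sided unpaired t-test comparing percent exon skipping between two
#' groups of replicate measurements (e.g. insertion-present vs
#' pre-insertion reporter constructs). Student's equal-variance test is the
#' default; set `welch = TRUE` for the Welch variant.
#'
#' @param group_a,group_b Numeric vectors of measurements, each of length
#'   >= 2.
#' @param welch Use the Welch unequal-variance test (default FALSE).
#' @param alpha_adjusted Optional family-wise adjusted alpha against which
#'   the `significant` flag is set (defaults to 0.05 when absent).
#' @return A `test_result` list with `test = "t_unpaired"`, `statistic`,
#'   `df`, `p`, `mean_diff` (mean_a - mean_b) and `degenerate` flag. When
#'   both groups have zero variance and equal means the comparison is
#'   degenerate and reported with p = 1.
#' @export
construct_ttest <- function(group_a, group_b, welch = FALSE,
                            alpha_adjusted = NULL) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 observations")
  pooled_var <- stats::var(group_a) + stats::var(group_b)
  if (pooled_var == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(new_test_result("t_unpaired", statistic = 0,
                             df = length(group_a) + length(group_b) - 2L,
                             p = 1, mean_diff = 0,
                             alpha_adjusted = alpha_adjusted,
                             degenerate = TRUE))
    }
    # different constants: infinitely strong evidence
    return(new_test_result("t_unpaired", statistic = Inf,
                           df = length(group_a) + length(group_b) - 2L,
                           p = 0, mean_diff = mean(group_a) - mean(group_b),
                           alpha_adjusted = alpha_adjusted,
                           degenerate = TRUE))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  new_test_result("t_unpaired", statistic = unname(tt$statistic),
                  df = unname(tt$parameter), p = tt$p.value,
                  mean_diff = mean(group_a) - mean(group_b),
                  alpha_adjusted = alpha_adjusted)
}

#' Bonferroni-adjusted significance threshold
#'
#' Divides the family-wise alpha by the number of tests. The display value
#' is rounded to 2 significant figures (0.05 over 21 tests -> 0.0024; over
#' 26 tests -> 0.0019); the unrounded threshold is retained.
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param m Number of tests in the family (>= 1).
#' @return List with `threshold` (alpha/m, full precision), `display`
#'   (2 significant figures), `alpha`, `m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  thr <- alpha / m
  list(threshold = thr, display = signif(thr, 2), alpha = alpha, m = m)
}

check_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("sample_id", "dose", "percent_skipping") %in% names(panel)))
  if (!all(panel$dose %in% c(0L, 1L, 2L)))
    stop("allele dose must be 0, 1 or 2")
  invisible(panel)
}

#' One-way ANOVA of splicing across genotype dose groups
#'
#' Tests whether percent exon skipping differs across insertion-allele
#' dose groups (0/1/2 copies) by one-way ANOVA.
#'
#' @param panel Genotype panel data frame with columns `sample_id`, `dose`
#'   (0/1/2) and `percent_skipping`.
#' @return A `test_result` with `test = "anova_oneway"`, the F statistic,
#'   `df` (between, within) and p. A panel in which every measurement is
#'   identical is degenerate and reported with F = 0, p = 1.
#' @export
genotype_anova <- function(panel) {
  check_panel(panel)
  groups <- split(panel$percent_skipping, panel$dose)
  if (length(groups) < 2L) stop("need >= 2 dose groups for ANOVA")
  if (nrow(panel) < 3L) stop("need >= 3 samples")
  if (stats::var(panel$percent_skipping) == 0)
    return(new_test_result("anova_oneway", statistic = 0,
                           df = c(length(groups) - 1L,
                                  nrow(panel) - length(groups)),
                           p = 1, degenerate = TRUE))
  fit <- stats::aov(percent_skipping ~ factor(dose), data = panel)
  s <- summary(fit)[[1]]
  new_test_result("anova_oneway", statistic = s$`F value`[1],
                  df = c(s$Df[1], s$Df[2]), p = s$`Pr(>F)`[1])
}

#' Allele-dose t-test between two genotype groups
#'
#' Unpaired t-test of percent exon skipping between two dose groups, e.g.
#' insertion homozygotes vs heterozygotes. The sign of `direction` reports
#' which group skips more (`+1` when `dose_a` has the larger mean).
#'
#' @param panel Genotype panel data frame (see [genotype_anova]).
#' @param dose_a,dose_b The two allele doses to compare (each in 0/1/2).
#' @param welch Use Welch's test (default FALSE).
#' @return A `test_result` as in [construct_ttest] plus `direction`.
#' @export
dose_test <- function(panel, dose_a, dose_b, welch = FALSE) {
  check_panel(panel)
  ga <- panel$percent_skipping[panel$dose == dose_a]
  gb <- panel$percent_skipping[panel$dose == dose_b]
  if (length(ga) < 2L || length(gb) < 2L)
    stop("both dose groups must be present with n >= 2")
  res <- construct_ttest(ga, gb, welch = welch)
  res$direction <- sign(mean(ga) - mean(gb))
  res$doses <- c(dose_a, dose_b)
  res
}

#' All pairwise construct comparisons with a family-wise threshold
#'
#' Runs every pairwise unpaired t-test among construct groups and flags
#' significance against the Bonferroni threshold for a declared family
#' size. The family size is an explicit input, not inferred from the number
#' of comparisons performed, so that reports can honour a pre-declared
#' testing plan; it must be at least the number of tests run.
#'
#' @param measures Data frame with columns `construct` and
#'   `percent_skipping` (one row per replicate).
#' @param family_size Declared number of tests in the family.
#' @param alpha Family-wise alpha (default 0.05).
#' @param welch Use Welch's test (default FALSE).
#' @return Data frame with one row per construct pair: `construct_a`,
#'   `construct_b`, `mean_a`, `mean_b`, `statistic`, `df`, `p`,
#'   `alpha_adjusted`, `significant`.
#' @export
per_locus_report <- function(measures, family_size, alpha = 0.05,
                             welch = FALSE) {
  stopifnot(is.data.frame(measures),
            all(c("construct", "percent_skipping") %in% names(measures)))
  groups <- split(measures$percent_skipping, measures$construct)
  if (length(groups) < 2L) stop("need >= 2 construct groups")
  pairs <- utils::combn(names(groups), 2L)
  n_tests <- ncol(pairs)
  if (family_size < n_tests)
    stop("declared family_size (", family_size,
         ") is smaller than the ", n_tests, " tests performed")
  thr <- bonferroni_threshold(alpha, family_size)
  rows <- lapply(seq_len(n_tests), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    tt <- construct_ttest(groups[[a]], groups[[b]], welch = welch,
                          alpha_adjusted = thr$threshold)
    data.frame(construct_a = a, construct_b = b,
               mean_a = mean(groups[[a]]), mean_b = mean(groups[[b]]),
               statistic = tt$statistic, df = tt$df[1], p = tt$p,
               alpha_adjusted = thr$threshold,
               significant = tt$significant,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- thr
  out
}
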