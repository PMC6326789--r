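# Candidate selection near alternatively used exons, with the enrichment
# statistics used to characterize the candidate set (orientation and
# position chi-square tests, linkage disequilibrium with trait-associated
# SNPs).

#' Screen insertion variants near exons
#'
#' Keeps intronic variants whose nearest exon lies within `window` bp
#' (inclusive; within-exon insertions are excluded from candidacy) and
#' annotates each candidate with its relative position and orientation with
#' respect to the gene and a frameshift flag for the nearby exon. A variant
#' near several genes yields one row per gene; within a gene it is counted
#' once, assigned to its nearest exon (tie broken toward the
#' transcriptionally downstream exon).
#'
#' @param variants Variant catalog data frame (see [read_variants]).
#' @param genes List of [gene_model] objects.
#' @param window Candidate window in bp, inclusive (default 100).
#' @param require_alternative If TRUE, keep only candidates whose nearby
#'   exon is alternatively used (`exon_class != "constitutive"`).
#' @return Data frame ordered by (chrom, pos): columns of
#'   [nearest_exon_distance] plus `relative_orientation` (`sense` /
#'   `antisense`, element strand vs gene strand) and `frameshift_flag`.
#' @export
screen_candidates <- function(variants, genes, window = 100L,
                              require_alternative = FALSE) {
  if (window <= 0) stop("window must be positive")
  nd <- nearest_exon_distance(variants, genes)
  keep <- !is.na(nd$distance) & nd$intronic & nd$distance >= 1L &
    nd$distance <= window
  if (require_alternative)
    keep <- keep & is_alternative_class(nd$exon_class)
  out <- nd[keep, , drop = FALSE]
  out$relative_orientation <- ifelse(out$element_strand == out$gene_strand,
                                     "sense", "antisense")
  out$frameshift_flag <- frameshift_flag(out$exon_length)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Does skipping or including an exon shift the reading frame?
#'
#' TRUE when the exon length is not a multiple of 3, so transcript isoforms
#' that include vs exclude the exon encode different downstream frames.
#'
#' @param exon_length Exon length(s) in bp, >= 1.
#' @return Logical vector.
#' @examples
#' frameshift_flag(c(143, 111, 265))  # TRUE FALSE TRUE
#' @export
frameshift_flag <- function(exon_length) {
  if (any(exon_length < 1)) stop("exon_length must be >= 1")
  exon_length %% 3 != 0
}

#' Chi-square test of two counts against a 50/50 expectation
#'
#' Pearson chi-square with df = 1 and no continuity correction, as used to
#' ask whether e.g. sense vs antisense candidate counts depart from the
#' equal split expected for random insertion.
#'
#' @param count_a,count_b Non-negative integer counts; at least one must be
#'   positive.
#' @return A `test_result` list: `test = "chi2"`, `statistic`, `df`, `p`,
#'   `observed`, `expected_fraction = 0.5`.
#' @examples
#' equal_expectation_chi2(42, 31)$p  # 0.1979
#' @export
equal_expectation_chi2 <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0) stop("counts must be non-negative")
  n <- count_a + count_b
  if (n < 1) stop("both counts are zero")
  e <- n / 2
  stat <- (count_a - e)^2 / e + (count_b - e)^2 / e
  new_test_result("chi2", statistic = stat, df = 1,
                  p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  observed = c(count_a, count_b), expected_fraction = 0.5)
}

#' One-sample chi-square of a proportion against an expected fraction
#'
#' Tests whether `observed_in_class` of `total` departs from
#' `expected_fraction` by a Pearson chi-square on the 2-cell table
#' (in-class, out-of-class), df = 1, no continuity correction.
#'
#' @param observed_in_class Count in the class of interest.
#' @param total Total count (>= observed_in_class).
#' @param expected_fraction Expected fraction, strictly between 0 and 1.
#' @return A `test_result` list as in [equal_expectation_chi2].
#' @export
proportion_chi2 <- function(observed_in_class, total, expected_fraction) {
  if (expected_fraction <= 0 || expected_fraction >= 1)
    stop("expected_fraction must lie strictly between 0 and 1")
  if (observed_in_class > total) stop("observed exceeds total")
  if (total < 1) stop("total must be >= 1")
  e1 <- total * expected_fraction
  e2 <- total * (1 - expected_fraction)
  o2 <- total - observed_in_class
  stat <- (observed_in_class - e1)^2 / e1 + (o2 - e2)^2 / e2
  new_test_result("chi2", statistic = stat, df = 1,
                  p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                  observed = c(observed_in_class, o2),
                  expected_fraction = expected_fraction)
}

#' Pairwise linkage disequilibrium from haplotype counts
#'
#' Computes D, D' and r-squared between two biallelic loci from a 2x2 table
#' of haplotype counts, with a bootstrap percentile CI for D'.
#'
#' @param haplotype_counts 2x2 numeric matrix of haplotype counts; rows are
#'   alleles A/a at the first locus, columns alleles B/b at the second.
#' @param n_boot Bootstrap replicates for the D' CI (default 1000).
#' @param seed Integer seed (required when `n_boot > 0`).
#' @param conf Confidence level for the CI (default 0.95).
#' @return An `ld_result` list: `d`, `d_prime`, `r2`, `ci` (for D'),
#'   `haplotype_freqs`, `allele_freqs`.
#' @details D = p_AB - p_A p_B; D' = D / Dmax where Dmax = min(p_A p_b,
#' p_a p_B) for D > 0 and min(p_A p_B, p_a p_b) for D < 0;
#' r2 = D^2 / (p_A p_a p_B p_b). Bootstrap resamples haplotypes
#' multinomially; degenerate (monomorphic) resamples are dropped from the
#' CI.
#' @export
ld_stats <- function(haplotype_counts, n_boot = 1000L, seed = NULL,
                     conf = 0.95) {
  m <- as.matrix(haplotype_counts)
  if (!all(dim(m) == c(2L, 2L))) stop("haplotype_counts must be 2x2")
  if (any(m < 0)) stop("negative haplotype count")
  n <- sum(m)
  if (n < 1) stop("empty haplotype table")
  ld_point <- function(m) {
    p <- m / sum(m)
    pA <- sum(p[1, ]); pB <- sum(p[, 1])
    if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(NULL)
    D <- p[1, 1] - pA * pB
    dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    dp <- if (D == 0) 0 else abs(D) / dmax
    r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
    list(d = D, d_prime = dp, r2 = r2, pA = pA, pB = pB, p = p)
  }
  pt <- ld_point(m)
  if (is.null(pt)) stop("monomorphic locus: LD undefined")
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    if (is.null(seed)) stop("a seed is required for the bootstrap CI")
    probs <- as.vector(m) / n
    boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        res <- matrix(stats::rmultinom(1, n, probs), 2, 2)
        bp <- ld_point(res)
        if (is.null(bp)) NA_real_ else bp$d_prime
      }, numeric(1))
    })
    boot <- boot[!is.na(boot)]
    alpha <- 1 - conf
    ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  }
  structure(list(d = pt$d, d_prime = pt$d_prime, r2 = pt$r2, ci = ci,
                 haplotype_freqs = pt$p,
                 allele_freqs = c(p_A = pt$pA, p_B = pt$pB), n = n),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> r2 = %.3f, D' = %.3f (CI %.2f-%.2f), n = %d\n",
              x$r2, x$d_prime, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Format a count as a percent of a total
#'
#' One-decimal display used in screen summary lines (e.g. 5 significant of
#' 23 assayed loci -> "21.7%").
#'
#' @param k Numerator count.
#' @param n Denominator count (> 0).
#' @param digits Decimal places for display (default 1).
#' @return List with `value` (full-precision percent), `display`
#'   (rounded number) and `label` (string with a percent sign).
#' @export
summary_fraction <- function(k, n, digits = 1L) {
  if (n <= 0) stop("denominator must be positive")
  value <- 100 * k / n
  display <- round(value, digits)
  list(value = value, display = display,
       label = sprintf(paste0("%.", digits, "f%%"), display))
}
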