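# Distance-distribution binning and depletion-zone quantification.
#
# Intronic insertion variants are summarized as the proportion of elements
# whose nearest-exon distance falls in each fixed-width bin, and the
# depletion of insertions near exons is quantified as a per-bp density
# ratio inside vs outside a window flanking exons.

#' Bin nearest-exon distances into a proportion profile
#'
#' Bins are left-open/right-closed: bin k covers
#' `(bin_width*(k-1), bin_width*k]`, so a distance exactly equal to the bin
#' width falls in the first bin. Distances beyond `max_distance` are pooled
#' into an overflow bin.
#'
#' @param distances Integer vector of nearest-exon distances in bp; all
#'   must be >= 1 (within-exon records are excluded upstream).
#' @param bin_width Bin width in bp (default 25).
#' @param max_distance Upper edge of the last regular bin in bp; distances
#'   above it go to the overflow bin. Default 2500.
#' @return An object of class `distance_profile`: a list with `bin_width`,
#'   `breaks`, a data frame `bins` (`bin_lo`, `bin_hi`, `count`,
#'   `proportion`; `bin_hi = Inf` marks overflow) and `n_total`.
#' @export
bin_distances <- function(distances, bin_width = 25L, max_distance = 2500L) {
  if (length(distances) == 0L) stop("no distances to bin")
  if (anyNA(distances)) stop("distances contain NA")
  if (any(distances < 1)) stop("distances must be >= 1 (intronic only)")
  if (bin_width < 1) stop("bin_width must be >= 1")
  if (max_distance < bin_width) stop("max_distance must be >= bin_width")
  n_bins <- ceiling(max_distance / bin_width)
  lo <- bin_width * (seq_len(n_bins) - 1L)
  hi <- bin_width * seq_len(n_bins)
  # (lo, hi] binning: distance d -> ceiling(d / width)
  idx <- ceiling(distances / bin_width)
  idx[idx > n_bins] <- n_bins + 1L
  counts <- tabulate(idx, nbins = n_bins + 1L)
  n_total <- length(distances)
  bins <- data.frame(bin_lo = c(lo, max_distance),
                     bin_hi = c(hi, Inf),
                     count = counts,
                     proportion = counts / n_total)
  structure(list(bin_width = bin_width, max_distance = max_distance,
                 bins = bins, n_total = n_total),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat(sprintf("<distance_profile> %d elements, %d bp bins up to %d bp (+overflow)\n",
              x$n_total, x$bin_width, x$max_distance))
  occupied <- sum(x$bins$count > 0)
  cat(sprintf("  %d occupied bin(s); first-bin proportion %.4f\n",
              occupied, x$bins$proportion[1]))
  invisible(x)
}

#' Write a distance profile as TSV
#'
#' @param profile A `distance_profile`.
#' @param path Output path. The header records the (lo, hi] bin convention.
#' @return The path, invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# nearest-exon distance profile; bins are (bin_lo, bin_hi] bp",
               sprintf("# bin_width=%d max_distance=%d n_total=%d",
                       profile$bin_width, profile$max_distance,
                       profile$n_total)), con)
  utils::write.table(profile$bins, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Estimate insertion depletion near exons
#'
#' Compares the per-bp density of insertions whose nearest-exon distance is
#' within `window` bp of an exon with the density farther away. A retention
#' ratio of 1 means no depletion; values below 1 mean insertions are
#' underrepresented near exons. The intronic bp of exposure inside and
#' outside the window must be supplied (computed from the annotation via
#' [intronic_exposure]); assuming uniform exposure biases the ratio when
#' introns are short.
#'
#' @param distances Integer vector of nearest-exon distances (bp, >= 1).
#' @param window Window in bp; "within" is inclusive (distance <= window).
#' @param bp_inside,bp_outside Intronic base pairs of exposure within and
#'   beyond the window; both must be positive.
#' @param n_boot Bootstrap replicates for the percentile CI (default 1000).
#' @param seed Integer seed for the bootstrap (required; no hidden RNG).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `depletion_estimate`: list with
#'   `retention_ratio`, `ci` (lo, hi), `n_inside`, `n_outside`, `window`.
#' @export
depletion_estimate <- function(distances, window = 100L, bp_inside,
                               bp_outside, n_boot = 1000L, seed,
                               conf = 0.95) {
  if (missing(seed)) stop("a seed is required for the bootstrap CI")
  if (any(distances < 1)) stop("distances must be >= 1")
  if (bp_inside <= 0 || bp_outside <= 0)
    stop("exposure totals must be positive")
  inside <- distances <= window
  n_in <- sum(inside)
  n_out <- sum(!inside)
  if (n_out == 0L) stop("no elements outside the window: ratio undefined")
  ratio_of <- function(ni, no) (ni / bp_inside) / (no / bp_outside)
  est <- ratio_of(n_in, n_out)
  n <- length(distances)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- sum(inside[sample.int(n, n, replace = TRUE)])
      if (res == n) return(Inf)
      ratio_of(res, n - res)
    }, numeric(1))
  })
  alpha <- 1 - conf
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  structure(list(retention_ratio = est, ci = ci, n_inside = n_in,
                 n_outside = n_out, window = window, n_boot = n_boot,
                 conf = conf),
            class = "depletion_estimate")
}

#' @export
print.depletion_estimate <- function(x, ...) {
  cat(sprintf(
    "<depletion_estimate> window %d bp: retention ratio %.3f (%d%% CI %.3f-%.3f)\n",
    x$window, x$retention_ratio, round(100 * x$conf), x$ci[1], x$ci[2]))
  cat(sprintf("  %d element(s) inside, %d outside\n", x$n_inside, x$n_outside))
  invisible(x)
}

#' Intronic exposure inside and outside an exon-flanking window
#'
#' For each gene, counts intronic base positions (positions intronic in at
#' least one isoform and located between the gene's outermost exon
#' boundaries) whose nearest-exon distance is within `window` bp, and
#' those farther away. Used as the exposure denominators of
#' [depletion_estimate].
#'
#' @param genes List of [gene_model] objects.
#' @param window Window in bp (inclusive).
#' @return Named numeric vector with `bp_inside` and `bp_outside`.
#' @export
intronic_exposure <- function(genes, window = 100L) {
  pool <- intronic_position_pool(genes)
  c(bp_inside = sum(pool$dist <= window),
    bp_outside = sum(pool$dist > window))
}

#' Compare two distance profiles
#'
#' Computes per-bin proportion ratios between two cohorts binned
#' identically (for example polymorphic insertions vs fixed reference
#' elements) and a chi-square test of homogeneity across bins of the two
#' count vectors.
#'
#' @param profile_a,profile_b `distance_profile` objects with identical
#'   binning.
#' @return List with `table` (bin_lo, bin_hi, count_a, count_b,
#'   proportion_a, proportion_b, ratio — `NaN` flags 0/0 bins) and
#'   `chi2` (`statistic`, `df`, `p`).
#' @export
compare_cohorts <- function(profile_a, profile_b) {
  if (!identical(profile_a$bin_width, profile_b$bin_width) ||
      !identical(profile_a$max_distance, profile_b$max_distance))
    stop("profiles are binned differently; rebin before comparing")
  a <- profile_a$bins
  b <- profile_b$bins
  tab <- data.frame(bin_lo = a$bin_lo, bin_hi = a$bin_hi,
                    count_a = a$count, count_b = b$count,
                    proportion_a = a$proportion, proportion_b = b$proportion,
                    ratio = a$proportion / b$proportion)
  m <- rbind(a$count, b$count)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  if (ncol(m) < 2L) {
    chi2 <- list(statistic = 0, df = 0, p = 1)
  } else {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    chi2 <- list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p = unname(ct$p.value))
  }
  list(table = tab, chi2 = chi2)
}
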