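# Independent brute-force oracles and random fixture builders. Oracles are
# written as plain loops over definitions, independent of the package's
# vectorized code paths.

# Distance from an insertion point to one exon, by literal base counting:
# 0 inside the exon, otherwise 1 + number of bases strictly between the
# insertion base and the nearest exon edge.
oracle_point_distance <- function(p, s, e) {
  if (p >= s && p < e) return(0)
  if (p < s) {
    between <- 0
    b <- p + 1
    while (b < s) { between <- between + 1; b <- b + 1 }
    return(between + 1)
  }
  between <- 0
  b <- e
  while (b < p) { between <- between + 1; b <- b + 1 }
  between + 1
}

# Scan every exon of a gene model; return min distance and all indices
# attaining it.
oracle_nearest <- function(p, gm) {
  ex <- gm$exons
  d <- numeric(nrow(ex))
  for (i in seq_len(nrow(ex)))
    d[i] <- oracle_point_distance(p, ex$start[i], ex$end[i])
  list(dmin = min(d), idx = which(d == min(d)))
}

# Exon classification by exhaustive comparison of boundary sets across
# isoforms (the classification rules restated with set operations).
oracle_classify <- function(start, end, isoforms, strand) {
  present <- vapply(isoforms, function(ex)
    any(ex$start == start & ex$end == end), logical(1))
  if (!any(present)) stop("exon not in any isoform")
  if (all(present)) return("constitutive")
  skipped <- FALSE
  left_diff <- FALSE
  right_diff <- FALSE
  for (ex in isoforms) {
    ov <- which(ex$start < end & ex$end > start)
    if (length(ov) == 0) {
      if (min(ex$start) <= start && max(ex$end) >= end) skipped <- TRUE
    } else {
      left_diff <- left_diff || !all(ex$start[ov] == start)
      right_diff <- right_diff || !all(ex$end[ov] == end)
    }
  }
  alt5 <- if (strand == "+") left_diff else right_diff
  alt3 <- if (strand == "+") right_diff else left_diff
  if (skipped && (alt5 || alt3)) return("skipped+alt-ends")
  if (skipped) return("skipped")
  if (alt5 && alt3) return("alt5+alt3")
  if (alt5) return("alt5")
  if (alt3) return("alt3")
  "constitutive"
}

# LD measures by direct frequency arithmetic on the four haplotype counts.
oracle_ld <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  pAB <- n_AB / n
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  list(d = D,
       d_prime = if (D == 0) 0 else abs(D) / dmax,
       r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# Molar fractions by an explicit loop.
oracle_molar <- function(lengths, intensities) {
  w <- numeric(length(lengths))
  for (i in seq_along(lengths)) w[i] <- intensities[i] / lengths[i]
  w / sum(w)
}

# Random gene model with skipped exons and jittered boundaries, built
# directly (not via the package's simulator).
random_gene_fixture <- function(seed, n_exons = NULL) {
  withr::with_seed(seed, {
    if (is.null(n_exons)) n_exons <- sample(3:8, 1)
    len <- sample(50:250, n_exons, replace = TRUE)
    gap <- sample(300:1500, n_exons - 1, replace = TRUE)
    starts <- 5000 + cumsum(c(0, len[-n_exons] + gap))
    ends <- starts + len
    canonical <- data.frame(start = starts, end = ends)
    isoforms <- list(isoA = canonical)
    # isoform skipping one random internal exon
    if (n_exons >= 3 && runif(1) < 0.7) {
      k <- sample(2:(n_exons - 1), 1)
      isoforms$isoB <- canonical[-k, ]
    }
    # isoform with a jittered boundary on one exon (stays non-overlapping)
    if (runif(1) < 0.5) {
      k <- sample(n_exons, 1)
      jit <- canonical
      jit$end[k] <- jit$end[k] + sample(10:100, 1)
      if (k == n_exons || jit$end[k] < jit$start[k + 1])
        isoforms$isoC <- jit
    }
    gene_model(sprintf("g%04d", seed), "chrT",
               sample(c("+", "-"), 1), isoforms)
  })
}
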