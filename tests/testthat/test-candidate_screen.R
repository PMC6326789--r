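# Candidate selection window, frameshift rule, enrichment chi-squares and
# linkage disequilibrium.

test_that("the candidate window is inclusive of its edge and excludes within-exon insertions", {
  gm <- gene_model("g1", "chr1", "+",
                   list(iso1 = data.frame(start = c(100, 1000, 2000),
                                          end = c(243, 1100, 2100)),
                        iso2 = data.frame(start = c(100, 2000),
                                          end = c(243, 2100))))
  mk <- function(pos) data.frame(chrom = "chr1", pos = pos,
                                 subfamily = "AluYa5", element_length = 300L,
                                 element_strand = "-",
                                 allele_frequency = 0.3)
  # distance to exon [1000,1100): pos 900 -> 100 (in); pos 899 -> 101 (out)
  expect_equal(nrow(screen_candidates(mk(900L), list(gm))), 1L)
  expect_equal(nrow(screen_candidates(mk(899L), list(gm))), 0L)
  # within-exon insertion is not a candidate
  expect_equal(nrow(screen_candidates(mk(1050L), list(gm))), 0L)
  # require_alternative drops candidates near constitutive exons
  cand <- screen_candidates(mk(900L), list(gm), require_alternative = TRUE)
  expect_equal(nrow(cand), 1L)  # exon [1000,1100) is skipped in iso2
  gm_const <- gene_model("g2", "chr1", "+",
                         list(only = data.frame(start = c(100, 1000, 2000),
                                                end = c(243, 1100, 2100))))
  expect_equal(nrow(screen_candidates(mk(900L), list(gm_const),
                                      require_alternative = TRUE)), 0L)
  expect_error(screen_candidates(mk(900L), list(gm), window = 0), "positive")
})

test_that("candidate annotation carries orientation and frameshift flags", {
  gm <- gene_model("g1", "chr1", "-",
                   list(iso1 = data.frame(start = c(100, 1000), end = c(243, 1100)),
                        iso2 = data.frame(start = 100, end = 243)))
  v <- data.frame(chrom = "chr1", pos = 950L, subfamily = "AluYb8",
                  element_length = 281L, element_strand = "-",
                  allele_frequency = 0.1)
  cand <- screen_candidates(v, list(gm))
  expect_equal(cand$relative_orientation, "sense")   # both minus
  expect_equal(cand$exon_id, "g1:1000-1100")
  expect_equal(cand$relative_position, "downstream") # lower coord, minus gene
  expect_true(cand$frameshift_flag)                  # 100 bp, not /3
})

test_that("screening equals a brute-force filter over all variant-exon pairs", {
  cfg <- simulation_config(seed = 61, n_genes = 20, n_variants = 500,
                           retention = 0.6)
  ann <- simulate_annotation(cfg)
  ins <- simulate_insertions(cfg, ann$genes)
  cand <- screen_candidates(ins$variants, ann$genes, window = 100)
  # brute force: for each variant x gene, scan all exons
  expected <- 0L
  for (i in seq_len(nrow(ins$variants))) {
    p <- ins$variants$pos[i]
    for (gm in ann$genes) {
      sp <- c(min(gm$exons$start), max(gm$exons$end))
      if (p < sp[1] || p >= sp[2]) next
      o <- oracle_nearest(p, gm)
      if (o$dmin >= 1 && o$dmin <= 100 && is_intronic(p, gm))
        expected <- expected + 1L
    }
  }
  expect_equal(nrow(cand), expected)
  # every candidate row agrees with the oracle distance
  for (i in seq_len(nrow(cand))) {
    gm <- ann$genes[[cand$gene_id[i]]]
    expect_equal(cand$distance[i], oracle_nearest(cand$pos[i], gm)$dmin)
  }
  # candidates are a subset of the distance table rows within the window
  nd <- nearest_exon_distance(ins$variants, ann$genes)
  in_window <- nd[!is.na(nd$distance) & nd$intronic &
                    nd$distance >= 1 & nd$distance <= 100, ]
  expect_setequal(paste(cand$pos, cand$gene_id),
                  paste(in_window$pos, in_window$gene_id))
})

test_that("exon lengths indivisible by three flag a frameshift", {
  expect_true(frameshift_flag(143))
  expect_false(frameshift_flag(111))
  expect_true(frameshift_flag(265))
  expect_equal(frameshift_flag(c(3, 4, 5, 6)), c(FALSE, TRUE, TRUE, FALSE))
  expect_error(frameshift_flag(0), ">= 1")
})

test_that("the equal-expectation chi-square uses Pearson with no continuity correction", {
  res <- equal_expectation_chi2(42, 31)
  expect_equal(res$p, 0.1979, tolerance = 5e-4 / 0.1979)
  expect_equal(res$df, 1)
  # symmetric in its arguments
  expect_equal(equal_expectation_chi2(31, 42)$p, res$p)
  # balanced counts: statistic 0, p 1
  bal <- equal_expectation_chi2(50, 50)
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p, 1)
  # closed form for the position test counts: chi2 = (40-36.5)^2/36.5 * 2
  pos <- equal_expectation_chi2(40, 33)
  expect_equal(pos$statistic, 0.671, tolerance = 1e-3)
  expect_equal(pos$p, 0.413, tolerance = 1e-3)
  expect_error(equal_expectation_chi2(0, 0), "zero")
})

test_that("the one-sample proportion chi-square matches the 2-cell Pearson sum", {
  null <- proportion_chi2(50, 100, 0.5)
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)
  cases <- withr::with_seed(8, data.frame(
    total = sample(50:500, 20),
    f = runif(20, 0.05, 0.95)))
  cases$obs <- withr::with_seed(9, rbinom(20, cases$total, cases$f))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      res <- proportion_chi2(obs, total, f)
      e1 <- total * f; e2 <- total * (1 - f)
      hand <- (obs - e1)^2 / e1 + ((total - obs) - e2)^2 / e2
      expect_equal(res$statistic, hand, tolerance = 1e-12)
      expect_equal(res$p, pchisq(hand, 1, lower.tail = FALSE))
    })
  }
  # near-null behaviour: observed at the expected count
  expect_gt(proportion_chi2(ceiling(0.3 * 200), 200, 0.3)$p, 0.9)
  expect_error(proportion_chi2(10, 100, 0), "strictly between")
  expect_error(proportion_chi2(101, 100, 0.5), "exceeds")
})

test_that("LD statistics agree with direct frequency arithmetic", {
  # perfect LD: only AB and ab haplotypes
  perfect <- ld_stats(matrix(c(60, 0, 0, 40), 2, 2, byrow = TRUE),
                      n_boot = 0)
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r2, 1)
  # independence: haplotype freqs are products of allele freqs
  indep <- ld_stats(matrix(c(30, 30, 20, 20), 2, 2, byrow = TRUE),
                    n_boot = 0)
  expect_equal(indep$r2, 0, tolerance = 1e-12)
  expect_equal(indep$d_prime, 0, tolerance = 1e-12)
  # 100 random tables against the oracle
  tabs <- withr::with_seed(31, replicate(100, rmultinom(1, 200, runif(4, 0.05, 1)),
                                         simplify = FALSE))
  for (tb in tabs) {
    m <- matrix(tb, 2, 2)
    o <- oracle_ld(m[1, 1], m[1, 2], m[2, 1], m[2, 2])
    got <- ld_stats(m, n_boot = 0)
    expect_equal(got$r2, o$r2, tolerance = 1e-12)
    expect_equal(got$d_prime, o$d_prime, tolerance = 1e-12)
    expect_equal(got$d, o$d, tolerance = 1e-12)
    # swapping allele labels at the first locus: D flips sign, D' and r2 fixed
    sw <- ld_stats(m[2:1, ], n_boot = 0)
    expect_equal(sw$r2, got$r2, tolerance = 1e-12)
    expect_equal(sw$d_prime, got$d_prime, tolerance = 1e-12)
    expect_equal(sw$d, -got$d, tolerance = 1e-12)
  }
  expect_error(ld_stats(matrix(c(50, 50, 0, 0), 2, 2)), "monomorphic")
  # bootstrap CI is deterministic given the seed and brackets the estimate
  ci1 <- ld_stats(matrix(c(50, 10, 8, 40), 2, 2), seed = 5)$ci
  ci2 <- ld_stats(matrix(c(50, 10, 8, 40), 2, 2), seed = 5)$ci
  expect_identical(ci1, ci2)
  expect_true(ci1[1] <= ci1[2])
})

test_that("summary fractions render at one decimal", {
  sf <- summary_fraction(5, 23)
  expect_equal(sf$display, 21.7)
  expect_equal(sf$label, "21.7%")
  expect_equal(summary_fraction(1, 3)$display, 33.3)
  expect_error(summary_fraction(1, 0), "positive")
})
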