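# Exon classification, nearest-exon distance geometry and annotation IO.

two_iso_gene <- function(strand = "+") {
  canonical <- data.frame(start = c(100, 1000, 2000), end = c(200, 1100, 2100))
  gene_model("g1", "chr1", strand,
             list(iso1 = canonical, iso2 = canonical[-2, ]))
}

test_that("an exon absent from one spanning isoform is skipped, the rest constitutive", {
  gm <- two_iso_gene()
  expect_equal(gm$exons$exon_class, c("constitutive", "skipped", "constitutive"))
  # single-isoform gene: everything constitutive
  gm1 <- gene_model("g2", "chr1", "+",
                    list(only = data.frame(start = c(10, 500), end = c(100, 600))))
  expect_true(all(gm1$exons$exon_class == "constitutive"))
})

test_that("alternative boundaries are oriented by gene strand", {
  iso <- list(A = data.frame(start = 100, end = 200),
              B = data.frame(start = 100, end = 230))
  expect_equal(classify_exon(100, 200, iso, strand = "+"), "alt3")
  expect_equal(classify_exon(100, 200, iso, strand = "-"), "alt5")
  iso2 <- list(A = data.frame(start = 100, end = 200),
               B = data.frame(start = 80, end = 200))
  expect_equal(classify_exon(100, 200, iso2, strand = "+"), "alt5")
  # identical in all isoforms -> constitutive regardless of how many
  iso3 <- rep(list(data.frame(start = 5, end = 50)), 3)
  names(iso3) <- c("a", "b", "c")
  expect_equal(classify_exon(5, 50, iso3), "constitutive")
  expect_error(classify_exon(900, 950, iso3), "not found")
})

test_that("classification matches the enumeration oracle on randomized gene models", {
  for (seed in 1:50) {
    gm <- random_gene_fixture(seed)
    ex <- gm$exons
    for (i in seq_len(nrow(ex))) {
      expect_equal(ex$exon_class[i],
                   oracle_classify(ex$start[i], ex$end[i], gm$isoforms,
                                   gm$strand),
                   info = sprintf("seed %d exon %d", seed, i))
    }
  }
})

test_that("classification is invariant to isoform order and coordinate translation", {
  for (seed in c(3, 17, 29)) {
    gm <- random_gene_fixture(seed)
    rev_iso <- rev(gm$isoforms)
    gm_rev <- gene_model(gm$gene_id, gm$chrom, gm$strand, rev_iso)
    expect_equal(gm$exons$exon_class, gm_rev$exons$exon_class)
    shifted <- lapply(gm$isoforms, function(e) data.frame(start = e$start + 10000,
                                                          end = e$end + 10000))
    gm_sh <- gene_model(gm$gene_id, gm$chrom, gm$strand, shifted)
    expect_equal(gm$exons$exon_class, gm_sh$exons$exon_class)
  }
})

test_that("gene model construction validates its invariants", {
  expect_error(gene_model("g", "chr1", "+",
                          list(a = data.frame(start = 10, end = 10))),
               "start >= end")
  expect_error(gene_model("g", "chr1", "+",
                          list(a = data.frame(start = c(10, 50), end = c(60, 100)))),
               "overlapping")
  expect_error(gene_model("g", "chr1", "*", list(a = data.frame(start = 1, end = 2))),
               "strand")
})

test_that("nearest-exon distance follows the adjacent-base-is-1 convention", {
  gm <- two_iso_gene("+")
  v <- function(pos) data.frame(chrom = "chr1", pos = pos)
  # 41 bases 3' of an exon end (mirrors a 41 bp upstream element on a - gene)
  nd <- nearest_exon_distance(v(1140L), list(gm))
  expect_equal(nd$distance, 41)
  expect_equal(nd$relative_position, "downstream")
  # within an exon
  nd0 <- nearest_exon_distance(v(1050L), list(gm))
  expect_equal(nd0$distance, 0)
  expect_equal(nd0$relative_position, "within_exon")
  # base adjacent to an exon edge on either side
  expect_equal(nearest_exon_distance(v(999L), list(gm))$distance, 1)
  expect_equal(nearest_exon_distance(v(1100L), list(gm))$distance, 1)
  # outside all gene bodies -> flagged intergenic, never dropped
  ndi <- nearest_exon_distance(v(99999L), list(gm))
  expect_equal(ndi$relative_position, "intergenic")
  expect_true(is.na(ndi$distance))
})

test_that("nearest exon and position match a brute-force scan at 200 random points", {
  gm <- withr::with_seed(11, {
    starts <- 1000 + cumsum(c(0, sample(400:900, 9) + 100))
    gene_model("g10", "chr1", "+",
               list(iso = data.frame(start = starts, end = starts + 100)))
  })
  sp <- c(min(gm$exons$start), max(gm$exons$end))
  pos <- withr::with_seed(12, sample(sp[1]:(sp[2] - 1), 200))
  nd <- nearest_exon_distance(data.frame(chrom = "chr1", pos = pos), list(gm))
  for (i in seq_along(pos)) {
    o <- oracle_nearest(pos[i], gm)
    expect_equal(nd$distance[i], o$dmin, info = paste("pos", pos[i]))
    expect_true(match(nd$exon_id[i], gm$exons$exon_id) %in% o$idx)
    # reported distance is <= distance to every exon edge
    expect_true(all(nd$distance[i] <= vapply(seq_len(nrow(gm$exons)),
      function(j) oracle_point_distance(pos[i], gm$exons$start[j],
                                        gm$exons$end[j]), numeric(1))))
  }
})

test_that("reversing gene strand swaps upstream/downstream but not distance", {
  gm_p <- two_iso_gene("+")
  gm_m <- two_iso_gene("-")
  pos <- c(950L, 1140L, 250L, 1950L)
  nd_p <- nearest_exon_distance(data.frame(chrom = "chr1", pos = pos), list(gm_p))
  nd_m <- nearest_exon_distance(data.frame(chrom = "chr1", pos = pos), list(gm_m))
  expect_equal(nd_p$distance, nd_m$distance)
  flip <- c(upstream = "downstream", downstream = "upstream")
  expect_equal(unname(flip[nd_p$relative_position]), nd_m$relative_position)
})

test_that("equidistant variants resolve to the downstream exon and are flagged", {
  # exons [100,200) and [300,400); pos 250: distance 51 to left (250-200+1),
  # 50 to right; pos 251: 52 vs 49. Equidistance needs pos where
  # s - p == p - e + 1  ->  p = (s + e - 1) / 2; with s=301,e=200 use exons
  # giving an integer midpoint.
  gm <- gene_model("gt", "chr1", "+",
                   list(i = data.frame(start = c(100, 301), end = c(200, 400))))
  nd <- nearest_exon_distance(data.frame(chrom = "chr1", pos = 250L), list(gm))
  expect_true(nd$tie)
  expect_equal(nd$exon_id, "gt:301-400")  # downstream on + strand
  gm_m <- gene_model("gt", "chr1", "-",
                     list(i = data.frame(start = c(100, 301), end = c(200, 400))))
  nd_m <- nearest_exon_distance(data.frame(chrom = "chr1", pos = 250L), list(gm_m))
  expect_true(nd_m$tie)
  expect_equal(nd_m$exon_id, "gt:100-200")  # downstream in transcription order
})

test_that("is_intronic matches containment against all exon intervals", {
  gm <- two_iso_gene()
  expect_true(is_intronic(500L, gm))       # between exon 1 and 2
  expect_false(is_intronic(150L, gm))      # inside exon 1 of both isoforms
  # inside the skipped exon: intronic with respect to the skipping isoform
  expect_true(is_intronic(1050L, gm))
  expect_false(is_intronic(50L, gm))       # before the gene
  pos <- withr::with_seed(4, sample(0:2500, 300))
  manual <- vapply(pos, function(p) {
    any(vapply(gm$isoforms, function(ex) {
      p >= min(ex$start) && p < max(ex$end) &&
        !any(p >= ex$start & p < ex$end)
    }, logical(1)))
  }, logical(1))
  expect_equal(is_intronic(pos, gm), manual)
})

test_that("GFF3 annotation round-trips through write and read", {
  cfg <- simulation_config(seed = 21, n_genes = 5)
  path <- withr::local_tempfile(fileext = ".gff3")
  ann <- simulate_annotation(cfg, path = path)
  back <- read_annotation(path)
  expect_setequal(names(back), names(ann$genes))
  for (g in names(ann$genes)) {
    expect_equal(back[[g]]$strand, ann$genes[[g]]$strand)
    expect_equal(back[[g]]$exons$start, ann$genes[[g]]$exons$start)
    expect_equal(back[[g]]$exons$end, ann$genes[[g]]$exons$end)
    expect_equal(back[[g]]$exons$exon_class, ann$genes[[g]]$exons$exon_class)
  }
})

test_that("BED12 transcripts are parsed with genomic block coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t100\t1000\tgeneA|iso1\t0\t+\t100\t1000\t0\t3\t50,80,100\t0,300,800",
    "chr1\t100\t1000\tgeneA|iso2\t0\t+\t100\t1000\t0\t2\t50,100\t0,800"),
    path)
  genes <- read_annotation(path)
  expect_equal(length(genes), 1L)
  ex <- genes[["geneA"]]$exons
  expect_equal(ex$start, c(100, 400, 900))
  expect_equal(ex$end, c(150, 480, 1000))
  expect_equal(ex$exon_class, c("constitutive", "skipped", "constitutive"))
})

test_that("the variant reader validates the extended-BED schema", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("# comment",
               "chr1\t500\t501\tAluYa5\t281\t-\t0.285",
               "chr1\t900\t901\tAluYb8\t300\t+\t."), path)
  v <- read_variants(path)
  expect_equal(v$pos, c(500L, 900L))
  expect_equal(v$allele_frequency, c(0.285, NA))
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t500\t502\tAluYa5\t281\t-", bad)
  expect_error(read_variants(bad), "pos \\+ 1")
})
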